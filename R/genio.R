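#' Construct a genotype dataset
#'
#' The central genotype container: an ordered marker table, an ordered sample
#' table, and a samples x markers matrix of allele counts in \{0, 1, 2, NA\}.
#' At load time calls count copies of `allele2` for every marker; the counted
#' allele is re-oriented to the minor allele only by
#' [recode_minor_allele()], so loading is deterministic and side-effect-free.
#'
#' @param calls integer matrix, samples in rows, markers in columns; values
#'   0/1/2 or NA for a missing call.
#' @param markers data.frame with columns `id`, `chrom`, `pos`, `allele1`,
#'   `allele2`; optional logical columns `counted_allele2` (default `TRUE`)
#'   and `referent_is_minor` (default `FALSE`).
#' @param samples data.frame with columns `fid`, `iid`, `sex`
#'   (`"male"`/`"female"`/`"unknown"`) and `phenotype` (may be `NA`).
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(calls, markers, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(is.data.frame(markers), is.data.frame(samples))
  if (nrow(calls) != nrow(samples) || ncol(calls) != nrow(markers))
    stop("calls matrix shape must be |samples| x |markers|")
  if (anyDuplicated(markers$id))
    stop("duplicate marker ids")
  key <- paste(samples$fid, samples$iid, sep = ":")
  if (anyDuplicated(key))
    stop("duplicate sample keys (FID:IID)")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("non-missing calls must lie in {0, 1, 2}")
  if (any(!is.na(markers$pos) & markers$pos < 1))
    stop("marker positions are 1-based: pos >= 1")
  if (is.null(markers$counted_allele2)) markers$counted_allele2 <- TRUE
  if (is.null(markers$referent_is_minor)) markers$referent_is_minor <- FALSE
  rownames(calls) <- key
  colnames(calls) <- markers$id
  structure(list(calls = calls, markers = markers, samples = samples),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d samples x %d markers (%.1f%% missing)\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$calls)

sample_keys <- function(data) paste(data$samples$fid, data$samples$iid, sep = ":")

## subset helpers shared by the QC filters
subset_markers <- function(data, keep) {
  genotype_dataset(data$calls[, keep, drop = FALSE],
                   data$markers[keep, , drop = FALSE],
                   data$samples)
}

subset_samples <- function(data, keep) {
  genotype_dataset(data$calls[keep, , drop = FALSE],
                   data$markers,
                   data$samples[keep, , drop = FALSE])
}

decode_sex <- function(x) {
  x <- as.character(x)
  out <- rep("unknown", length(x))
  out[x %in% c("1", "male", "M")] <- "male"
  out[x %in% c("2", "female", "F")] <- "female"
  out
}

encode_sex <- function(x) {
  out <- rep("0", length(x))
  out[x == "male"] <- "1"
  out[x == "female"] <- "2"
  out
}

## ---------------------------------------------------------------------------
## PED/MAP (PLINK 1.x text)

read_map_file <- function(map) {
  m <- utils::read.table(map, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (ncol(m) == 4L) {
    names(m) <- c("chrom", "id", "cm", "pos")
  } else if (ncol(m) == 3L) {
    names(m) <- c("chrom", "id", "pos")
    m$cm <- "0"
  } else stop("MAP file must have 3 or 4 columns")
  m$pos <- as.integer(m$pos)
  m[, c("chrom", "id", "cm", "pos")]
}

read_plink_ped <- function(ped, map) {
  mp <- read_map_file(map)
  n_mark <- nrow(mp)
  lines <- readLines(ped)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * n_mark
  nc <- lengths(toks)
  if (any(nc != want))
    stop(sprintf("PED line %d has %d fields; MAP implies %d",
                 which(nc != want)[1], nc[nc != want][1], want))
  tokm <- do.call(rbind, toks)
  samples <- data.frame(fid = tokm[, 1], iid = tokm[, 2],
                        sex = decode_sex(tokm[, 5]),
                        phenotype = suppressWarnings(as.numeric(tokm[, 6])),
                        stringsAsFactors = FALSE)
  samples$phenotype[samples$phenotype %in% c(-9, 0)] <- NA
  n_samp <- nrow(tokm)
  calls <- matrix(NA_integer_, n_samp, n_mark)
  a1v <- character(n_mark); a2v <- character(n_mark)
  for (j in seq_len(n_mark)) {
    a <- tokm[, 6L + 2L * j - 1L]
    b <- tokm[, 6L + 2L * j]
    obs <- sort(setdiff(unique(c(a, b)), "0"))
    if (length(obs) > 2L)
      stop(sprintf("marker %s has >2 alleles in PED", mp$id[j]))
    if (length(obs) == 2L) { a1 <- obs[1]; a2 <- obs[2] }
    else if (length(obs) == 1L) { a1 <- "0"; a2 <- obs[1] }  # monomorphic
    else { a1 <- "0"; a2 <- "0" }                            # all missing
    g <- (a == a2) + (b == a2)
    g[a == "0" | b == "0"] <- NA
    calls[, j] <- as.integer(g)
    a1v[j] <- a1; a2v[j] <- a2
  }
  markers <- data.frame(id = mp$id, chrom = mp$chrom, pos = mp$pos,
                        allele1 = a1v, allele2 = a2v,
                        stringsAsFactors = FALSE)
  genotype_dataset(calls, markers, samples)
}

## counted/other allele labels for each marker, used by every writer
counted_other <- function(markers) {
  cnt <- ifelse(markers$counted_allele2, markers$allele2, markers$allele1)
  oth <- ifelse(markers$counted_allele2, markers$allele1, markers$allele2)
  list(counted = cnt, other = oth)
}

write_plink_ped <- function(data, ped, map) {
  mk <- data$markers
  utils::write.table(
    data.frame(mk$chrom, mk$id, "0", mk$pos),
    map, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  al <- counted_other(mk)
  n <- nrow(data$calls)
  geno <- matrix("0", n, 2L * ncol(data$calls))
  for (j in seq_len(ncol(data$calls))) {
    g <- data$calls[, j]
    a <- ifelse(is.na(g), "0", ifelse(g >= 1L, al$counted[j], al$other[j]))
    b <- ifelse(is.na(g), "0", ifelse(g == 2L, al$counted[j], al$other[j]))
    geno[, 2L * j - 1L] <- a
    geno[, 2L * j] <- b
  }
  sm <- data$samples
  pheno <- ifelse(is.na(sm$phenotype), "-9", as.character(sm$phenotype))
  out <- cbind(sm$fid, sm$iid, "0", "0", encode_sex(sm$sex), pheno, geno)
  writeLines(apply(out, 1L, paste, collapse = " "), ped)
  invisible(c(ped = ped, map = map))
}

## ---------------------------------------------------------------------------
## BED/BIM/FAM (PLINK 1.x binary, SNP-major)

read_plink_bed <- function(bed, bim, fam) {
  bm <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  names(bm) <- c("chrom", "id", "cm", "pos", "allele1", "allele2")
  fm <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  samples <- data.frame(fid = fm[, 1], iid = fm[, 2],
                        sex = decode_sex(fm[, 5]),
                        phenotype = suppressWarnings(as.numeric(fm[, 6])),
                        stringsAsFactors = FALSE)
  samples$phenotype[samples$phenotype %in% c(-9, 0)] <- NA
  n_samp <- nrow(fm); n_mark <- nrow(bm)
  raw <- readBin(bed, "raw", n = file.info(bed)$size)
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("BED magic-byte mismatch: not a PLINK .bed file")
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major BED files are supported")
  bpm <- ceiling(n_samp / 4)
  if (length(raw) - 3L != bpm * n_mark)
    stop("BED payload size inconsistent with BIM/FAM dimensions")
  body <- raw[-(1:3)]
  bits <- as.integer(rawToBits(body))        # LSB first within each byte
  dim(bits) <- c(8L * bpm, n_mark)
  lo <- bits[seq(1L, 2L * n_samp, by = 2L), , drop = FALSE]
  hi <- bits[seq(2L, 2L * n_samp, by = 2L), , drop = FALSE]
  v <- lo + 2L * hi                          # 0=homA1 1=missing 2=het 3=homA2
  calls <- matrix(NA_integer_, n_samp, n_mark)
  calls[v == 0L] <- 0L
  calls[v == 2L] <- 1L
  calls[v == 3L] <- 2L
  markers <- data.frame(id = bm$id, chrom = bm$chrom,
                        pos = as.integer(bm$pos),
                        allele1 = bm$allele1, allele2 = bm$allele2,
                        stringsAsFactors = FALSE)
  genotype_dataset(calls, markers, samples)
}

write_plink_bed <- function(data, bed, bim, fam) {
  mk <- data$markers
  al <- counted_other(mk)
  ## BIM A1/A2 written so that stored 2-bit codes count copies of A2
  utils::write.table(
    data.frame(mk$chrom, mk$id, "0", mk$pos, al$other, al$counted),
    bim, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  sm <- data$samples
  pheno <- ifelse(is.na(sm$phenotype), "-9", as.character(sm$phenotype))
  utils::write.table(
    data.frame(sm$fid, sm$iid, "0", "0", encode_sex(sm$sex), pheno),
    fam, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  n_samp <- nrow(data$calls); n_mark <- ncol(data$calls)
  bpm <- ceiling(n_samp / 4)
  con <- file(bed, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  vmap <- c(`0` = 0L, `1` = 2L, `2` = 3L)    # call -> 2-bit value; NA -> 1
  for (j in seq_len(n_mark)) {
    g <- data$calls[, j]
    v <- ifelse(is.na(g), 1L, vmap[as.character(g)])
    bits <- integer(8L * bpm)
    bits[seq(1L, 2L * n_samp, by = 2L)] <- v %% 2L
    bits[seq(2L, 2L * n_samp, by = 2L)] <- v %/% 2L
    writeBin(packBits(as.integer(bits), type = "raw"), con)
  }
  invisible(c(bed = bed, bim = bim, fam = fam))
}

## ---------------------------------------------------------------------------
## VCF (bi-allelic SNVs; multi-allelic sites skipped with a warning)

read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    warning(sprintf("skipping %d multi-allelic VCF site(s): %s",
                    sum(multi),
                    paste(utils::head(fix[multi, "ID"], 5), collapse = ", ")))
  keep <- which(!multi)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, names(gt)))
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  gt[is.na(gt)] <- "./."
  al <- strsplit(as.vector(gt), "[/|]")
  cnt <- vapply(al, function(z) {
    if (length(z) == 0L || any(z == ".")) NA_integer_ else sum(z == "1")
  }, integer(1))
  ## gt is markers x samples; calls are samples x markers
  calls <- t(matrix(cnt, nrow = nrow(gt), ncol = ncol(gt)))
  ids <- fix[, "ID"]
  ids[ids == "." | is.na(ids)] <-
    paste0(fix[ids == "." | is.na(ids), "CHROM"], ":",
           fix[ids == "." | is.na(ids), "POS"])
  markers <- data.frame(id = ids, chrom = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]),
                        allele1 = fix[, "REF"], allele2 = fix[, "ALT"],
                        stringsAsFactors = FALSE)
  sn <- colnames(gt)
  samples <- data.frame(fid = sn, iid = sn, sex = "unknown",
                        phenotype = NA_real_, stringsAsFactors = FALSE)
  genotype_dataset(calls, markers, samples)
}

write_vcf_genotypes <- function(data, path) {
  mk <- data$markers
  al <- counted_other(mk)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=assocpipe",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", data$samples$iid), collapse = "\t"))
  gt_str <- c("0/0", "0/1", "1/1")
  lines <- character(ncol(data$calls))
  for (j in seq_len(ncol(data$calls))) {
    g <- data$calls[, j]
    ## ALT is allele2; express counts as ALT copies
    alt_copies <- if (mk$counted_allele2[j]) g else 2L - g
    gs <- ifelse(is.na(alt_copies), "./.", gt_str[alt_copies + 1L])
    lines[j] <- paste(c(mk$chrom[j], mk$pos[j], mk$id[j],
                        mk$allele1[j], mk$allele2[j], ".", "PASS", ".",
                        "GT", gs), collapse = "\t")
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

## ---------------------------------------------------------------------------

#' Read genotypes from PLINK text, PLINK binary, or VCF
#'
#' @param paths either a file-path prefix (extensions are appended per
#'   dialect) or a named list/vector of explicit paths (`ped`+`map`,
#'   `bed`+`bim`+`fam`, or `vcf`).
#' @param dialect one of `"ped_map"`, `"bed_bim_fam"`, `"vcf"`.
#' @return A [genotype_dataset()] whose calls count copies of `allele2`
#'   (ALT for VCF, BIM A2 for binary PLINK, the lexicographically larger
#'   observed allele for text PLINK). Multi-allelic VCF sites are skipped
#'   with a warning; PED allele code `"0"` and VCF `./.` load as missing.
#' @export
read_genotypes <- function(paths, dialect = c("ped_map", "bed_bim_fam", "vcf")) {
  dialect <- match.arg(dialect)
  p <- as.list(paths)
  pfx <- if (is.null(names(p)) && length(p) == 1L) p[[1]] else NULL
  switch(dialect,
    ped_map = {
      ped <- if (!is.null(pfx)) paste0(pfx, ".ped") else p$ped
      map <- if (!is.null(pfx)) paste0(pfx, ".map") else p$map
      read_plink_ped(ped, map)
    },
    bed_bim_fam = {
      bed <- if (!is.null(pfx)) paste0(pfx, ".bed") else p$bed
      bim <- if (!is.null(pfx)) paste0(pfx, ".bim") else p$bim
      fam <- if (!is.null(pfx)) paste0(pfx, ".fam") else p$fam
      read_plink_bed(bed, bim, fam)
    },
    vcf = read_vcf_genotypes(if (!is.null(pfx)) pfx else p$vcf))
}

#' Write genotypes to PLINK text, PLINK binary, or VCF
#'
#' Inverse of [read_genotypes()]; the genotype configuration (allele pairs
#' per sample) is written faithfully in every dialect.
#'
#' @inheritParams read_genotypes
#' @param data a [genotype_dataset()].
#' @export
write_genotypes <- function(data, paths,
                            dialect = c("ped_map", "bed_bim_fam", "vcf")) {
  dialect <- match.arg(dialect)
  p <- as.list(paths)
  pfx <- if (is.null(names(p)) && length(p) == 1L) p[[1]] else NULL
  switch(dialect,
    ped_map = write_plink_ped(data,
      if (!is.null(pfx)) paste0(pfx, ".ped") else p$ped,
      if (!is.null(pfx)) paste0(pfx, ".map") else p$map),
    bed_bim_fam = write_plink_bed(data,
      if (!is.null(pfx)) paste0(pfx, ".bed") else p$bed,
      if (!is.null(pfx)) paste0(pfx, ".bim") else p$bim,
      if (!is.null(pfx)) paste0(pfx, ".fam") else p$fam),
    vcf = write_vcf_genotypes(data, if (!is.null(pfx)) pfx else p$vcf))
}

## ---------------------------------------------------------------------------
## Trait tables

#' Read a phenotype/exposure/covariate table
#'
#' Whitespace-delimited with a header row.  Key columns (`FID` `IID`, or
#' `IID` alone with `has_fid = FALSE`) precede the variables.  Variable types
#' are inferred: any non-numeric column is `categorical`, a numeric column
#' with at most two distinct non-missing values is `binary`, anything else
#' is `continuous`.
#'
#' @param path file path.
#' @param has_fid the first two columns are FID and IID; when `FALSE` the
#'   first column is IID and FID is synthesised equal to IID.
#' @param dummy_samples mark the table as self-contained: downstream analyses
#'   may run on its samples with no genotype data loaded.
#' @param missing_code token treated as a missing value (default `"-9"`).
#' @return A `trait_table`: a data.frame with `fid`, `iid` and the variable
#'   columns, plus a `types` attribute naming each variable's inferred type.
#' @export
read_trait_table <- function(path, has_fid = TRUE, dummy_samples = FALSE,
                             missing_code = "-9") {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE,
                          comment.char = "")
  if (has_fid) {
    if (ncol(df) < 3L) stop("trait table needs FID, IID and >=1 variable")
    fid <- df[[1]]; iid <- df[[2]]; vars <- df[-(1:2)]
  } else {
    if (ncol(df) < 2L) stop("trait table needs IID and >=1 variable")
    iid <- df[[1]]; fid <- iid; vars <- df[-1]
  }
  if (ncol(vars) == 0L) stop("empty variable set")
  if (anyDuplicated(names(vars))) stop("duplicate variable names")
  key <- paste(fid, iid, sep = ":")
  if (anyDuplicated(key)) stop("duplicate sample keys in trait table")
  types <- character(ncol(vars)); names(types) <- names(vars)
  for (nm in names(vars)) {
    x <- vars[[nm]]
    x[x == missing_code] <- NA
    num <- suppressWarnings(as.numeric(x))
    if (any(!is.na(x) & is.na(num))) {
      types[nm] <- "categorical"
      vars[[nm]] <- x
    } else {
      vars[[nm]] <- num
      types[nm] <- if (length(unique(num[!is.na(num)])) <= 2L) "binary"
                   else "continuous"
    }
  }
  out <- cbind(data.frame(fid = fid, iid = iid, stringsAsFactors = FALSE), vars)
  make_trait_table(out, types = types, dummy_samples = dummy_samples)
}

#' Assemble a trait table in memory
#'
#' @param df data.frame with `fid` and `iid` columns followed by variables.
#' @param types optional named character vector of variable types
#'   (`binary`/`continuous`/`categorical`); inferred when omitted.
#' @param dummy_samples see [read_trait_table()].
#' @export
make_trait_table <- function(df, types = NULL, dummy_samples = FALSE) {
  stopifnot(all(c("fid", "iid") %in% names(df)))
  vn <- setdiff(names(df), c("fid", "iid"))
  if (is.null(types)) {
    types <- vapply(vn, function(nm) {
      x <- df[[nm]]
      if (!is.numeric(x)) "categorical"
      else if (length(unique(x[!is.na(x)])) <= 2L) "binary"
      else "continuous"
    }, character(1))
  }
  stopifnot(setequal(names(types), vn))
  structure(df, types = types[vn], dummy_samples = dummy_samples,
            class = c("trait_table", "data.frame"))
}

#' @export
trait_types <- function(traits) attr(traits, "types")

trait_keys <- function(traits) paste(traits$fid, traits$iid, sep = ":")

## ---------------------------------------------------------------------------
## CNV call tables (PennCNV-style rectangles)

#' Read a CNV call table
#'
#' Expects a header with columns (case-insensitive, some aliases accepted):
#' `sample`, `chrom`/`chr`, `start`, `stop`/`end`, `copy_number`/`cn` and/or
#' `state`, `n_snps`/`numsnp`.  Coordinates are 1-based fully inclusive.
#' The state is derived from the copy number when absent: `< 2` deletion,
#' `> 2` duplication; a copy number of exactly 2 is rejected (not a CNV).
#'
#' @param path file path.
#' @return A `cnv_calls` data.frame with columns `sample`, `chrom`, `start`,
#'   `stop`, `copy_number`, `state`, `n_snps`, in input order.
#' @export
read_cnv_calls <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  nm <- tolower(names(df))
  pick <- function(...) {
    i <- which(nm %in% c(...))
    if (length(i)) df[[i[1]]] else NULL
  }
  sample <- pick("sample", "sample_id", "iid")
  chrom <- pick("chrom", "chr", "chromosome")
  start <- pick("start")
  stop_ <- pick("stop", "end")
  cn <- pick("copy_number", "cn", "state_cn")
  state <- pick("state")
  n_snps <- pick("n_snps", "numsnp", "num_snp", "snps")
  if (is.null(sample) || is.null(chrom) || is.null(start) || is.null(stop_) ||
      (is.null(cn) && is.null(state)) || is.null(n_snps))
    stop("CNV table needs sample, chrom, start, stop, copy_number (or state), n_snps")
  cnv_calls(sample = as.character(sample), chrom = as.character(chrom),
            start = as.integer(start), stop = as.integer(stop_),
            copy_number = if (is.null(cn)) NULL else {
              v <- suppressWarnings(as.integer(cn))
              if (any(is.na(v) & !is.na(cn))) stop("unparseable copy number")
              v
            },
            state = if (is.null(state)) NULL else as.character(state),
            n_snps = as.integer(n_snps))
}

#' Construct a CNV call set
#'
#' @param sample,chrom,start,stop,n_snps per-call fields; 1-based inclusive
#'   coordinates.
#' @param copy_number integer copy-number state (`< 2` deletion, `> 2`
#'   duplication; 2 is rejected).  May be omitted when `state` is given.
#' @param state `"deletion"`/`"duplication"`; derived from `copy_number`
#'   when omitted.
#' @export
cnv_calls <- function(sample, chrom, start, stop, copy_number = NULL,
                      state = NULL, n_snps) {
  if (any(start > stop)) stop("CNV call with start > stop")
  if (is.null(state)) {
    if (any(copy_number == 2L)) stop("copy number 2 is not a CNV")
    state <- ifelse(copy_number < 2L, "deletion", "duplication")
  } else {
    state <- ifelse(state %in% c("deletion", "del", "DEL"), "deletion",
                    ifelse(state %in% c("duplication", "dup", "DUP"),
                           "duplication", NA))
    if (anyNA(state)) stop("unrecognised CNV state")
    if (is.null(copy_number))
      copy_number <- ifelse(state == "deletion", 1L, 3L)
  }
  bad <- (copy_number < 2L & state != "deletion") |
         (copy_number > 2L & state != "duplication")
  if (any(bad)) stop("state inconsistent with copy number")
  structure(data.frame(sample = sample, chrom = chrom,
                       start = as.integer(start), stop = as.integer(stop),
                       copy_number = as.integer(copy_number), state = state,
                       n_snps = as.integer(n_snps),
                       stringsAsFactors = FALSE),
            class = c("cnv_calls", "data.frame"))
}

## ---------------------------------------------------------------------------
## Concordance check

#' Genotype concordance between two datasets
#'
#' Compares calls over the intersection of sample keys and marker ids.
#' Allele labels are reconciled strand-naively by exact match on the sorted
#' allele pair; markers whose sorted pairs differ are dropped with a warning.
#' A pair where either call is missing is excluded from both the numerator
#' and the denominator.
#'
#' @param a,b two [genotype_dataset()]s.
#' @return A `concordance_report`: list with `per_sample` and `per_marker`
#'   data.frames (`discordant`, `compared`) and a `detail` data.frame of the
#'   individual discordant calls.
#' @export
check_concordance <- function(a, b) {
  ka <- sample_keys(a); kb <- sample_keys(b)
  samp <- intersect(ka, kb)
  mark <- intersect(a$markers$id, b$markers$id)
  if (length(samp) == 0L || length(mark) == 0L)
    stop("no overlap between datasets (shared samples and markers required)")
  ia <- match(mark, a$markers$id); ib <- match(mark, b$markers$id)
  ## strand-naive reconciliation on the sorted allele pair; "0" marks an
  ## unobserved allele (monomorphic or all-missing), which matches anything
  ok <- vapply(seq_along(mark), function(j) {
    sa <- setdiff(c(a$markers$allele1[ia[j]], a$markers$allele2[ia[j]]), "0")
    sb <- setdiff(c(b$markers$allele1[ib[j]], b$markers$allele2[ib[j]]), "0")
    all(sa %in% sb) || all(sb %in% sa)
  }, logical(1))
  if (!all(ok)) {
    warning(sprintf("%d shared marker(s) dropped: allele pairs do not match",
                    sum(!ok)))
    mark <- mark[ok]; ia <- ia[ok]; ib <- ib[ok]
    if (length(mark) == 0L) stop("no overlap after allele reconciliation")
  }
  ca <- a$calls[match(samp, ka), ia, drop = FALSE]
  cb <- b$calls[match(samp, kb), ib, drop = FALSE]
  ## align counted allele: flip b where its counted label differs from a's
  cnt_a <- counted_other(a$markers)$counted[ia]
  cnt_b <- counted_other(b$markers)$counted[ib]
  flip <- cnt_a != cnt_b
  if (any(flip)) cb[, flip] <- 2L - cb[, flip]
  both <- !is.na(ca) & !is.na(cb)
  disc <- both & (ca != cb)
  per_sample <- data.frame(sample = samp,
                           discordant = rowSums(disc),
                           compared = rowSums(both),
                           stringsAsFactors = FALSE)
  per_marker <- data.frame(marker = mark,
                           discordant = colSums(disc),
                           compared = colSums(both),
                           stringsAsFactors = FALSE)
  idx <- which(disc, arr.ind = TRUE)
  detail <- data.frame(sample = samp[idx[, 1]], marker = mark[idx[, 2]],
                       call_a = ca[idx], call_b = cb[idx],
                       stringsAsFactors = FALSE)
  structure(list(per_sample = per_sample, per_marker = per_marker,
                 detail = detail),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("concordance: %d samples x %d markers compared, %d discordant call(s)\n",
              nrow(x$per_sample), nrow(x$per_marker), nrow(x$detail)))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Results writer

#' Write scan results as a tab-delimited table
#'
#' One header row; missing statistics are emitted as `NA`; p-value columns
#' (names equal to `p` or ending in `_p`) are printed in scientific notation
#' with six significant digits for diffability.
#'
#' @param results data.frame of scan result rows.
#' @param path output file path.
#' @export
write_results <- function(results, path) {
  out <- as.data.frame(results)
  is_p <- grepl("(^|_)p$", names(out)) & vapply(out, is.numeric, logical(1))
  for (nm in names(out)[is_p]) {
    v <- out[[nm]]
    out[[nm]] <- ifelse(is.na(v), NA, formatC(v, digits = 5, format = "e"))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
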