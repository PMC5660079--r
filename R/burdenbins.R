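#' Read a region (gene) definition file
#'
#' Tab- or whitespace-delimited `chrom start stop name`.  The package works
#' in 1-based fully inclusive coordinates throughout; standard BED files
#' are 0-based half-open, so pass `one_based = FALSE` to convert
#' (`start + 1`, `stop` unchanged).
#'
#' @param path file path (no header, `#` comments allowed).
#' @param one_based set `FALSE` for standard BED input.
#' @return A `region_set` data.frame: `chrom`, `start`, `stop`, `name`.
#' @export
read_regions <- function(path, one_based = TRUE) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 4L) stop("region file needs chrom, start, stop, name")
  names(df)[1:4] <- c("chrom", "start", "stop", "name")
  df$start <- as.integer(df$start); df$stop <- as.integer(df$stop)
  if (!one_based) df$start <- df$start + 1L
  if (any(df$start > df$stop)) stop("region with start > stop")
  if (anyDuplicated(df$name)) stop("duplicate region names")
  structure(df[, c("chrom", "start", "stop", "name")],
            class = c("region_set", "data.frame"))
}

#' Region set constructor
#' @param chrom,start,stop,name region fields (1-based inclusive).
#' @export
region_set <- function(chrom, start, stop, name) {
  structure(data.frame(chrom = as.character(chrom), start = as.integer(start),
                       stop = as.integer(stop), name = as.character(name),
                       stringsAsFactors = FALSE),
            class = c("region_set", "data.frame"))
}

#' Per-sample CNV burden in base pairs
#'
#' Each call contributes its inclusive length `stop - start + 1` to the
#' deletion or duplication burden of its sample, regardless of copy-number
#' depth (a homozygous deletion counts once).  Overlapping calls within a
#' sample are summed without merging.  Samples with no calls get zeros.
#'
#' @param calls a [cnv_calls()] table (already filtered, see
#'   [filter_cnv_calls()]).
#' @param samples character vector of sample ids defining the output rows;
#'   a call referencing a sample outside this set is an error.
#' @return A `trait_table` (fid = iid = sample) with continuous columns
#'   `deletion_bp`, `duplication_bp`, `total_bp`.
#' @export
compute_cnv_burden <- function(calls, samples) {
  unknown <- setdiff(calls$sample, samples)
  if (length(unknown))
    stop(sprintf("CNV call references unknown sample(s): %s",
                 paste(utils::head(unknown, 5), collapse = ", ")))
  len <- as.numeric(calls$stop - calls$start + 1L)
  del <- tapply(len[calls$state == "deletion"],
                calls$sample[calls$state == "deletion"], sum)
  dup <- tapply(len[calls$state == "duplication"],
                calls$sample[calls$state == "duplication"], sum)
  d <- unname(ifelse(is.na(del[samples]), 0, del[samples]))
  u <- unname(ifelse(is.na(dup[samples]), 0, dup[samples]))
  make_trait_table(
    data.frame(fid = samples, iid = samples,
               deletion_bp = d, duplication_bp = u, total_bp = d + u,
               stringsAsFactors = FALSE),
    types = c(deletion_bp = "continuous", duplication_bp = "continuous",
              total_bp = "continuous"))
}

#' Madsen-Browning rare-variant weight
#'
#' `q = (m + 1) / (2 * n_controls + 2)`, the pseudo-count-smoothed minor
#' allele frequency in controls; `w = 1 / sqrt(n_total * q * (1 - q))`.
#' Rarer variants receive larger weights.
#'
#' @param minor_count_in_controls minor-allele count among controls (m).
#' @param n_controls number of control subjects.
#' @param n_total total number of genotyped subjects.
#' @return The weight(s), vectorized.
#' @export
madsen_browning_weight <- function(minor_count_in_controls, n_controls,
                                   n_total) {
  stopifnot(all(n_controls >= 1), all(n_total >= 1))
  q <- (minor_count_in_controls + 1) / (2 * n_controls + 2)
  1 / sqrt(n_total * q * (1 - q))
}

## calls oriented so values count the minor allele, whatever the stored
## counted allele is
minor_oriented_calls <- function(genotypes) {
  st <- compute_marker_stats(genotypes)
  calls <- genotypes$calls
  flip <- !is.na(st$counted_freq) & st$counted_freq > 0.5
  if (any(flip)) calls[, flip] <- 2L - calls[, flip, drop = FALSE]
  calls
}

#' Assign rare variants to region bins with Madsen-Browning weights
#'
#' A marker joins a bin if its position lies within the region span
#' (1-based inclusive) and its MAF is strictly below `maf_max`.  Regions
#' may overlap: a variant may belong to several bins.  Weights use the
#' control-sample allele counts when a binary phenotype is supplied, else
#' all samples (with a message).
#'
#' @param regions a `region_set`.
#' @param genotypes a [genotype_dataset()].
#' @param maf_max MAF upper bound (strict; default 0.05).
#' @param phenotype optional 0/1 vector aligned with the dataset's samples;
#'   0 marks controls.
#' @return A `bin_definitions` list, one element per region:
#'   `name`, `chrom`, `start`, `stop`, `members`, `weights` (named).
#'   Empty bins are retained with zero members.
#' @export
define_bins <- function(regions, genotypes, maf_max = 0.05,
                        phenotype = NULL) {
  st <- compute_marker_stats(genotypes)
  calls <- minor_oriented_calls(genotypes)
  if (is.null(phenotype)) {
    message("no phenotype supplied: Madsen-Browning q estimated from all samples")
    is_control <- rep(TRUE, nrow(calls))
  } else {
    stopifnot(length(phenotype) == nrow(calls))
    is_control <- !is.na(phenotype) & phenotype == 0
    if (!any(is_control)) {
      message("no controls available: Madsen-Browning q falls back to all samples")
      is_control <- rep(TRUE, nrow(calls))
    }
  }
  bins <- lapply(seq_len(nrow(regions)), function(r) {
    inside <- genotypes$markers$chrom == regions$chrom[r] &
      genotypes$markers$pos >= regions$start[r] &
      genotypes$markers$pos <= regions$stop[r]
    member <- inside & !is.na(st$maf) & st$maf < maf_max
    ids <- genotypes$markers$id[member]
    w <- numeric(0)
    if (length(ids)) {
      sub <- calls[, member, drop = FALSE]
      m <- colSums(sub[is_control, , drop = FALSE], na.rm = TRUE)
      n_tot <- colSums(!is.na(sub))
      w <- madsen_browning_weight(m, sum(is_control), pmax(n_tot, 1))
      names(w) <- ids
    }
    list(name = regions$name[r], chrom = regions$chrom[r],
         start = regions$start[r], stop = regions$stop[r],
         members = ids, weights = w)
  })
  names(bins) <- regions$name
  structure(bins, class = "bin_definitions")
}

#' @export
print.bin_definitions <- function(x, ...) {
  cat(sprintf("bin_definitions: %d bin(s), %d empty\n", length(x),
              sum(lengths(lapply(x, `[[`, "members")) == 0L)))
  invisible(x)
}

#' Weighted per-sample burden scores for each bin
#'
#' `score(sample, bin) = sum over member variants of w_v * minor-allele
#' count`.  Missing genotypes contribute 0 copies (the count of zero-imputed
#' calls is reported with a message).
#'
#' @param bins a `bin_definitions` list from [define_bins()].
#' @param genotypes the same [genotype_dataset()] the bins were defined on.
#' @return A `trait_table` (fid/iid from the dataset) with one continuous
#'   column per bin.
#' @export
compute_bin_scores <- function(bins, genotypes) {
  calls <- minor_oriented_calls(genotypes)
  n_imputed <- 0L
  scores <- lapply(bins, function(b) {
    if (length(b$members) == 0L) return(numeric(nrow(calls)))
    sub <- calls[, b$members, drop = FALSE]
    n_imputed <<- n_imputed + sum(is.na(sub))
    sub[is.na(sub)] <- 0L
    drop(sub %*% b$weights[b$members])
  })
  if (n_imputed > 0L)
    message(sprintf("%d missing genotype(s) inside bins counted as 0 copies",
                    n_imputed))
  df <- data.frame(fid = genotypes$samples$fid, iid = genotypes$samples$iid,
                   stringsAsFactors = FALSE)
  for (nm in names(scores)) df[[nm]] <- scores[[nm]]
  tp <- stats::setNames(rep("continuous", length(scores)), names(scores))
  make_trait_table(df, types = tp)
}
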