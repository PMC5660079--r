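#' Per-marker call rate and minor allele frequency
#'
#' Frequencies are computed over non-missing calls only.  `counted_freq` is
#' the frequency of the counted allele (allele2 at load time, the minor
#' allele after [recode_minor_allele()]); `maf = min(f, 1 - f)`.  A marker
#' with no non-missing calls gets `call_rate` 0 and undefined (`NA`)
#' frequencies.
#'
#' @param data a [genotype_dataset()].
#' @return data.frame with one row per marker: `id`, `call_rate`,
#'   `counted_freq`, `maf`, `minor_allele`, `monomorphic`.
#' @export
compute_marker_stats <- function(data) {
  if (nrow(data$calls) == 0L) stop("dataset has no samples")
  cr <- colMeans(!is.na(data$calls))
  f <- colMeans(data$calls, na.rm = TRUE) / 2
  f[cr == 0] <- NA_real_
  maf <- pmin(f, 1 - f)
  cnt <- counted_other(data$markers)
  minor <- ifelse(is.na(f), NA_character_,
                  ifelse(f <= 0.5, cnt$counted, cnt$other))
  data.frame(id = data$markers$id, call_rate = cr, counted_freq = f,
             maf = maf, minor_allele = minor,
             monomorphic = !is.na(maf) & maf == 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter markers on MAF and call rate
#'
#' Keeps markers with `maf > maf_min` and `call_rate > call_rate_min`
#' (strict inequalities, mirroring the conventional "> 5%", "> 99%"
#' thresholds).  Statistics are computed once on the dataset as passed in;
#' the sample set is unchanged.
#'
#' @param data a [genotype_dataset()].
#' @param maf_min,call_rate_min thresholds in `[0, 1]`.
#' @export
filter_markers <- function(data, maf_min = 0.05, call_rate_min = 0.99) {
  stopifnot(maf_min >= 0, maf_min <= 1, call_rate_min >= 0, call_rate_min <= 1)
  st <- compute_marker_stats(data)
  keep <- !is.na(st$maf) & st$maf > maf_min & st$call_rate > call_rate_min
  subset_markers(data, keep)
}

#' Filter samples on genotype call rate and/or missing outcome
#'
#' Drops samples whose genotype call rate is `<= call_rate_min`; when an
#' `outcome` column is named, additionally drops samples whose outcome value
#' is missing (or who are absent from the trait table).  With both filters
#' the surviving set is the intersection.
#'
#' @param data a [genotype_dataset()].
#' @param call_rate_min threshold in `[0, 1]`; default 0 keeps everyone on
#'   this criterion.
#' @param traits optional `trait_table`.
#' @param outcome optional trait column name for the trait-missing filter.
#' @export
filter_samples <- function(data, call_rate_min = 0, traits = NULL,
                           outcome = NULL) {
  cr <- rowMeans(!is.na(data$calls))
  keep <- cr > call_rate_min
  if (ncol(data$calls) == 0L) keep <- rep(TRUE, nrow(data$samples))
  if (!is.null(outcome)) {
    if (is.null(traits)) stop("outcome filter requires a trait table")
    if (!outcome %in% names(traits))
      stop(sprintf("outcome column '%s' absent from traits", outcome))
    y <- traits[[outcome]][match(sample_keys(data), trait_keys(traits))]
    keep <- keep & !is.na(y)
  }
  subset_samples(data, keep)
}

#' Re-express every marker's calls as minor-allele counts
#'
#' Markers whose counted-allele frequency exceeds 0.5 have their calls
#' complemented (`g -> 2 - g`) and their counted allele switched; at an
#' exact 0.5 tie the current counted allele (allele2 at load) is kept.
#' Idempotent; preserves the missingness pattern and the MAF.
#'
#' @param data a [genotype_dataset()].
#' @export
recode_minor_allele <- function(data) {
  st <- compute_marker_stats(data)
  flip <- !is.na(st$counted_freq) & st$counted_freq > 0.5
  if (any(flip)) {
    data$calls[, flip] <- 2L - data$calls[, flip, drop = FALSE]
    data$markers$counted_allele2[flip] <- !data$markers$counted_allele2[flip]
  }
  data$markers$referent_is_minor <- TRUE
  data
}

#' Genetic encodings of a minor-allele count
#'
#' * `additive`: g
#' * `dominant`: 1 if g >= 1
#' * `recessive`: 1 if g == 2
#' * `codominant`: two indicator columns (heterozygote, homozygote-minor);
#'   the reference category is the major-allele homozygote.
#'
#' Missing calls propagate as `NA`.
#'
#' @param call integer vector of minor-allele counts in `{0, 1, 2, NA}`.
#' @param encoding encoding name.
#' @param name optional column-name stem for the codominant pair.
#' @return A numeric vector, or a two-column matrix for `codominant`.
#' @export
encode_genotype <- function(call,
                            encoding = c("additive", "dominant", "recessive",
                                         "codominant"),
                            name = "g") {
  encoding <- match.arg(encoding)
  g <- as.numeric(call)
  switch(encoding,
    additive = g,
    dominant = ifelse(is.na(g), NA_real_, as.numeric(g >= 1)),
    recessive = ifelse(is.na(g), NA_real_, as.numeric(g == 2)),
    codominant = {
      het <- ifelse(is.na(g), NA_real_, as.numeric(g == 1))
      hom <- ifelse(is.na(g), NA_real_, as.numeric(g == 2))
      m <- cbind(het, hom)
      colnames(m) <- paste0(name, c("_het", "_hom"))
      m
    })
}

#' Dummy-code a categorical variable
#'
#' A categorical variable of N observed levels generates N-1 indicator
#' columns; the reference level is the first level in sorted order.
#' Missing values propagate.
#'
#' @param column vector (character/factor/numeric treated as labels).
#' @param name column-name stem.
#' @return Matrix with N-1 columns.
#' @export
dummy_code <- function(column, name = "x") {
  x <- as.character(column)
  lev <- sort(unique(x[!is.na(x)]))
  if (length(lev) < 2L)
    stop(sprintf("'%s' has fewer than 2 observed levels (zero variance)", name))
  m <- vapply(lev[-1], function(l) ifelse(is.na(x), NA_real_,
                                          as.numeric(x == l)),
              numeric(length(x)))
  m <- matrix(m, nrow = length(x),
              dimnames = list(NULL, paste0(name, ".", lev[-1])))
  m
}

#' Filter CNV calls on probe support and length
#'
#' Keeps calls with `n_snps >= min_snps` and inclusive length
#' `stop - start + 1 >= min_length` (both thresholds inclusive).
#'
#' @param calls a [cnv_calls()] table.
#' @param min_snps minimum supporting SNP count (default 10).
#' @param min_length minimum length in base pairs (default 1000).
#' @export
filter_cnv_calls <- function(calls, min_snps = 10, min_length = 1000) {
  len <- calls$stop - calls$start + 1L
  keep <- calls$n_snps >= min_snps & len >= min_length
  calls[keep, , drop = FALSE]
}
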