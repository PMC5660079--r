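## Deterministic synthetic-data generators.  Every generator is a pure
## function of its arguments and seed: the global RNG state is saved and
## restored around each call.

#' Evaluate code under a fixed RNG seed, restoring the previous state
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @export
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  code
}

#' Simulate a genotype dataset under Hardy-Weinberg equilibrium
#'
#' Independent markers; per marker, each sample's minor-allele count is a
#' Binomial(2, maf) draw, so the counted allele (allele2) is the minor
#' allele by construction.  Optional uniform missingness.
#'
#' @param n_samples,n_markers dimensions.
#' @param maf minor allele frequency per marker, recycled; in `(0, 0.5]`.
#' @param missing_rate per-call missingness probability.
#' @param seed integer seed (mandatory for reproducibility).
#' @param chrom chromosome label(s), recycled across markers.
#' @param pos_start,pos_step base-pair positions `pos_start + (j-1) *
#'   pos_step` within each chromosome label.
#' @return A [genotype_dataset()].
#' @export
simulate_genotypes <- function(n_samples, n_markers, maf = 0.3,
                               missing_rate = 0, seed = 1, chrom = "1",
                               pos_start = 10000L, pos_step = 1000L) {
  maf <- rep_len(maf, n_markers)
  stopifnot(all(maf > 0), all(maf <= 0.5), missing_rate >= 0, missing_rate < 1)
  with_seed(seed, {
    calls <- vapply(maf, function(q) stats::rbinom(n_samples, 2L, q),
                    integer(n_samples))
    calls <- matrix(as.integer(calls), nrow = n_samples)
    if (missing_rate > 0) {
      miss <- matrix(stats::runif(n_samples * n_markers) < missing_rate,
                     nrow = n_samples)
      calls[miss] <- NA_integer_
    }
    ref_alt <- matrix(c("A", "C", "A", "G", "A", "T", "C", "G", "C", "T",
                        "G", "T"), ncol = 2, byrow = TRUE)
    pick <- sample.int(nrow(ref_alt), n_markers, replace = TRUE)
    markers <- data.frame(
      id = sprintf("snp%05d", seq_len(n_markers)),
      chrom = rep_len(as.character(chrom), n_markers),
      pos = as.integer(pos_start + (seq_len(n_markers) - 1L) * pos_step),
      allele1 = ref_alt[pick, 1], allele2 = ref_alt[pick, 2],
      stringsAsFactors = FALSE)
    samples <- data.frame(
      fid = sprintf("S%05d", seq_len(n_samples)),
      iid = sprintf("S%05d", seq_len(n_samples)),
      sex = rep_len(c("male", "female"), n_samples),
      phenotype = NA_real_, stringsAsFactors = FALSE)
    genotype_dataset(calls, markers, samples)
  })
}

#' Simulate a phenotype from genotypes and an optional exposure
#'
#' Builds the linear predictor
#' `intercept + sum(beta_m * g_m) + beta_exposure * E +
#' beta_interaction * g_int * E` on additive minor-allele counts, then
#' draws `Y = lp + N(0, sigma^2)` (linear) or `Y ~ Bernoulli(plogis(lp))`
#' (logistic).
#'
#' @param genotypes a [genotype_dataset()] (may be `NULL` for pure
#'   exposure models).
#' @param betas named numeric vector of per-marker main effects.
#' @param exposure optional numeric exposure vector (one value per sample).
#' @param beta_exposure exposure main effect.
#' @param interaction_marker marker id entering the product term.
#' @param beta_interaction product-term effect (0 drops the term).
#' @param intercept baseline log-odds / mean.
#' @param family `"logistic"` or `"linear"`.
#' @param sigma residual SD for the linear family.
#' @param seed integer seed.
#' @return Numeric outcome vector (0/1 for logistic).
#' @export
simulate_phenotype <- function(genotypes = NULL, betas = NULL,
                               exposure = NULL, beta_exposure = 0,
                               interaction_marker = NULL,
                               beta_interaction = 0, intercept = 0,
                               family = c("logistic", "linear"), sigma = 1,
                               seed = 1) {
  family <- match.arg(family)
  n <- if (!is.null(genotypes)) nrow(genotypes$calls) else length(exposure)
  lp <- rep(intercept, n)
  if (!is.null(betas) && length(betas)) {
    for (nm in names(betas)) {
      g <- genotypes$calls[, nm]
      lp <- lp + betas[[nm]] * as.numeric(g)
    }
  }
  if (!is.null(exposure)) lp <- lp + beta_exposure * exposure
  if (beta_interaction != 0) {
    stopifnot(!is.null(interaction_marker), !is.null(exposure))
    lp <- lp + beta_interaction *
      as.numeric(genotypes$calls[, interaction_marker]) * exposure
  }
  with_seed(seed, {
    y <- rep(NA_real_, n)
    ok <- !is.na(lp)
    if (family == "logistic")
      y[ok] <- stats::rbinom(sum(ok), 1L, stats::plogis(lp[ok]))
    else y[ok] <- lp[ok] + stats::rnorm(sum(ok), 0, sigma)
    y
  })
}

#' Simulate a CNV call set
#'
#' Per sample, a Poisson number of background calls with log-uniform
#' lengths in `len_range`, uniform placement, and a configurable
#' deletion:duplication ratio.  Optionally, a target region is enriched:
#' each sample carries an extra deletion overlapping the region with
#' probability `enrich_p_case` (cases) or `enrich_p_control` (controls).
#'
#' @param sample_ids character vector of sample ids.
#' @param phenotype optional 0/1 vector aligned with `sample_ids`
#'   (needed only for targeted enrichment).
#' @param mean_calls Poisson mean of background calls per sample.
#' @param chroms chromosome labels used for placement.
#' @param chrom_length length of each chromosome in bp.
#' @param del_prob probability a background call is a deletion.
#' @param len_range base-pair length range (log-uniform; default 1 kb-1 Mb).
#' @param enrich_region optional list/row with `chrom`, `start`, `stop`.
#' @param enrich_p_case,enrich_p_control carrier probabilities for the
#'   targeted deletion.
#' @param seed integer seed.
#' @return A [cnv_calls()] table; byte-identical for identical inputs and
#'   seed.
#' @export
simulate_cnv_calls <- function(sample_ids, phenotype = NULL, mean_calls = 2,
                               chroms = c("1", "2"), chrom_length = 5e7,
                               del_prob = 0.5, len_range = c(1e3, 1e6),
                               enrich_region = NULL, enrich_p_case = 0,
                               enrich_p_control = 0, seed = 1) {
  n <- length(sample_ids)
  with_seed(seed, {
    k <- stats::rpois(n, mean_calls)
    tot <- sum(k)
    rows <- NULL
    if (tot > 0) {
      samp <- rep(sample_ids, k)
      len <- round(exp(stats::runif(tot, log(len_range[1]),
                                    log(len_range[2]))))
      chrom <- sample(chroms, tot, replace = TRUE)
      start <- floor(stats::runif(tot, 1, chrom_length - len)) + 1L
      state <- ifelse(stats::runif(tot) < del_prob, "deletion", "duplication")
      cn <- ifelse(state == "deletion",
                   ifelse(stats::runif(tot) < 0.1, 0L, 1L),
                   ifelse(stats::runif(tot) < 0.1, 4L, 3L))
      n_snps <- pmax(10L, as.integer(round(len / 1000)))
      rows <- data.frame(sample = samp, chrom = chrom,
                         start = as.integer(start),
                         stop = as.integer(start + len - 1L),
                         copy_number = cn, state = state, n_snps = n_snps,
                         stringsAsFactors = FALSE)
    }
    if (!is.null(enrich_region) &&
        (enrich_p_case > 0 || enrich_p_control > 0)) {
      stopifnot(!is.null(phenotype), length(phenotype) == n)
      p_carrier <- ifelse(phenotype == 1L, enrich_p_case, enrich_p_control)
      carrier <- stats::runif(n) < p_carrier
      if (any(carrier)) {
        w <- which(carrier)
        rlen <- enrich_region$stop - enrich_region$start + 1L
        len <- pmax(1000L, as.integer(round(rlen *
                                              stats::runif(length(w), 0.3, 1))))
        start <- enrich_region$start +
          as.integer(floor(stats::runif(length(w), 0, pmax(rlen - len, 1))))
        extra <- data.frame(sample = sample_ids[w],
                            chrom = as.character(enrich_region$chrom),
                            start = start,
                            stop = start + len - 1L,
                            copy_number = 1L, state = "deletion",
                            n_snps = pmax(10L, as.integer(round(len / 1000))),
                            stringsAsFactors = FALSE)
        rows <- rbind(rows, extra)
      }
    }
    if (is.null(rows) || nrow(rows) == 0L) {
      return(cnv_calls(sample = character(0), chrom = character(0),
                       start = integer(0), stop = integer(0),
                       copy_number = integer(0), n_snps = integer(0)))
    }
    cnv_calls(sample = rows$sample, chrom = rows$chrom, start = rows$start,
              stop = rows$stop, copy_number = rows$copy_number,
              n_snps = rows$n_snps)
  })
}
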