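#' Enumerate the models of a study design
#'
#' Builds the ordered model list for one scan:
#' * `main_effect` — one model per marker against a single outcome;
#' * `gxg_pairwise` — every unordered marker pair (m(m-1)/2 models);
#' * `gxg_list` — exactly the pairs named in a model-list file;
#' * `gxe` — each marker crossed with each exposure;
#' * `phewas` — each marker against each phenotype (main-effect model per
#'   pair);
#' * `burden` / `burden_x_e` — burden variables in place of markers.
#'
#' Pair identifiers are `termA×termB` with the pair in lexicographic
#' order, for stable output.
#'
#' @param design_kind one of the kinds above.
#' @param markers character vector of marker ids.
#' @param outcome outcome column name (all designs except `phewas`).
#' @param exposures exposure column names (`gxe`, `burden_x_e`).
#' @param phenotypes phenotype column names (`phewas`).
#' @param model_list_file path to a model-list file: two whitespace-separated
#'   marker ids per line, `#` comments allowed (`gxg_list`).
#' @param burden_vars burden variable names (`burden`, `burden_x_e`).
#' @return A `model_list`: data.frame with `model_id`, `outcome`, `term1`,
#'   `term2`, `interaction`, carrying the design kind as an attribute.
#' @export
enumerate_models <- function(design_kind = c("main_effect", "gxg_pairwise",
                                             "gxg_list", "gxe", "phewas",
                                             "burden", "burden_x_e"),
                             markers = NULL, outcome = NULL, exposures = NULL,
                             phenotypes = NULL, model_list_file = NULL,
                             burden_vars = NULL) {
  design_kind <- match.arg(design_kind)
  x_sep <- "×"
  ml <- switch(design_kind,
    main_effect = {
      stopifnot(!is.null(markers), !is.null(outcome))
      data.frame(model_id = markers, outcome = outcome, term1 = markers,
                 term2 = NA_character_, interaction = FALSE,
                 stringsAsFactors = FALSE)
    },
    gxg_pairwise = {
      stopifnot(!is.null(markers), !is.null(outcome))
      m <- sort(unique(markers))
      if (length(m) < 2L) stop("pairwise design needs >= 2 markers")
      pr <- utils::combn(m, 2L)
      data.frame(model_id = paste0(pr[1, ], x_sep, pr[2, ]),
                 outcome = outcome, term1 = pr[1, ], term2 = pr[2, ],
                 interaction = TRUE, stringsAsFactors = FALSE)
    },
    gxg_list = {
      stopifnot(!is.null(markers), !is.null(outcome),
                !is.null(model_list_file))
      pairs <- read_model_list(model_list_file, known = markers)
      t1 <- pmin(pairs[, 1], pairs[, 2])
      t2 <- pmax(pairs[, 1], pairs[, 2])
      data.frame(model_id = paste0(t1, x_sep, t2), outcome = outcome,
                 term1 = t1, term2 = t2, interaction = TRUE,
                 stringsAsFactors = FALSE)
    },
    gxe = {
      stopifnot(!is.null(markers), !is.null(outcome), !is.null(exposures))
      g <- expand.grid(term1 = markers, term2 = exposures,
                       stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
      data.frame(model_id = paste0(g$term1, x_sep, g$term2),
                 outcome = outcome, term1 = g$term1, term2 = g$term2,
                 interaction = TRUE, stringsAsFactors = FALSE)
    },
    phewas = {
      stopifnot(!is.null(markers), !is.null(phenotypes))
      g <- expand.grid(term1 = markers, outcome = phenotypes,
                       stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
      data.frame(model_id = paste0(g$term1, "~", g$outcome),
                 outcome = g$outcome, term1 = g$term1,
                 term2 = NA_character_, interaction = FALSE,
                 stringsAsFactors = FALSE)
    },
    burden = {
      stopifnot(!is.null(burden_vars), !is.null(outcome))
      data.frame(model_id = burden_vars, outcome = outcome,
                 term1 = burden_vars, term2 = NA_character_,
                 interaction = FALSE, stringsAsFactors = FALSE)
    },
    burden_x_e = {
      stopifnot(!is.null(burden_vars), !is.null(outcome),
                !is.null(exposures))
      g <- expand.grid(term1 = burden_vars, term2 = exposures,
                       stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
      data.frame(model_id = paste0(g$term1, x_sep, g$term2),
                 outcome = outcome, term1 = g$term1, term2 = g$term2,
                 interaction = TRUE, stringsAsFactors = FALSE)
    })
  if (anyDuplicated(ml$model_id)) stop("duplicate model entries")
  structure(ml, design_kind = design_kind,
            class = c("model_list", "data.frame"))
}

read_model_list <- function(path, known = NULL) {
  lines <- readLines(path)
  out <- matrix(character(0), ncol = 2L)
  for (i in seq_along(lines)) {
    l <- sub("#.*$", "", lines[i])
    if (!nzchar(trimws(l))) next
    tk <- strsplit(trimws(l), "[ \t]+")[[1]]
    if (length(tk) != 2L)
      stop(sprintf("model list line %d: expected two marker ids", i))
    if (!is.null(known)) {
      miss <- setdiff(tk, known)
      if (length(miss))
        stop(sprintf("model list line %d: unknown marker id '%s'",
                     i, miss[1]))
    }
    out <- rbind(out, tk)
  }
  if (nrow(out) == 0L) stop("model list is empty")
  unname(out)
}

## ---------------------------------------------------------------------------
## Multiple-testing corrections

#' Bonferroni correction
#'
#' @param p uncorrected p-value(s) in `[0, 1]`.
#' @param m number of tests (>= 1).
#' @return `min(1, p * m)`, vectorized.
#' @export
bonferroni <- function(p, m) {
  stopifnot(m >= 1, all(p >= 0 & p <= 1, na.rm = TRUE))
  pmin(1, p * m)
}

#' Uncorrected significance threshold implied by Bonferroni
#'
#' @param alpha family-wise significance level.
#' @param m number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(m >= 1)
  alpha / m
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted values (monotone in rank, capped at 1), computed by
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p_vector p-values in `[0, 1]`.
#' @export
fdr_bh <- function(p_vector) {
  if (length(p_vector) == 0L) return(numeric(0))
  stopifnot(all(p_vector >= 0 & p_vector <= 1, na.rm = TRUE))
  stats::p.adjust(p_vector, method = "BH")
}

## ---------------------------------------------------------------------------
## Scan execution

align_trait_columns <- function(traits, keys, cols) {
  idx <- match(keys, trait_keys(traits))
  out <- lapply(cols, function(nm) {
    if (!nm %in% names(traits))
      stop(sprintf("column '%s' absent from traits", nm))
    traits[[nm]][idx]
  })
  names(out) <- cols
  out
}

build_covariate_design <- function(traits, keys, covariates) {
  if (length(covariates) == 0L)
    return(matrix(numeric(0), nrow = length(keys), ncol = 0L))
  types <- trait_types(traits)
  vals <- align_trait_columns(traits, keys, covariates)
  mats <- lapply(covariates, function(nm) {
    if (!is.null(types) && !is.na(types[nm]) && types[nm] == "categorical")
      dummy_code(vals[[nm]], name = nm)
    else matrix(as.numeric(vals[[nm]]), ncol = 1,
                dimnames = list(NULL, nm))
  })
  do.call(cbind, mats)
}

encode_term_columns <- function(term, genotypes, traits, keys, encoding) {
  if (!is.null(genotypes) && term %in% genotypes$markers$id) {
    g <- genotypes$calls[match(keys, sample_keys(genotypes)),
                         term]
    enc <- encode_genotype(g, encoding, name = term)
    if (is.matrix(enc)) enc
    else matrix(enc, ncol = 1, dimnames = list(NULL, term))
  } else {
    v <- align_trait_columns(traits, keys, term)[[1]]
    matrix(as.numeric(v), ncol = 1, dimnames = list(NULL, term))
  }
}

empty_scan_row <- function(entry, family, encoding) {
  data.frame(model_id = entry$model_id, outcome = entry$outcome,
             term1 = entry$term1, term2 = entry$term2,
             encoding = encoding, family = family,
             n_used = NA_integer_, n_cases = NA_integer_,
             n_controls = NA_integer_,
             term1_beta = NA_real_, term1_se = NA_real_, term1_p = NA_real_,
             term2_beta = NA_real_, term2_se = NA_real_, term2_p = NA_real_,
             interaction_beta = NA_real_, interaction_se = NA_real_,
             interaction_p = NA_real_,
             converged = FALSE, note = NA_character_,
             lrt_stat = NA_real_, lrt_df = NA_integer_, lrt_p = NA_real_,
             p = NA_real_, stringsAsFactors = FALSE)
}

#' Run a scan over an enumerated model list
#'
#' Each model is fitted with the package's regression engine on the
#' complete cases of its own design (outcome, encoded terms, interaction
#' product, covariates).  Interaction designs additionally fit the reduced
#' model on the same complete-case set and report the full-vs-reduced
#' likelihood-ratio test.  Per-model failures are recorded in the row
#' (`converged = FALSE`, `note`) and never abort the scan.  Multiple-testing
#' corrections are applied across the scan's primary p-vector, with the
#' number of tests m equal to the number of converged fits.
#'
#' @param models a `model_list` from [enumerate_models()].
#' @param genotypes optional [genotype_dataset()] (not needed for pure
#'   burden/trait designs).
#' @param traits a `trait_table` holding outcomes, exposures, burden
#'   variables, and covariates.
#' @param covariates covariate column names; categorical covariates of N
#'   levels contribute N-1 dummy columns.
#' @param encoding genetic encoding for marker terms.
#' @param family `"auto"` (per-outcome detection, the PheWAS behaviour),
#'   `"logistic"`, `"linear"`, or `"firth"`.
#' @param corrections subset of `c("bonferroni", "fdr")`.
#' @return A `scan_result` data.frame, one row per model in enumeration
#'   order, with an `m_tests` attribute.
#' @export
run_scan <- function(models, genotypes = NULL, traits,
                     covariates = character(),
                     encoding = c("additive", "dominant", "recessive",
                                  "codominant"),
                     family = c("auto", "logistic", "linear", "firth"),
                     corrections = c("bonferroni", "fdr")) {
  encoding <- match.arg(encoding)
  family <- match.arg(family)
  stopifnot(inherits(models, "model_list"), inherits(traits, "trait_table"))
  keys <- if (!is.null(genotypes))
    intersect(sample_keys(genotypes), trait_keys(traits))
  else trait_keys(traits)
  if (length(keys) == 0L) stop("no samples shared between genotypes and traits")
  covX <- build_covariate_design(traits, keys, covariates)
  rows <- vector("list", nrow(models))
  for (i in seq_len(nrow(models))) {
    entry <- models[i, ]
    row <- empty_scan_row(entry, family, encoding)
    res <- tryCatch({
      yraw <- align_trait_columns(traits, keys, entry$outcome)[[1]]
      fam <- family
      if (family == "auto") {
        det <- auto_detect_family(yraw)
        fam <- det$family
        y <- det$outcome
      } else if (family %in% c("logistic", "firth")) {
        det <- auto_detect_family(yraw)
        if (det$family != "logistic")
          stop("logistic regression requires a binary outcome")
        y <- det$outcome
      } else y <- as.numeric(yraw)
      X1 <- encode_term_columns(entry$term1, genotypes, traits, keys, encoding)
      X2 <- if (!is.na(entry$term2))
        encode_term_columns(entry$term2, genotypes, traits, keys, encoding)
      else NULL
      Xint <- NULL
      if (isTRUE(entry$interaction)) {
        Xint <- do.call(cbind, lapply(seq_len(ncol(X1)), function(a)
          vapply(seq_len(ncol(if (is.null(X2)) X1 else X2)), function(b)
            X1[, a] * (if (is.null(X2)) X1 else X2)[, b],
            numeric(nrow(X1)))))
        Xint <- matrix(Xint, nrow = nrow(X1))
        colnames(Xint) <- paste0("int_",
          as.vector(outer(colnames(X1),
                          colnames(if (is.null(X2)) X1 else X2),
                          paste, sep = ":")))
      }
      Xfull <- cbind(X1, X2, Xint, covX)
      cc <- stats::complete.cases(cbind(y, Xfull))
      yc <- y[cc]
      row$n_used <- sum(cc)
      if (fam %in% c("logistic", "firth")) {
        row$n_cases <- sum(yc == 1)
        row$n_controls <- sum(yc == 0)
      }
      row$family <- fam
      full <- fit_glm(yc, Xfull[cc, , drop = FALSE], fam)
      grab <- function(fit, cols) {
        cf <- fit$coefficients
        j <- match(cols, cf$term)
        j <- j[!is.na(j)][1]
        if (is.na(j)) c(NA_real_, NA_real_, NA_real_)
        else c(cf$estimate[j], cf$se[j], cf$p[j])
      }
      t1 <- grab(full, colnames(X1))
      row$term1_beta <- t1[1]; row$term1_se <- t1[2]; row$term1_p <- t1[3]
      if (!is.null(X2)) {
        t2 <- grab(full, colnames(X2))
        row$term2_beta <- t2[1]; row$term2_se <- t2[2]; row$term2_p <- t2[3]
      }
      row$converged <- full$converged
      if (isTRUE(entry$interaction)) {
        ti <- grab(full, colnames(Xint))
        row$interaction_beta <- ti[1]; row$interaction_se <- ti[2]
        row$interaction_p <- ti[3]
        Xred <- cbind(X1, X2, covX)
        reduced <- fit_glm(yc, Xred[cc, , drop = FALSE], fam)
        lrt <- likelihood_ratio_test(full, reduced)
        row$lrt_stat <- lrt$stat
        row$lrt_df <- lrt$df
        row$lrt_p <- lrt$p
        row$p <- lrt$p
        row$converged <- full$converged && reduced$converged
      } else {
        row$p <- t1[3]
      }
      row
    }, error = function(e) {
      row$note <- conditionMessage(e)
      row$converged <- FALSE
      row
    })
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  usable <- out$converged & !is.na(out$p)
  m <- sum(usable)
  if ("bonferroni" %in% corrections)
    out$bonferroni_p <- ifelse(usable, bonferroni(out$p, max(m, 1L)), NA_real_)
  if ("fdr" %in% corrections) {
    out$fdr_p <- NA_real_
    if (m > 0) out$fdr_p[usable] <- fdr_bh(out$p[usable])
  }
  structure(out, m_tests = m, class = c("scan_result", "data.frame"))
}
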