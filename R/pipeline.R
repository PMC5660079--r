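## Pipeline-of-steps command interface.  An analysis is a strictly ordered
## sequence of verbs operating on one shared state (genotypes, traits,
## results), mirroring how the tool is driven from a shell.

pipeline_verbs <- c("load-data", "load-trait", "recode-alleles",
                    "filter-maf", "filter-marker-call", "filter-sample-call",
                    "filter-trait-missing", "logistic", "linear",
                    "regress-auto", "concordance", "output-data")

pipeline_flags <- c("interaction", "interactions", "pairwise", "models",
                    "model", "use-traits", "use-trait", "phewas",
                    "covariates", "correction", "auto", "no-fid",
                    "dummy-samples", "exclude-markers", "maf", "call-rate",
                    "permutations")

## flags that may consume a following value token
value_flags <- c("covariates", "correction", "models", "model", "maf",
                 "call-rate", "permutations")

#' Parse a pipeline command line into steps
#'
#' Tokens are verbs followed by their flags.  Flags are written `--flag`,
#' `--flag=value`, or `--flag value` (for value-taking flags); a run of two
#' or more leading dashes is normalised to `--`, so the occasional
#' `---covariates` typo parses.  Unknown verbs and unknown flags are
#' errors that list the valid choices.
#'
#' @param tokens character vector of tokens, or a single string which is
#'   split on whitespace.
#' @return A `pipeline` object: list of steps, each
#'   `list(verb = ..., options = named list)`.
#' @export
parse_pipeline <- function(tokens) {
  if (length(tokens) == 1L && grepl("\\s", tokens))
    tokens <- strsplit(trimws(tokens), "\\s+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  steps <- list()
  cur <- NULL
  i <- 1L
  while (i <= length(tokens)) {
    tk <- tokens[i]
    if (grepl("^-", tk)) {
      if (is.null(cur))
        stop("flag before any step verb: ", tk)
      flag <- sub("^-+", "", tk)
      val <- TRUE
      if (grepl("=", flag)) {
        val <- sub("^[^=]*=", "", flag)
        flag <- sub("=.*$", "", flag)
      }
      if (!flag %in% pipeline_flags)
        stop(sprintf("unknown flag '--%s'; valid flags: %s", flag,
                     paste0("--", pipeline_flags, collapse = ", ")))
      if (isTRUE(val) && flag %in% value_flags && i < length(tokens) &&
          !grepl("^-", tokens[i + 1L]) &&
          !tokens[i + 1L] %in% pipeline_verbs) {
        val <- tokens[i + 1L]
        i <- i + 1L
      }
      cur$options[[flag]] <- val
    } else {
      if (!tk %in% pipeline_verbs)
        stop(sprintf("unknown step verb '%s'; valid verbs: %s", tk,
                     paste(pipeline_verbs, collapse = ", ")))
      if (!is.null(cur)) steps[[length(steps) + 1L]] <- cur
      cur <- list(verb = tk, options = list())
    }
    i <- i + 1L
  }
  if (!is.null(cur)) steps[[length(steps) + 1L]] <- cur
  if (length(steps) == 0L) stop("empty pipeline")
  structure(steps, class = "pipeline")
}

opt_flag <- function(step, ...) {
  any(vapply(c(...), function(f) isTRUE(step$options[[f]]) ||
               is.character(step$options[[f]]), logical(1)))
}

opt_value <- function(step, flag, default = NULL) {
  v <- step$options[[flag]]
  if (is.character(v)) v else default
}

split_commas <- function(x) {
  if (is.null(x)) return(NULL)
  trimws(strsplit(x, ",")[[1]])
}

#' Execute a parsed pipeline
#'
#' Steps run strictly in order against one shared state.  File paths and
#' analysis parameters that the shell command shapes leave open (which
#' files, which outcome, which covariates) are supplied through `bindings`:
#'
#' * `data`: genotype input — list of paths plus `dialect`, or a
#'   ready [genotype_dataset()]
#' * `trait`: trait-table path or a ready `trait_table`
#' * `outcome`: outcome column name
#' * `covariates`: character vector (a `--covariates a,b,c` flag value
#'   overrides it)
#' * `exposures`: exposure column names for `--use-traits`
#' * `phenotypes`: phenotype column names for `--phewas` (default: every
#'   trait variable except outcome, covariates and exposures)
#' * `terms`: trait columns used as predictors under `--exclude-markers`
#'   (e.g. CNV burden variables)
#' * `models`: model-list file for `--models`
#' * `compare`: second dataset for `concordance`
#' * `out`: results file path; `out_prefix`: prefix for `output-data`
#' * `missing_code`: trait missing sentinel (default `"-9"`)
#'
#' @param steps a `pipeline` from [parse_pipeline()], or a command string.
#' @param bindings named list, see above.
#' @return List with `results` (last scan's `scan_result`), `all_results`,
#'   `genotypes`, `traits`, `log` (one line per step).
#' @export
execute_pipeline <- function(steps, bindings = list()) {
  if (is.character(steps)) steps <- parse_pipeline(steps)
  stopifnot(inherits(steps, "pipeline"))
  st <- new.env(parent = emptyenv())
  st$genotypes <- NULL
  st$traits <- NULL
  st$results <- NULL
  st$all_results <- list()
  st$log <- character(0)
  note <- function(fmt, ...)
    st$log <- c(st$log, sprintf(fmt, ...))
  need_data <- function(verb) {
    if (is.null(st$genotypes))
      stop(sprintf("step '%s': no data loaded (run load-data first)", verb))
  }
  for (step in steps) {
    verb <- step$verb
    switch(verb,
      "load-data" = {
        d <- bindings[["data"]]
        if (is.null(d)) stop("load-data: no 'data' binding supplied")
        st$genotypes <- if (inherits(d, "genotype_dataset")) d
          else read_genotypes(d[setdiff(names(d), "dialect")],
                              dialect = d$dialect)
        note("load-data: %d samples x %d markers",
             nrow(st$genotypes$calls), ncol(st$genotypes$calls))
      },
      "load-trait" = {
        tr <- bindings[["trait"]]
        if (is.null(tr)) stop("load-trait: no 'trait' binding supplied")
        st$traits <- if (inherits(tr, "trait_table")) tr
          else read_trait_table(tr,
                 has_fid = !opt_flag(step, "no-fid"),
                 dummy_samples = opt_flag(step, "dummy-samples"),
                 missing_code = bindings[["missing_code"]] %||% "-9")
        note("load-trait: %d samples, %d variables",
             nrow(st$traits), length(trait_types(st$traits)))
      },
      "recode-alleles" = {
        need_data(verb)
        if (!opt_flag(step, "auto"))
          stop("recode-alleles: only --auto recoding is supported")
        st$genotypes <- recode_minor_allele(st$genotypes)
        note("recode-alleles: referent set to minor allele")
      },
      "filter-maf" = {
        need_data(verb)
        thr <- as.numeric(opt_value(step, "maf",
                                    bindings[["maf"]] %||% 0.05))
        before <- ncol(st$genotypes$calls)
        st$genotypes <- filter_markers(st$genotypes, maf_min = thr,
                                       call_rate_min = 0)
        note("filter-maf %.4g: %d -> %d markers", thr, before,
             ncol(st$genotypes$calls))
      },
      "filter-marker-call" = {
        need_data(verb)
        thr <- as.numeric(opt_value(step, "call-rate",
                                    bindings[["marker_call_rate"]] %||% 0.99))
        before <- ncol(st$genotypes$calls)
        st$genotypes <- filter_markers(st$genotypes, maf_min = 0,
                                       call_rate_min = thr)
        note("filter-marker-call %.4g: %d -> %d markers", thr, before,
             ncol(st$genotypes$calls))
      },
      "filter-sample-call" = {
        need_data(verb)
        thr <- as.numeric(opt_value(step, "call-rate",
                                    bindings[["sample_call_rate"]] %||% 0.99))
        before <- nrow(st$genotypes$calls)
        st$genotypes <- filter_samples(st$genotypes, call_rate_min = thr)
        note("filter-sample-call %.4g: %d -> %d samples", thr, before,
             nrow(st$genotypes$calls))
      },
      "filter-trait-missing" = {
        need_data(verb)
        if (is.null(st$traits)) stop("filter-trait-missing: no traits loaded")
        outcome <- bindings[["outcome"]]
        if (is.null(outcome)) stop("filter-trait-missing: no 'outcome' binding")
        before <- nrow(st$genotypes$calls)
        st$genotypes <- filter_samples(st$genotypes, call_rate_min = 0,
                                       traits = st$traits, outcome = outcome)
        note("filter-trait-missing '%s': %d -> %d samples", outcome, before,
             nrow(st$genotypes$calls))
      },
      "logistic" = ,
      "linear" = ,
      "regress-auto" = {
        if (is.null(st$traits))
          stop(sprintf("step '%s': no traits loaded (run load-trait first)",
                       verb))
        ## trait-only models: explicit --exclude-markers, or no genotype
        ## data loaded at all (burden variables live in the trait table)
        exclude_markers <- opt_flag(step, "exclude-markers") ||
          (is.null(st$genotypes) && !is.null(bindings[["terms"]]))
        if (!exclude_markers) need_data(verb)
        family <- switch(verb, logistic = "logistic", linear = "linear",
                         "regress-auto" = "auto")
        covariates <- split_commas(opt_value(step, "covariates")) %||%
          bindings[["covariates"]] %||% character(0)
        corr_raw <- split_commas(opt_value(step, "correction")) %||%
          bindings[["correction"]] %||% c("bonferroni", "fdr")
        corrections <- intersect(corr_raw, c("bonferroni", "fdr"))
        interaction <- opt_flag(step, "interaction", "interactions")
        pairwise <- opt_flag(step, "pairwise")
        use_traits <- opt_flag(step, "use-traits", "use-trait")
        phewas <- opt_flag(step, "phewas")
        model_file <- opt_value(step, "models",
                                opt_value(step, "model", bindings[["models"]]))
        outcome <- bindings[["outcome"]]
        vars <- names(trait_types(st$traits))
        models <-
          if (exclude_markers) {
            terms <- bindings[["terms"]]
            if (is.null(terms))
              stop("--exclude-markers requires a 'terms' binding")
            if (interaction) {
              exposures <- bindings[["exposures"]]
              if (is.null(exposures))
                stop("burden-x-environment design requires 'exposures'")
              enumerate_models("burden_x_e", burden_vars = terms,
                               outcome = outcome, exposures = exposures)
            } else
              enumerate_models("burden", burden_vars = terms,
                               outcome = outcome)
          } else if (phewas) {
            phenos <- bindings[["phenotypes"]] %||%
              setdiff(vars, c(outcome, covariates, bindings[["exposures"]]))
            enumerate_models("phewas", markers = st$genotypes$markers$id,
                             phenotypes = phenos)
          } else if (interaction && pairwise) {
            enumerate_models("gxg_pairwise",
                             markers = st$genotypes$markers$id,
                             outcome = outcome)
          } else if (interaction && !is.null(model_file) &&
                     !isTRUE(model_file)) {
            enumerate_models("gxg_list", markers = st$genotypes$markers$id,
                             outcome = outcome,
                             model_list_file = model_file)
          } else if (interaction && use_traits) {
            exposures <- bindings[["exposures"]]
            if (is.null(exposures))
              stop("--use-traits interaction requires an 'exposures' binding")
            enumerate_models("gxe", markers = st$genotypes$markers$id,
                             outcome = outcome, exposures = exposures)
          } else {
            enumerate_models("main_effect",
                             markers = st$genotypes$markers$id,
                             outcome = outcome)
          }
        res <- run_scan(models,
                        genotypes = if (exclude_markers) NULL
                          else st$genotypes,
                        traits = st$traits, covariates = covariates,
                        family = family, corrections = corrections)
        st$results <- res
        st$all_results[[length(st$all_results) + 1L]] <- res
        nc <- sum(!res$converged)
        note("%s: %d model(s) fitted, %d non-converged", verb, nrow(res), nc)
        if (nc > 0) note("warning: %d model(s) did not converge", nc)
        if (!is.null(bindings[["out"]])) {
          write_results(res, bindings[["out"]])
          note("results written to %s", bindings[["out"]])
        }
      },
      "concordance" = {
        need_data(verb)
        cmp <- bindings[["compare"]]
        if (is.null(cmp)) stop("concordance: no 'compare' binding supplied")
        other <- if (inherits(cmp, "genotype_dataset")) cmp
          else read_genotypes(cmp[setdiff(names(cmp), "dialect")],
                              dialect = cmp$dialect)
        rep <- check_concordance(st$genotypes, other)
        st$results <- rep
        note("concordance: %d discordant call(s) over %d sample(s)",
             nrow(rep$detail), nrow(rep$per_sample))
      },
      "output-data" = {
        need_data(verb)
        pfx <- bindings[["out_prefix"]]
        if (is.null(pfx)) stop("output-data: no 'out_prefix' binding supplied")
        write_genotypes(st$genotypes, pfx, dialect = "ped_map")
        note("output-data: PED/MAP written to %s.*", pfx)
      },
      stop("unhandled verb: ", verb))
  }
  list(results = st$results, all_results = st$all_results,
       genotypes = st$genotypes, traits = st$traits, log = st$log)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
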