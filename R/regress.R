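## The statistical engine: least squares, IRLS logistic, and Firth-penalized
## logistic, written directly on QR decompositions so behaviour under
## separation and non-convergence is explicit and reportable.

new_fit_result <- function(coefficients, family, log_likelihood, n_used,
                           df_model, converged, separation_detected = FALSE) {
  structure(list(coefficients = coefficients, family = family,
                 log_likelihood = log_likelihood, n_used = n_used,
                 df_model = df_model, converged = converged,
                 separation_detected = separation_detected),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit: n = %d, logLik = %.4f, converged = %s%s\n",
              x$family, x$n_used, x$log_likelihood, x$converged,
              if (x$separation_detected) " (separation detected)" else ""))
  print(x$coefficients, digits = 4)
  invisible(x)
}

check_design <- function(y, X) {
  stopifnot(is.matrix(X), length(y) == nrow(X))
  if (anyNA(y) || anyNA(X))
    stop("design contains missing values; complete-case rows required")
  v <- apply(X, 2L, stats::var)
  nz <- names(v)[v == 0 & colnames(X) != "(Intercept)"]
  if (length(nz))
    stop(sprintf("degenerate design: zero-variance column(s) %s",
                 paste(nz, collapse = ", ")))
  if (nrow(X) < ncol(X) + 1L)
    stop("fewer complete-case rows than parameters + 1")
  if (qr(X)$rank < ncol(X)) stop("degenerate design: rank-deficient")
  invisible(TRUE)
}

add_intercept <- function(X) {
  if ("(Intercept)" %in% colnames(X)) return(X)
  cbind(`(Intercept)` = 1, X)
}

fit_linear <- function(y, X) {
  n <- nrow(X); p <- ncol(X)
  qx <- qr(X)
  beta <- qr.coef(qx, y)
  res <- y - X %*% beta
  rss <- sum(res^2)
  df <- n - p
  sigma2 <- rss / df
  xtxinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(pmax(diag(xtxinv) * sigma2, 0))
  tt <- beta / se
  pv <- 2 * stats::pt(-abs(tt), df)
  ## exact fits: se = 0 makes t undefined; report p = NA there
  pv[se == 0] <- NA
  ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
  coefs <- data.frame(term = colnames(X), estimate = as.numeric(beta),
                      se = se, stat = as.numeric(tt), p = as.numeric(pv),
                      stringsAsFactors = FALSE, row.names = NULL)
  new_fit_result(coefs, "linear", ll, n, p, converged = TRUE)
}

fit_logistic_irls <- function(y, X, max_iter = 50L, tol = 1e-8,
                              firth = FALSE) {
  n <- nrow(X); p <- ncol(X)
  beta <- numeric(p)
  dev_old <- Inf
  pll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-12)
    info <- crossprod(X * w, X)
    infoinv <- tryCatch(chol2inv(chol(info)),
                        error = function(e) solve(info))
    if (firth) {
      Xs <- X * sqrt(w)
      h <- rowSums((Xs %*% infoinv) * Xs)
      score <- crossprod(X, y - mu + h * (0.5 - mu))
    } else {
      score <- crossprod(X, y - mu)
    }
    delta <- drop(infoinv %*% score)
    ## step-halving to keep the (penalized) likelihood monotone
    obj <- function(b) {
      m <- stats::plogis(drop(X %*% b))
      m <- pmin(pmax(m, 1e-15), 1 - 1e-15)
      ll <- sum(y * log(m) + (1 - y) * log(1 - m))
      if (firth) {
        ww <- pmax(m * (1 - m), 1e-12)
        ll <- ll + 0.5 * determinant(crossprod(X * ww, X))$modulus
      }
      ll
    }
    step <- 1
    for (k in 1:12) {
      if (obj(beta + step * delta) >= obj(beta) - 1e-12) break
      step <- step / 2
    }
    beta <- beta + step * delta
    pll <- obj(beta)
    mu2 <- stats::plogis(drop(X %*% beta))
    mu2c <- pmin(pmax(mu2, 1e-15), 1 - 1e-15)
    dev <- -2 * sum(y * log(mu2c) + (1 - y) * log(1 - mu2c))
    ## a deviance plateau at ~0 means a perfectly separating fit, not
    ## convergence: keep iterating so the boundary becomes detectable
    plateau <- abs(dev - dev_old) < tol && !(dev < 1e-6 && !firth)
    if (plateau || (firth && abs(pll - pll_old) < tol)) {
      converged <- TRUE
      break
    }
    dev_old <- dev
    pll_old <- pll
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  separated <- any(mu < 1e-10 | mu > 1 - 1e-10)
  w <- pmax(mu * (1 - mu), 1e-12)
  info <- crossprod(X * w, X)
  infoinv <- tryCatch(chol2inv(chol(info)), error = function(e) solve(info))
  se <- sqrt(pmax(diag(infoinv), 0))
  z <- beta / se
  pv <- 2 * stats::pnorm(-abs(z))
  muc <- pmin(pmax(mu, 1e-15), 1 - 1e-15)
  ll <- sum(y * log(muc) + (1 - y) * log(1 - muc))
  if (firth)
    ll <- ll + 0.5 * as.numeric(determinant(info)$modulus)
  sep_flag <- FALSE
  if (!firth && separated) {
    ## plain logistic under (quasi-)separation: estimates are reported but
    ## Wald inference is meaningless; flag and withhold p-values
    sep_flag <- TRUE
    converged <- FALSE
    pv[] <- NA_real_
  }
  coefs <- data.frame(term = colnames(X), estimate = beta, se = se,
                      stat = z, p = pv, odds_ratio = exp(beta),
                      stringsAsFactors = FALSE, row.names = NULL)
  new_fit_result(coefs, if (firth) "firth" else "logistic",
                 ll, n, p, converged = converged,
                 separation_detected = sep_flag)
}

#' Fit a regression model
#'
#' The package's own fitting engine.  `linear` is closed-form least squares
#' with t-test Wald p-values; `logistic` is iteratively reweighted least
#' squares run to a deviance tolerance of 1e-8 (at most 50 iterations);
#' `firth` maximises the Jeffreys-prior penalized likelihood by the modified
#' score, giving finite estimates under separation.  A plain logistic fit
#' whose fitted probabilities reach within 1e-10 of 0 or 1 is flagged
#' `separation_detected` with `NA` p-values; it does not fall back to Firth
#' automatically.  For Firth fits `log_likelihood` is the penalized
#' log-likelihood, so a likelihood-ratio test between two Firth fits is a
#' penalized LRT.
#'
#' @param y outcome vector; must be coded 0/1 for `logistic`/`firth`.
#' @param X numeric design matrix (terms of interest first, then
#'   covariates); an intercept column is added unless already present.
#'   Rows must be complete cases.
#' @param family `"linear"`, `"logistic"`, or `"firth"`.
#' @return A `fit_result`: per-term `coefficients`
#'   (estimate/se/stat/p, plus odds ratios for binomial families),
#'   `log_likelihood`, `n_used`, `df_model`, `converged`,
#'   `separation_detected`.
#' @export
fit_glm <- function(y, X, family = c("linear", "logistic", "firth")) {
  family <- match.arg(family)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1,
                                   dimnames = list(NULL, "x"))
  X <- as.matrix(X)
  if (ncol(X) > 0L && is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  X <- add_intercept(X)
  y <- as.numeric(y)
  check_design(y, X)
  if (family %in% c("logistic", "firth")) {
    if (!all(y %in% c(0, 1)))
      stop("logistic outcome must be binary 0/1 (see auto_detect_family)")
    fit_logistic_irls(y, X, firth = family == "firth")
  } else {
    fit_linear(y, X)
  }
}

#' Likelihood-ratio test between nested fits
#'
#' `stat = 2 * (logLik_full - logLik_reduced)`, clamped at zero;
#' `df` is the difference in estimated parameters; `p` is the upper-tail
#' chi-square probability.  Both fits must be of the same family and must
#' have been fitted on the same complete-case sample set (a silent N
#' mismatch is the classic interaction-test bug, so it is an error here).
#'
#' @param full,reduced `fit_result` objects from [fit_glm()].
#' @return An `lrt_result` list: `stat`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  if (full$family != reduced$family)
    stop("LRT requires fits of the same family")
  if (full$n_used != reduced$n_used)
    stop(sprintf("LRT sample sets differ (full n=%d, reduced n=%d); refit on common complete cases",
                 full$n_used, reduced$n_used))
  df <- full$df_model - reduced$df_model
  if (df < 0L) stop("full model must have at least as many parameters as reduced")
  stat <- max(0, 2 * (full$log_likelihood - reduced$log_likelihood))
  ## df 0 only when the models coincide: no evidence, p = 1
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(stat = stat, df = df, p = p), class = "lrt_result")
}

#' Choose logistic vs linear from the outcome's values
#'
#' Exactly two distinct non-missing values selects logistic regression, with
#' the lower value mapped to 0 and the higher to 1; more than two numeric
#' values selects linear regression.  A constant outcome is an error, as is
#' a non-numeric outcome with more than two levels.
#'
#' @param outcome vector of outcome values (may contain `NA`).
#' @return List with `family` (`"logistic"` or `"linear"`) and `outcome`,
#'   the (possibly remapped) numeric outcome vector.
#' @export
auto_detect_family <- function(outcome) {
  obs <- outcome[!is.na(outcome)]
  u <- unique(obs)
  if (length(u) < 2L) stop("constant outcome: cannot choose a family")
  if (length(u) == 2L) {
    lev <- sort(u)
    y <- ifelse(is.na(outcome), NA_real_,
                as.numeric(as.character(outcome) == as.character(lev[2])))
    return(list(family = "logistic", outcome = y))
  }
  num <- suppressWarnings(as.numeric(outcome))
  if (any(!is.na(outcome) & is.na(num)))
    stop("categorical outcome with >2 levels is not supported")
  list(family = "linear", outcome = num)
}

#' Permutation p-value for a term of interest
#'
#' The outcome vector is permuted uniformly `n_perm` times against the
#' intact design (covariates stay attached to their samples) and the model
#' refitted each time.  The returned value is the proportion of
#' permutations whose p-value for the tested term is strictly smaller (more
#' significant) than the unpermuted model's, so 0 is attainable.  Permuted
#' fits that fail or do not converge count as p = 1 (they cannot beat the
#' observed fit).
#'
#' @param y outcome vector (complete cases).
#' @param X design matrix (complete cases), terms of interest included.
#' @param family passed to [fit_glm()].
#' @param term name (or index into `colnames(X)`) of the tested term;
#'   default the first column of `X`.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed; the permutation order is deterministic given
#'   the seed.
#' @return The permutation p-value, a fraction in `[0, 1]`.
#' @export
permutation_pvalue <- function(y, X, family = "logistic", term = NULL,
                               n_perm = 100, seed = 1) {
  stopifnot(n_perm >= 1)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1, dimnames = list(NULL, "x"))
  if (is.null(term)) term <- colnames(X)[1]
  if (is.numeric(term)) term <- colnames(X)[term]
  term_p <- function(fit) {
    p <- fit$coefficients$p[fit$coefficients$term == term]
    if (length(p) != 1L || is.na(p)) NA_real_ else p
  }
  obs <- term_p(fit_glm(y, X, family))
  if (is.na(obs)) stop("observed fit has no p-value for the tested term")
  n_smaller <- 0L
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      yp <- sample(y)
      pp <- tryCatch({
        f <- fit_glm(yp, X, family)
        if (!f$converged) 1 else term_p(f)
      }, error = function(e) 1)
      if (!is.na(pp) && pp < obs) n_smaller <- n_smaller + 1L
    }
  })
  n_smaller / n_perm
}
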