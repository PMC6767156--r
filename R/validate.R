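# Marker validation battery: Pearson correlation with RVEF, Steiger
# tests for dependent correlations sharing RVEF, covariate-adjusted
# bootstrapped regression with last-entry variance partitioning,
# model-type comparison, leave-one-out prediction, and Kruskal-Wallis
# comparison of absolute prediction errors.

#' Pearson correlation with RVEF
#'
#' @param x,y numeric vectors, n >= 3, non-constant.
#' @return List with `r`, `p` (two-sided, t transform), `n`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Steiger test for two dependent correlations sharing one variable
#'
#' Tests `H0: cor(j,k) = cor(j,h)` where variable `j` (here RVEF) is
#' shared, given the correlation `r_kh` between the two competing
#' markers. Uses the recommended variant with the back-transformed mean
#' correlation in the covariance term:
#' `z = (z_jk - z_jh) * sqrt((n - 3) / (2 * (1 - s)))` with
#' `s = psi / (1 - rbar^2)^2`,
#' `psi = r_kh * (1 - 2 rbar^2) - rbar^2 * (1 - 2 rbar^2 - r_kh^2) / 2`,
#' and `rbar = tanh((z_jk + z_jh) / 2)`.
#'
#' @param r_jk,r_jh the two correlations with the shared variable.
#' @param r_kh correlation between the two non-shared variables.
#' @param n sample size (> 3).
#' @return List with `z` and two-sided normal `p`.
#' @export
steiger_test <- function(r_jk, r_jh, r_kh, n) {
  stopifnot(n > 3)
  if (any(abs(c(r_jk, r_jh, r_kh)) >= 1)) stop("correlations must be in (-1, 1)")
  z1 <- atanh(r_jk); z2 <- atanh(r_jh)
  rbar <- tanh((z1 + z2) / 2)
  psi <- r_kh * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_kh^2)
  s <- psi / (1 - rbar^2)^2
  z <- (z1 - z2) * sqrt((n - 3) / (2 * (1 - s)))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

# standardised RVEF-on-marker model shared by the validation routines;
# returns the design (marker first), response, and column groups
marker_design <- function(marker, covariates, rvef) {
  D <- build_design(covariates)
  X <- cbind(`(Intercept)` = 1, marker = as.numeric(scale(marker)), D)
  list(X = X, y = as.numeric(scale(rvef)),
       groups = c("marker", attr(D, "groups")))
}

ols_r2 <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Covariate-adjusted regression of RVEF on a marker
#'
#' OLS of standardised RVEF on the standardised marker plus age, sex,
#' race (dummy-coded) and BSA, with subject-resampling bootstrap
#' percentile CIs for the coefficients, and a variance partition: each
#' variable's fraction is its last-entry incremental R-squared (squared
#' semi-partial), i.e. full-model R^2 minus the R^2 without that
#' variable's columns.
#'
#' @param marker numeric marker values.
#' @param covariates data.frame (age, sex, race, bsa).
#' @param rvef numeric (%).
#' @param n_boot bootstrap replicates (default 10,000; 0 skips CIs).
#' @param seed bootstrap seed.
#' @return List of class `marker_fit`: `coefficients` (data.frame with
#'   estimate, ci_lo, ci_hi), `variance_fractions` (named, incl. the
#'   marker), `r2`, `f_marker` (partial F of the marker term), `n`,
#'   `seed`.
#' @export
covariate_regression <- function(marker, covariates, rvef, n_boot = 10000,
                                 seed = 1) {
  md <- marker_design(marker, covariates, rvef)
  X <- md$X; y <- md$y
  n <- length(y)
  if (n <= ncol(X) + 1) stop("too few subjects for the design")
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  r2_full <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  vars <- unique(md$groups)
  vf <- vapply(vars, function(v) {
    keep <- c(TRUE, md$groups != v)  # intercept always kept
    r2_full - ols_r2(X[, keep, drop = FALSE], y)
  }, numeric(1))
  # partial F of the marker term (1 df)
  df2 <- n - ncol(X)
  f_marker <- unname(vf["marker"] / 1 / ((1 - r2_full) / df2))
  ci <- matrix(NA_real_, ncol(X), 2)
  if (n_boot > 0) {
    set.seed(seed)
    bs <- matrix(NA_real_, n_boot, ncol(X))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, replace = TRUE)
      cb <- tryCatch(stats::lm.fit(X[idx, , drop = FALSE], y[idx])$coefficients,
                     error = function(e) rep(NA_real_, ncol(X)))
      bs[b, ] <- ifelse(is.na(cb), 0, cb)
    }
    ci <- t(apply(bs, 2, stats::quantile, probs = c(0.025, 0.975),
                  na.rm = TRUE, names = FALSE))
  }
  structure(list(coefficients = data.frame(term = colnames(X),
                                           estimate = unname(beta),
                                           ci_lo = ci[, 1], ci_hi = ci[, 2]),
                 variance_fractions = vf, r2 = r2_full,
                 f_marker = f_marker, n = n, n_boot = n_boot, seed = seed),
            class = "marker_fit")
}

#' Compare two marker models by a model-type interaction
#'
#' Stacks the two marker models and regresses standardised RVEF on the
#' standardised marker, a model-type indicator, their interaction, and
#' the covariates; the interaction term tests whether the two markers
#' carry different slopes for RVEF.
#'
#' @param marker_a,marker_b numeric marker values on the same subjects.
#' @param covariates data.frame.
#' @param rvef numeric (%).
#' @return List with `interaction_estimate` and `p`.
#' @export
compare_models <- function(marker_a, marker_b, covariates, rvef) {
  n <- length(rvef)
  stopifnot(length(marker_a) == n, length(marker_b) == n)
  D <- build_design(covariates)
  m <- c(as.numeric(scale(marker_a)), as.numeric(scale(marker_b)))
  g <- rep(c(0, 1), each = n)
  X <- cbind(`(Intercept)` = 1, marker = m, model_type = g,
             `marker:model_type` = m * g, rbind(D, D))
  y <- rep(as.numeric(scale(rvef)), 2)
  fit <- stats::lm.fit(X, y)
  k <- sum(!is.na(fit$coefficients))
  sigma2 <- sum(fit$residuals^2) / (2 * n - k)
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtXinv[4, 4])
  est <- fit$coefficients["marker:model_type"]
  tval <- est / se
  list(interaction_estimate = unname(est),
       p = 2 * stats::pt(-abs(tval), df = 2 * n - k))
}

#' Leave-one-out RVEF prediction from a marker model
#'
#' For each subject, the covariate-adjusted marker regression is refitted
#' on the remaining subjects and used to predict the held-out RVEF.
#' Absolute errors are reported in EF points and converted to ml by
#' `|dEF| / 100 * EDV` of the held-out subject. Rank-deficient training
#' folds (a factor level present only in the held-out subject) use
#' zero-filled coefficients for the unestimable dummies.
#'
#' @param marker numeric marker values.
#' @param covariates data.frame.
#' @param rvef numeric (%).
#' @param edv numeric end-diastolic volumes (ml).
#' @param include_covariates include age/sex/race/BSA in the model
#'   (default) or use the marker alone.
#' @return List of class `loo_result`: `predicted`, `abs_error_ef`,
#'   `abs_error_ml`, and `summary` (median/IQR/range of both).
#' @export
loo_predict <- function(marker, covariates, rvef, edv,
                        include_covariates = TRUE) {
  n <- length(rvef)
  stopifnot(n >= 20, length(marker) == n, length(edv) == n)
  X <- if (include_covariates) {
    cbind(`(Intercept)` = 1, marker = marker, build_design(covariates))
  } else {
    cbind(`(Intercept)` = 1, marker = marker)
  }
  pred <- numeric(n)
  for (i in seq_len(n)) {
    fit <- tryCatch(stats::lm.fit(X[-i, , drop = FALSE], rvef[-i]),
                    error = function(e) {
                      stop("leave-one-out refit failed at fold ", i, ": ",
                           conditionMessage(e))
                    })
    beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    pred[i] <- sum(X[i, ] * beta)
  }
  err_ef <- abs(rvef - pred)
  err_ml <- err_ef / 100 * edv
  summ <- function(x) c(median = stats::median(x),
                        q25 = unname(stats::quantile(x, 0.25)),
                        q75 = unname(stats::quantile(x, 0.75)),
                        min = min(x), max = max(x))
  structure(list(predicted = pred, abs_error_ef = err_ef,
                 abs_error_ml = err_ml,
                 summary = rbind(ef_points = summ(err_ef),
                                 ml = summ(err_ml))),
            class = "loo_result")
}

#' Kruskal-Wallis comparison of absolute prediction errors
#'
#' @param errors named list of per-marker absolute-error vectors.
#' @return List with `chi_squared`, `df`, `p`.
#' @export
compare_errors_kruskal <- function(errors) {
  stopifnot(length(errors) >= 2, all(lengths(errors) > 0))
  if (length(unique(unlist(errors))) == 1L) {
    return(list(chi_squared = 0, df = length(errors) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(errors)
  list(chi_squared = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}
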