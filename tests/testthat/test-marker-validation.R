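test_that("Pearson correlation matches the explicit formula", {
  x <- c(1.2, 3.4, 2.2, 5.6, 4.1, 0.3, 2.8, 3.9, 1.1, 4.4)
  y <- c(2.0, 3.1, 2.9, 6.2, 3.8, 1.1, 2.2, 4.5, 0.9, 5.0)
  res <- pearson_cor(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  t_hand <- r_hand * sqrt(8 / (1 - r_hand^2))
  expect_equal(res$p, 2 * stats::pt(-abs(t_hand), 8), tolerance = 1e-12)

  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  yo <- stats::resid(stats::lm(y ~ x))
  expect_equal(pearson_cor(x, yo)$r, 0, tolerance = 1e-12)
  expect_error(pearson_cor(x, rep(1, 10)), "constant")
})

test_that("Steiger test is antisymmetric and matches the closed form", {
  expect_equal(steiger_test(0.4, 0.4, 0.3, 100)$z, 0)
  expect_equal(steiger_test(0.4, 0.4, 0.3, 100)$p, 1)
  a <- steiger_test(0.5, 0.3, 0.4, 200)
  b <- steiger_test(0.3, 0.5, 0.4, 200)
  expect_equal(a$z, -b$z, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)

  # independent arithmetic for one case
  r_jk <- 0.44; r_jh <- 0.24; r_kh <- 0.5; n <- 300
  z1 <- 0.5 * log((1 + r_jk) / (1 - r_jk))
  z2 <- 0.5 * log((1 + r_jh) / (1 - r_jh))
  rb <- tanh((z1 + z2) / 2)
  psi <- r_kh * (1 - 2 * rb^2) - 0.5 * rb^2 * (1 - 2 * rb^2 - r_kh^2)
  z_hand <- (z1 - z2) * sqrt((n - 3) / (2 * (1 - psi / (1 - rb^2)^2)))
  expect_equal(steiger_test(r_jk, r_jh, r_kh, n)$z, z_hand,
               tolerance = 1e-12)

  expect_error(steiger_test(1, 0.5, 0.2, 50), "in \\(-1, 1\\)")
})

test_that("covariate regression matches the normal-equations oracle", {
  set.seed(61)
  n <- 40
  cov <- fixture_covariates(n)
  rvef <- rnorm(n, 57, 7)
  marker <- 0.5 * as.numeric(scale(rvef)) + rnorm(n, 0, 0.8)
  fit <- covariate_regression(marker, cov, rvef, n_boot = 100, seed = 9)
  X <- cbind(1, scale(marker), build_design(cov))
  y <- as.numeric(scale(rvef))
  beta_oracle <- solve(crossprod(X), crossprod(X, y))
  expect_equal(fit$coefficients$estimate, as.numeric(beta_oracle),
               tolerance = 1e-10)
  expect_true(all(fit$variance_fractions >= -1e-12))
  expect_lte(sum(fit$variance_fractions), fit$r2 + 1e-9)

  # marker identical to RVEF with inert covariates: marker owns the variance
  set.seed(62)
  rvef2 <- rnorm(n, 57, 7)
  fitx <- covariate_regression(rvef2, fixture_covariates(n, seed = 3), rvef2,
                               n_boot = 0)
  expect_gt(fitx$variance_fractions[["marker"]], 0.95)
  # independent marker: near-zero share
  fit0 <- covariate_regression(rnorm(n), fixture_covariates(n, seed = 3),
                               rvef2, n_boot = 0)
  expect_lt(fit0$variance_fractions[["marker"]], 0.12)
})

test_that("model-type interaction separates unequal marker slopes", {
  set.seed(63)
  n <- 120
  cov <- fixture_covariates(n)
  rvef <- rnorm(n, 57, 7)
  m <- rnorm(n)
  same <- compare_models(m, m, cov, rvef)
  expect_equal(same$interaction_estimate, 0, tolerance = 1e-10)

  # equal true slopes: rarely significant
  S <- chol(matrix(c(1, .4, .4, .4, 1, .5, .4, .5, 1), 3))
  nullp <- vapply(1:20, function(i) {
    set.seed(200 + i)
    X <- matrix(rnorm(300 * 3), 300) %*% S
    compare_models(X[, 2], X[, 3], fixture_covariates(300, seed = i),
                   50 + 7 * X[, 1])$p
  }, numeric(1))
  expect_gte(sum(nullp > 0.05), 16)

  # slope difference of 0.3 SD at n = 300: usually detected
  S2 <- chol(matrix(c(1, .5, .2, .5, 1, .3, .2, .3, 1), 3))
  altp <- vapply(1:20, function(i) {
    set.seed(300 + i)
    X <- matrix(rnorm(300 * 3), 300) %*% S2
    compare_models(X[, 2], X[, 3], fixture_covariates(300, seed = i),
                   50 + 7 * X[, 1])$p
  }, numeric(1))
  expect_gte(mean(altp < 0.05), 0.8)
})

test_that("leave-one-out predictions match the hat-matrix oracle", {
  set.seed(64)
  n <- 50
  cov <- fixture_covariates(n)
  rvef <- rnorm(n, 57, 7)
  edv <- rnorm(n, 140, 20)
  marker <- 0.5 * as.numeric(scale(rvef)) + rnorm(n, 0, 0.8)
  res <- loo_predict(marker, cov, rvef, edv)
  X <- cbind(1, marker, build_design(cov))
  H <- X %*% solve(crossprod(X), t(X))
  e <- rvef - as.numeric(H %*% rvef)
  oracle <- rvef - e / (1 - diag(H))
  expect_equal(res$predicted, oracle, tolerance = 1e-8)
  expect_equal(res$abs_error_ml, abs(rvef - oracle) / 100 * edv,
               tolerance = 1e-8)
  expect_equal(length(res$abs_error_ef), n)

  # perfect marker predicts perfectly
  perfect <- loo_predict(rvef, cov, rvef, edv)
  expect_lt(max(perfect$abs_error_ef), 1e-8)

  # a pure-noise marker approaches the covariates-only model error
  noise_m <- loo_predict(rnorm(n), cov, rvef, edv)
  const_m <- loo_predict(rep(0, n), cov, rvef, edv)  # marker carries nothing
  expect_equal(noise_m$summary["ef_points", "median"],
               const_m$summary["ef_points", "median"], tolerance = 0.25)
})

test_that("Kruskal-Wallis comparison matches the tie-corrected hand formula", {
  expect_equal(compare_errors_kruskal(list(a = c(1, 1), b = c(1, 1)))$p, 1)

  g <- list(a = c(2.1, 3.5, 3.5), b = c(1.0, 2.1, 4.2), c = c(5.0, 6.1, 3.5))
  res <- compare_errors_kruskal(g)
  x <- unlist(g); grp <- rep(names(g), lengths(g))
  r <- rank(x); N <- length(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, grp, function(ri) length(ri) * mean(ri)^2)) - 3 * (N + 1)
  ties <- table(x)
  H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
  expect_equal(res$chi_squared, H, tolerance = 1e-10)
  expect_equal(res$df, 2)
  expect_equal(res$p, stats::pchisq(H, 2, lower.tail = FALSE),
               tolerance = 1e-12)
})
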