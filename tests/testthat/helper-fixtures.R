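# Shared fixtures, built in code at test time.

# single right triangle with 10 mm legs in the z = 0 plane
triangle_mesh <- function() {
  rv_mesh(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0)),
          rbind(c(1, 2, 3)),
          apex = 1L, annulus = c(2L, 3L),
          plane_point = c(0, 0, 0), plane_normal = c(0, 0, 1))
}

# two triangles sharing edge (2,3); vertex 1 and 4 are not adjacent
quad_mesh <- function() {
  rv_mesh(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(10, 10, 0)),
          rbind(c(1, 2, 3), c(2, 4, 3)),
          apex = 1L, annulus = c(2L, 3L, 4L))
}

# small deterministic half-ellipsoid used across mesh/motion tests
fixture_mesh <- function(n = 300) generate_mesh(n, axis_length = 85, radius = 30)

# small cohort; motion fields on unless stated
fixture_cohort <- function(n_subjects = 60, n_vertices = 120,
                           effect_size = 0.3, seed = 7, ...) {
  generate_cohort(generator_config(n_subjects = n_subjects,
                                   n_vertices = n_vertices,
                                   effect_size = effect_size,
                                   seed = seed, ...))
}

# a small covariate table with all factor levels guaranteed present
fixture_covariates <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(age = runif(n, 20, 70),
             sex = factor(rep_len(c("F", "F", "M"), n)),
             race = factor(rep_len(c("A", "A", "A", "B", "C"), n)),
             bsa = rnorm(n, 1.8, 0.15))
}

# brute-force per-vertex OLS of standardised rvef on standardised
# excursion + covariates via lm(); oracle for the FWL implementation
oracle_pointwise <- function(excursion, covariates, rvef) {
  D <- build_design(covariates)
  y <- as.numeric(scale(rvef))
  t(vapply(seq_len(ncol(excursion)), function(j) {
    x <- as.numeric(scale(excursion[, j]))
    fit <- summary(stats::lm(y ~ x + D))
    fit$coefficients["x", c("Estimate", "t value")]
  }, numeric(2)))
}

# hand-coded BH step-up (independent of stats::p.adjust)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}
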