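# Test-retest agreement: Bland-Altman-style bias with limits of
# agreement, and single-measure two-way random absolute-agreement
# intraclass correlation, ICC(2,1).

#' Bias and 95% limits of agreement between paired measurements
#'
#' @param m1,m2 paired numeric vectors (occasion 1 and 2).
#' @return List of class `agreement`: `bias` (mean of `m1 - m2`),
#'   `sd`, `loa` (bias +/- 1.96 SD).
#' @export
bias_loa <- function(m1, m2) {
  if (length(m1) != length(m2)) stop("paired series differ in length")
  d <- m1 - m2
  b <- mean(d); s <- stats::sd(d)
  structure(list(bias = b, sd = s, loa = c(b - 1.96 * s, b + 1.96 * s)),
            class = "agreement")
}

#' ICC(2,1): two-way random effects, absolute agreement, single measure
#'
#' From the two-way ANOVA decomposition with subjects as rows and
#' raters/occasions as columns:
#' `ICC = (MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n) (MS_C - MS_E))`.
#' Zero between-subject variance returns 0 with a `degenerate` attribute.
#'
#' @param x n x k numeric matrix (subjects x occasions), no missing
#'   cells, n >= 2, k >= 2.
#' @return ICC point estimate.
#' @export
icc_two_way_random_absolute <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  stopifnot(n >= 2, k >= 2)
  if (any(is.na(x))) stop("missing cells are not supported")
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ss_r <- k * sum((row_m - grand)^2)
  ss_c <- n * sum((col_m - grand)^2)
  ss_t <- sum((x - grand)^2)
  ss_e <- ss_t - ss_r - ss_c
  ms_r <- ss_r / (n - 1)
  ms_c <- ss_c / (k - 1)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  if (ms_r < 1e-12 && ms_e < 1e-12) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e))
}

#' Per-vertex test-retest ICC of pointwise excursion
#'
#' ICC(2,1) computed vertex-by-vertex between two excursion matrices,
#' summarised by the cohort mean (the across-vertex aggregation used
#' when one number is reported for the whole surface).
#'
#' @param excursion_1,excursion_2 subjects x vertices matrices from two
#'   scans.
#' @return List with `per_vertex` ICCs, `mean`, `median`.
#' @export
pointwise_icc <- function(excursion_1, excursion_2) {
  stopifnot(all(dim(excursion_1) == dim(excursion_2)))
  per_v <- vapply(seq_len(ncol(excursion_1)), function(j) {
    as.numeric(icc_two_way_random_absolute(
      cbind(excursion_1[, j], excursion_2[, j])))
  }, numeric(1))
  list(per_vertex = per_v, mean = mean(per_v),
       median = stats::median(per_v))
}
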