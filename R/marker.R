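# Marker derivation: PCA of patch motion, PC1 reconstruction
# correlation, and the optimised single-point marker (SPM-O) at the
# best plane-coinciding patch vertex.

#' PCA of the patch excursion matrix
#'
#' PCA on the column-centred (not rescaled: columns share mm units)
#' subjects x patch-vertices matrix. PC1 is the single retained mode for
#' marker derivation and is oriented so that its score correlates
#' positively with mean patch excursion.
#'
#' @param x subjects x patch-vertices excursion matrix.
#' @return List of class `patch_pca`: `loadings` (vertices x components,
#'   orthonormal), `scores` (subjects x components), `sdev`,
#'   `explained_variance_ratio`, `center`.
#' @export
patch_pca <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) stop("need >= 2 subjects and >= 2 vertices")
  if (all(apply(x, 2, stats::sd) < 1e-12)) stop("zero-variance patch matrix")
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  if (stats::cor(pr$x[, 1], rowMeans(x)) < 0) {
    pr$rotation[, 1] <- -pr$rotation[, 1]
    pr$x[, 1] <- -pr$x[, 1]
  }
  structure(list(loadings = pr$rotation, scores = pr$x, sdev = pr$sdev,
                 explained_variance_ratio = pr$sdev^2 / sum(pr$sdev^2),
                 center = pr$center),
            class = "patch_pca")
}

#' Per-vertex PC reconstruction correlation
#'
#' Reconstructs the patch matrix from the first `k` components (plus
#' column means) and returns the per-vertex Pearson correlation between
#' the reconstructed and original columns. Vertices with a constant
#' original or reconstructed column get `NA` (flagged, excluded from
#' marker selection).
#'
#' @param pca a [patch_pca()] result.
#' @param x the original subjects x patch-vertices matrix.
#' @param k number of leading components used (default 1).
#' @return Numeric vector of per-vertex correlations.
#' @export
reconstruction_correlation <- function(pca, x, k = 1) {
  x <- as.matrix(x)
  stopifnot(k >= 1, k <= ncol(pca$loadings))
  xhat <- pca$scores[, seq_len(k), drop = FALSE] %*%
    t(pca$loadings[, seq_len(k), drop = FALSE])
  xhat <- sweep(xhat, 2, pca$center, "+")
  vapply(seq_len(ncol(x)), function(j) {
    if (stats::sd(x[, j]) < 1e-12 || stats::sd(xhat[, j]) < 1e-12) {
      return(NA_real_)
    }
    stats::cor(x[, j], xhat[, j])
  }, numeric(1))
}

#' Select the optimised single-point marker (SPM-O)
#'
#' Among patch vertices coinciding with the imaging plane, picks the one
#' whose excursion is best reconstructed by PC1 (maximal reconstruction
#' correlation). Ties break to the smaller vertex index.
#'
#' @param correlations per-patch-vertex reconstruction correlations,
#'   ordered as `patch$vertices`.
#' @param patch an [extract_patch()] result (or any list with a
#'   `vertices` field).
#' @param plane_set integer vertex indices from [plane_vertices()].
#' @param axial output of [axial_coordinate()].
#' @param plane_name label recorded in the definition.
#' @return List of class `marker_def`: `vertex`, `correlation`,
#'   `base_to_apex_fraction`, `distance_from_apex_cm`, `plane`.
#' @export
select_spm_o <- function(correlations, patch, plane_set, axial,
                         plane_name = "four-chamber") {
  stopifnot(length(correlations) == length(patch$vertices))
  keep <- patch$vertices %in% plane_set & !is.na(correlations)
  if (!any(keep)) {
    stop("no patch vertex coincides with the plane; ",
         "increase the plane tolerance")
  }
  cand_v <- patch$vertices[keep]
  cand_r <- correlations[keep]
  best <- which(cand_r == max(cand_r))
  pick <- best[which.min(cand_v[best])]
  structure(list(vertex = cand_v[pick], correlation = cand_r[pick],
                 base_to_apex_fraction = axial$fraction[cand_v[pick]],
                 distance_from_apex_cm =
                   axial$distance_from_apex[cand_v[pick]] / 10,
                 plane = plane_name),
            class = "marker_def")
}

#' @export
print.marker_def <- function(x, ...) {
  cat(sprintf(paste0("SPM-O: vertex %d (%s plane), reconstruction R = %.2f, ",
                     "%.0f%% of base-to-apex distance\n"),
              x$vertex, x$plane, x$correlation,
              100 * x$base_to_apex_fraction))
  invisible(x)
}

#' Measure SPM-O on a subject's motion field
#'
#' The marker value is the Euclidean ED-to-ES displacement of the marker
#' vertex (mm); the fractional form normalises by the subject's ED
#' base-to-apex axis length (as a percentage). Note the measurement is a
#' displacement, not a deformation: rigid whole-heart motion contributes
#' to it.
#'
#' @param motion a [motion_field].
#' @param marker a [select_spm_o()] definition.
#' @param mesh the cohort [rv_mesh] (supplies the landmark indices used
#'   to compute the ED axis length).
#' @return List with `mm` and `fractional_pct`.
#' @export
measure_spm_o <- function(motion, marker, mesh) {
  v <- marker$vertex
  stopifnot(v >= 1, v <= nrow(motion$ed))
  disp <- sqrt(sum((motion$es[v, ] - motion$ed[v, ])^2))
  base <- colMeans(motion$ed[mesh$annulus, , drop = FALSE])
  axis_len <- sqrt(sum((motion$ed[mesh$apex, ] - base)^2))
  list(mm = disp, fractional_pct = 100 * disp / axis_len)
}

#' Serialise a marker definition to JSON
#' @param marker a `marker_def`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_marker_json <- function(marker, path) {
  jsonlite::write_json(unclass(marker), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
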