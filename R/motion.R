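# Per-vertex systolic excursion and its decomposition into longitudinal,
# transverse (radial) and circumferential components in a per-vertex
# cylindrical frame about the RV long axis.

#' Construct a single-subject motion field
#'
#' End-diastolic and end-systolic vertex positions with the same
#' correspondence as the cohort mesh.
#'
#' @param ed,es n x 3 matrices of vertex positions (mm).
#' @param subject_id optional identifier.
#' @return An object of class `motion_field`.
#' @export
motion_field <- function(ed, es, subject_id = NA_character_) {
  ed <- as.matrix(ed); es <- as.matrix(es)
  if (!all(dim(ed) == dim(es)) || ncol(ed) != 3L) {
    stop("ed and es must be equal-sized n x 3 matrices")
  }
  structure(list(subject_id = subject_id, ed = ed, es = es),
            class = "motion_field")
}

#' Systolic excursion of every vertex
#'
#' Excursion is the distance travelled in 3D from end-diastole to
#' end-systole: the per-vertex displacement vector `es - ed` and its
#' Euclidean norm.
#'
#' @param motion a [motion_field].
#' @return A list of class `excursion_field` with `vectors` (n x 3, mm)
#'   and `scalars` (length n, mm).
#' @export
compute_excursion <- function(motion) {
  bad <- which(!stats::complete.cases(cbind(motion$ed, motion$es)) |
                 rowSums(!is.finite(cbind(motion$ed, motion$es))) > 0)
  if (length(bad)) {
    stop("non-finite coordinates at vertex/vertices: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  v <- motion$es - motion$ed
  structure(list(vectors = v, scalars = sqrt(rowSums(v^2))),
            class = "excursion_field")
}

#' Per-vertex orthonormal anatomical frames
#'
#' For each vertex: longitudinal = unit long-axis direction (base to
#' apex); transverse = unit radial vector from the axis through the
#' vertex (outward); circumferential = longitudinal x transverse, tangent
#' to the circle about the axis. Vertices lying on the axis (radial
#' direction undefined) receive an arbitrary perpendicular and are
#' flagged.
#'
#' @param mesh an [rv_mesh].
#' @return List with `longitudinal`, `transverse`, `circumferential`
#'   (each n x 3 unit rows) and `on_axis` (logical flags).
#' @export
local_frames <- function(mesh) {
  ax <- axial_coordinate(mesh)
  el <- ax$axis_direction
  n <- nrow(mesh$vertices)
  rel <- mesh$vertices - matrix(ax$base_point, n, 3, byrow = TRUE)
  along <- as.numeric(rel %*% el)
  radial <- rel - outer(along, el)
  rn <- sqrt(rowSums(radial^2))
  on_axis <- rn < 1e-9
  if (any(on_axis)) {
    # arbitrary perpendicular to the axis for on-axis vertices
    perp <- if (abs(el[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp <- perp - sum(perp * el) * el
    perp <- perp / sqrt(sum(perp^2))
    radial[on_axis, ] <- matrix(perp, sum(on_axis), 3, byrow = TRUE)
    rn[on_axis] <- 1
  }
  et <- radial / rn
  ec <- cbind(el[2] * et[, 3] - el[3] * et[, 2],
              el[3] * et[, 1] - el[1] * et[, 3],
              el[1] * et[, 2] - el[2] * et[, 1])
  list(longitudinal = matrix(el, n, 3, byrow = TRUE),
       transverse = et, circumferential = ec, on_axis = on_axis)
}

#' Decompose excursion vectors into directional components
#'
#' Projects each vertex's displacement vector onto its local frame. The
#' directional composition of a region is the mean absolute component
#' over the region (and over subjects when a subject x vertex x 3
#' array or list of fields is supplied), normalised so the three
#' percentages sum to 100.
#'
#' @param vectors n x 3 displacement matrix (one subject), or a list of
#'   such matrices (cohort).
#' @param frames output of [local_frames()].
#' @param region optional integer vertex subset over which to summarise
#'   the composition (default: all vertices).
#' @return List with `components` (n x 3 matrix, or list of matrices,
#'   columns longitudinal/transverse/circumferential in mm) and
#'   `composition` (named percentages summing to 100).
#' @export
decompose_excursion <- function(vectors, frames, region = NULL) {
  one <- function(v) {
    stopifnot(nrow(v) == nrow(frames$transverse))
    cbind(longitudinal = rowSums(v * frames$longitudinal),
          transverse = rowSums(v * frames$transverse),
          circumferential = rowSums(v * frames$circumferential))
  }
  if (is.list(vectors) && !is.matrix(vectors)) {
    comp <- lapply(vectors, one)
    pool <- do.call(rbind, lapply(comp, function(m) {
      if (is.null(region)) m else m[region, , drop = FALSE]
    }))
  } else {
    comp <- one(vectors)
    pool <- if (is.null(region)) comp else comp[region, , drop = FALSE]
  }
  mabs <- colMeans(abs(pool))
  list(components = comp,
       composition = 100 * mabs / sum(mabs))
}

#' Median (IQR [range]) summary of regional component excursion
#'
#' Per-subject mean absolute component over a region, summarised across
#' subjects the way clinical tables report motion amplitudes.
#'
#' @param vector_list list of per-subject n x 3 displacement matrices.
#' @param frames output of [local_frames()].
#' @param region integer vertex subset.
#' @return data.frame with one row per component: median, q25, q75, min,
#'   max (mm).
#' @export
component_summary <- function(vector_list, frames, region) {
  per_subj <- t(vapply(vector_list, function(v) {
    comp <- cbind(rowSums(v * frames$longitudinal),
                  rowSums(v * frames$transverse),
                  rowSums(v * frames$circumferential))
    colMeans(abs(comp[region, , drop = FALSE]))
  }, numeric(3)))
  colnames(per_subj) <- c("longitudinal", "transverse", "circumferential")
  out <- t(apply(per_subj, 2, function(x) {
    c(median = stats::median(x),
      q25 = unname(stats::quantile(x, 0.25)),
      q75 = unname(stats::quantile(x, 0.75)),
      min = min(x), max = max(x))
  }))
  data.frame(component = rownames(out), out, row.names = NULL)
}
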