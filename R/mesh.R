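# Corresponded triangulated RV surface mesh with anatomical landmarks.
# Coordinates are millimetres in an arbitrary right-handed frame; vertex
# indices are 1-based throughout the package (0-based only on disk).

#' Construct an RV surface mesh
#'
#' A corresponded triangulated surface of the right-ventricular wall with
#' the two landmarks needed to define the long axis (apex vertex and
#' tricuspid-annulus ring) and the four-chamber imaging plane.
#'
#' @param vertices numeric matrix, n x 3, vertex positions in mm.
#' @param faces integer matrix, f x 3, 1-based vertex index triples.
#' @param apex integer, vertex index of the RV apex.
#' @param annulus integer vector, vertex indices of the tricuspid annulus
#'   ring. Must not contain `apex`.
#' @param plane_point,plane_normal numeric length-3; a point on the
#'   four-chamber plane and its normal (normalised internally).
#'
#' @return An object of class `rv_mesh` with elements `vertices`, `faces`,
#'   `apex`, `annulus`, `plane` (list with `point`, `normal`).
#' @export
rv_mesh <- function(vertices, faces, apex, annulus,
                    plane_point = NULL, plane_normal = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an f x 3 matrix")
  n <- nrow(vertices)
  if (any(!is.finite(vertices))) stop("non-finite vertex coordinates")
  if (any(faces < 1L) || any(faces > n)) {
    stop("face indices out of range 1..", n)
  }
  degen <- faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
    faces[, 2] == faces[, 3]
  if (any(degen)) {
    stop("degenerate faces (repeated vertex index) at rows: ",
         paste(utils::head(which(degen), 5L), collapse = ", "))
  }
  apex <- as.integer(apex)
  annulus <- as.integer(annulus)
  stopifnot(length(apex) == 1L, apex >= 1L, apex <= n)
  if (apex %in% annulus) stop("apex vertex cannot be part of the annulus ring")
  if (any(annulus < 1L) || any(annulus > n)) stop("annulus indices out of range")
  plane <- NULL
  if (!is.null(plane_normal)) {
    plane_normal <- as.numeric(plane_normal)
    nn <- sqrt(sum(plane_normal^2))
    if (nn == 0) stop("plane normal has zero length")
    plane <- list(point = as.numeric(plane_point %||% c(0, 0, 0)),
                  normal = plane_normal / nn)
  }
  structure(list(vertices = vertices, faces = faces, apex = apex,
                 annulus = annulus, plane = plane),
            class = "rv_mesh")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rv_mesh <- function(x, ...) {
  cat("rv_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces\n")
  cat("  apex vertex:", x$apex, "; annulus ring:", length(x$annulus),
      "vertices\n")
  if (!is.null(x$plane)) {
    cat("  four-chamber plane normal:",
        paste(signif(x$plane$normal, 3), collapse = " "), "\n")
  }
  invisible(x)
}

#' Vertex adjacency of a triangulated mesh
#'
#' Two vertices are adjacent iff they share an edge of some face. Also
#' checks 2-manifoldness: every undirected edge may belong to at most two
#' faces.
#'
#' @param mesh an [rv_mesh].
#' @return A list with `graph` (an undirected [igraph::igraph] whose edges
#'   carry Euclidean `length` weights in mm) and `neighbors` (list of
#'   integer neighbour vectors per vertex).
#' @export
build_adjacency <- function(mesh) {
  f <- mesh$faces
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  mult <- table(key)
  if (any(mult > 2L)) {
    stop("mesh is not 2-manifold: some edge shared by > 2 faces")
  }
  keep <- !duplicated(key)
  eu <- edges[keep, , drop = FALSE]
  eu <- cbind(pmin(eu[, 1], eu[, 2]), pmax(eu[, 1], eu[, 2]))
  len <- sqrt(rowSums((mesh$vertices[eu[, 1], , drop = FALSE] -
                         mesh$vertices[eu[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(eu, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(mesh$vertices) - igraph::vcount(g)))
  igraph::E(g)$length <- len
  nb <- igraph::as_adj_list(g)
  nb <- lapply(nb, as.integer)
  list(graph = g, neighbors = nb)
}

face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' Surface area of a vertex subset
#'
#' A face contributes its full area iff all three of its vertices are in
#' the subset (so the whole-mesh call returns the total surface area, and
#' areas are additive over disjoint face-complete subsets). Input
#' coordinates are mm; the area is returned in cm^2.
#'
#' @param mesh an [rv_mesh].
#' @param vertex_subset integer vertex indices; defaults to all vertices.
#' @return Area in cm^2.
#' @export
surface_area <- function(mesh, vertex_subset = seq_len(nrow(mesh$vertices))) {
  vertex_subset <- as.integer(vertex_subset)
  if (length(vertex_subset) == 0L) {
    warning("empty vertex subset: area 0")
    return(0)
  }
  if (any(vertex_subset < 1L) || any(vertex_subset > nrow(mesh$vertices))) {
    stop("vertex subset indices out of range")
  }
  inset <- logical(nrow(mesh$vertices))
  inset[vertex_subset] <- TRUE
  full <- inset[mesh$faces[, 1]] & inset[mesh$faces[, 2]] & inset[mesh$faces[, 3]]
  sum(face_areas(mesh)[full]) / 100  # mm^2 -> cm^2
}

#' Apex--base axial coordinate of every vertex
#'
#' The long axis runs from the tricuspid-annulus ring centroid (base) to
#' the apex vertex. Each vertex's base-to-apex fraction is its scalar
#' projection onto this axis, clipped to \[0, 1\] (0 at the base, 1 at the
#' apex); distance from the apex is `(1 - fraction) * axis_length`.
#'
#' @param mesh an [rv_mesh].
#' @return A list with `fraction` (per-vertex, in \[0,1\]),
#'   `distance_from_apex` (mm), `axis_length` (mm), `axis_direction`
#'   (unit vector base -> apex), `base_point` (annulus centroid).
#' @export
axial_coordinate <- function(mesh) {
  base <- colMeans(mesh$vertices[mesh$annulus, , drop = FALSE])
  apex <- mesh$vertices[mesh$apex, ]
  ax <- apex - base
  len <- sqrt(sum(ax^2))
  if (len < 1e-9) stop("zero-length long axis: apex coincides with annulus centroid")
  frac <- as.numeric((mesh$vertices - matrix(base, nrow(mesh$vertices), 3,
                                             byrow = TRUE)) %*% ax) / len^2
  frac <- pmin(1, pmax(0, frac))
  list(fraction = frac,
       distance_from_apex = (1 - frac) * len,
       axis_length = len,
       axis_direction = ax / len,
       base_point = base)
}

#' Vertices coinciding with the four-chamber plane
#'
#' @param mesh an [rv_mesh] with its `plane` set.
#' @param tolerance maximum unsigned point-plane distance in mm. The
#'   default of 2 mm corresponds to one acquisition voxel.
#' @return Integer vertex indices within `tolerance` of the plane.
#' @export
plane_vertices <- function(mesh, tolerance = 2) {
  stopifnot(tolerance > 0)
  if (is.null(mesh$plane)) stop("mesh has no four-chamber plane defined")
  d <- abs(as.numeric((mesh$vertices - matrix(mesh$plane$point,
                                              nrow(mesh$vertices), 3,
                                              byrow = TRUE)) %*%
                        mesh$plane$normal))
  idx <- which(d <= tolerance)
  if (length(idx) == 0L) {
    warning("no vertices within ", tolerance,
            " mm of the plane; marker selection will fail downstream")
  }
  idx
}

#' Per-vertex correspondence distance between two meshes
#'
#' Summarises the Euclidean distance between corresponded vertex positions
#' (e.g. automated vs manual segmentation of the same subject).
#'
#' @param positions_a,positions_b n x 3 matrices with identical vertex
#'   correspondence.
#' @return List with `distances` (mm), `mean`, `sd`, and `ci95`
#'   (normal-approximation 95% CI of the mean).
#' @export
mean_correspondence_distance <- function(positions_a, positions_b) {
  positions_a <- as.matrix(positions_a)
  positions_b <- as.matrix(positions_b)
  if (!all(dim(positions_a) == dim(positions_b))) {
    stop("vertex counts differ: meshes are not corresponded")
  }
  d <- sqrt(rowSums((positions_a - positions_b)^2))
  m <- mean(d)
  s <- stats::sd(d)
  se <- s / sqrt(length(d))
  list(distances = d, mean = m, sd = s,
       ci95 = c(m - 1.96 * se, m + 1.96 * se))
}
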