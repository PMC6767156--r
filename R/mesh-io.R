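# Plain-text mesh I/O: legacy ASCII VTK polydata and ASCII PLY, with a
# YAML sidecar for landmarks and the four-chamber plane. Indices are
# 0-based on disk (VTK/PLY convention), 1-based in R.

#' Write a mesh as legacy ASCII VTK polydata
#'
#' @param mesh an [rv_mesh].
#' @param path output file path.
#' @param point_data optional named list of per-vertex numeric vectors
#'   written as `POINT_DATA` scalar fields (e.g. effect sizes, q-values).
#' @param sidecar if `TRUE` (default) also write `<path>.yaml` with the
#'   landmarks and plane via [write_mesh_sidecar()].
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = NULL, sidecar = TRUE) {
  n <- nrow(mesh$vertices)
  f <- nrow(mesh$faces)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "rvatlas surface mesh", "ASCII",
               "DATASET POLYDATA",
               paste("POINTS", n, "double")), con)
  utils::write.table(format(mesh$vertices, scientific = FALSE, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  writeLines(paste("POLYGONS", f, 4 * f), con)
  utils::write.table(cbind(3L, mesh$faces - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  if (!is.null(point_data)) {
    writeLines(paste("POINT_DATA", n), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      stopifnot(length(v) == n)
      writeLines(c(paste("SCALARS", nm, "double", 1),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(as.numeric(v), scientific = FALSE, trim = TRUE), con)
    }
  }
  if (sidecar) write_mesh_sidecar(mesh, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a legacy ASCII VTK polydata mesh
#'
#' Reads `POINTS` and `POLYGONS` (triangles only) and, when present, the
#' `<path>.yaml` sidecar with landmarks and plane. Without a sidecar the
#' landmarks must be supplied later; the returned object then has apex 1
#' and an empty annulus placeholder rejected by [rv_mesh()], so the raw
#' geometry is returned as a plain list instead.
#'
#' @param path file path.
#' @return An [rv_mesh] if a sidecar is found, otherwise a list with
#'   `vertices` and `faces`.
#' @export
read_vtk <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  if (is.na(ip)) stop("no POINTS section in ", path)
  n <- as.integer(strsplit(trimws(lines[ip]), "\\s+")[[1]][2])
  vals <- scan(text = lines[(ip + 1):length(lines)], what = double(),
               n = 3 * n, quiet = TRUE)
  verts <- matrix(vals, ncol = 3, byrow = TRUE)
  ifc <- grep("^POLYGONS", lines)[1]
  if (is.na(ifc)) stop("no POLYGONS section in ", path)
  f <- as.integer(strsplit(trimws(lines[ifc]), "\\s+")[[1]][2])
  fv <- scan(text = lines[(ifc + 1):length(lines)], what = integer(),
             n = 4 * f, quiet = TRUE)
  fm <- matrix(fv, ncol = 4, byrow = TRUE)
  if (any(fm[, 1] != 3L)) stop("non-triangular polygons are not supported")
  faces <- fm[, 2:4, drop = FALSE] + 1L
  side <- paste0(path, ".yaml")
  if (file.exists(side)) {
    meta <- read_mesh_sidecar(side)
    rv_mesh(verts, faces, apex = meta$apex, annulus = meta$annulus,
            plane_point = meta$plane_point, plane_normal = meta$plane_normal)
  } else {
    list(vertices = verts, faces = faces)
  }
}

#' Write a mesh as ASCII PLY
#' @inheritParams write_vtk
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path, sidecar = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               paste("element face", nrow(mesh$faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  utils::write.table(format(mesh$vertices, scientific = FALSE, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  if (sidecar) write_mesh_sidecar(mesh, paste0(path, ".yaml"))
  invisible(path)
}

#' Read an ASCII PLY mesh
#' @inheritParams read_vtk
#' @return As [read_vtk()].
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  hend <- grep("^end_header", lines)[1]
  if (is.na(hend)) stop("no end_header in ", path)
  header <- lines[seq_len(hend)]
  n <- as.integer(sub("element vertex ", "", grep("^element vertex",
                                                  header, value = TRUE)))
  f <- as.integer(sub("element face ", "", grep("^element face",
                                                header, value = TRUE)))
  body <- lines[(hend + 1):length(lines)]
  verts <- matrix(scan(text = body[seq_len(n)], what = double(),
                       quiet = TRUE), ncol = 3, byrow = TRUE)
  fm <- matrix(scan(text = body[n + seq_len(f)], what = integer(),
                    quiet = TRUE), ncol = 4, byrow = TRUE)
  faces <- fm[, 2:4, drop = FALSE] + 1L
  side <- paste0(path, ".yaml")
  if (file.exists(side)) {
    meta <- read_mesh_sidecar(side)
    rv_mesh(verts, faces, apex = meta$apex, annulus = meta$annulus,
            plane_point = meta$plane_point, plane_normal = meta$plane_normal)
  } else {
    list(vertices = verts, faces = faces)
  }
}

#' Write / read the landmark and plane sidecar
#'
#' Landmarks (apex vertex, annulus ring) and the four-chamber plane are
#' stored in a YAML file next to the geometry, with 0-based indices on
#' disk.
#'
#' @param mesh an [rv_mesh].
#' @param path sidecar file path.
#' @return `path` (write) or a list with 1-based `apex`, `annulus`,
#'   `plane_point`, `plane_normal` (read).
#' @export
write_mesh_sidecar <- function(mesh, path) {
  meta <- list(apex = mesh$apex - 1L,
               annulus = as.integer(mesh$annulus - 1L))
  if (!is.null(mesh$plane)) {
    meta$plane <- list(point = as.numeric(mesh$plane$point),
                       normal = as.numeric(mesh$plane$normal))
  }
  yaml::write_yaml(meta, path)
  invisible(path)
}

#' @rdname write_mesh_sidecar
#' @export
read_mesh_sidecar <- function(path) {
  meta <- yaml::read_yaml(path)
  list(apex = as.integer(meta$apex) + 1L,
       annulus = as.integer(meta$annulus) + 1L,
       plane_point = if (!is.null(meta$plane)) as.numeric(meta$plane$point),
       plane_normal = if (!is.null(meta$plane)) as.numeric(meta$plane$normal))
}
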