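test_that("adjacency matches edge structure on hand meshes and by brute force", {
  adj <- build_adjacency(triangle_mesh())
  expect_setequal(adj$neighbors[[1]], c(2L, 3L))
  expect_setequal(adj$neighbors[[2]], c(1L, 3L))

  adj2 <- build_adjacency(quad_mesh())
  expect_false(4L %in% adj2$neighbors[[1]])
  expect_true(3L %in% adj2$neighbors[[2]])

  m <- fixture_mesh(100)
  adj3 <- build_adjacency(m)
  # brute-force edge scan
  edges <- unique(t(apply(rbind(m$faces[, 1:2], m$faces[, 2:3],
                                m$faces[, c(3, 1)]), 1, sort)))
  for (v in sample(nrow(m$vertices), 10)) {
    nb <- sort(unique(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1])))
    expect_identical(sort(adj3$neighbors[[v]]), as.integer(nb))
  }
  expect_true(igraph::is_connected(adj3$graph))
})

test_that("degenerate faces are rejected with a diagnostic", {
  expect_error(
    build_adjacency(rv_mesh(diag(3) * 10, rbind(c(1, 1, 2)), apex = 3L,
                            annulus = c(1L, 2L))),
    "degenerate")
})

test_that("surface area follows the face-complete apportionment rule", {
  tri <- triangle_mesh()
  expect_equal(surface_area(tri), 0.5)              # 10x10/2 mm^2 = 0.5 cm^2
  expect_equal(surface_area(tri, c(1, 2)), 0)       # face not complete
  expect_warning(a0 <- surface_area(tri, integer(0)), "empty")
  expect_equal(a0, 0)

  m <- fixture_mesh(200)
  areas <- rvatlas:::face_areas(m)
  expect_equal(surface_area(m), sum(areas) / 100)
  # random subset equals brute-force per-face membership sum
  set.seed(5)
  sub <- sample(nrow(m$vertices), 80)
  inset <- seq_len(nrow(m$vertices)) %in% sub
  oracle <- sum(areas[inset[m$faces[, 1]] & inset[m$faces[, 2]] &
                        inset[m$faces[, 3]]]) / 100
  expect_equal(surface_area(m, sub), oracle)
})

test_that("surface area is additive and rigid-invariant", {
  m <- fixture_mesh(200)
  # two disjoint face-complete subsets: split faces by index parity
  f1 <- m$faces[seq(1, nrow(m$faces), 2), ]
  v1 <- sort(unique(as.integer(f1)))
  v2 <- setdiff(seq_len(nrow(m$vertices)), v1)
  expect_lte(surface_area(m, v1) + suppressWarnings(surface_area(m, v2)),
             surface_area(m) + 1e-9)
  set.seed(2)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  m2 <- m
  m2$vertices <- m$vertices %*% R + matrix(c(5, -3, 2), nrow(m$vertices), 3,
                                           byrow = TRUE)
  expect_equal(surface_area(m2), surface_area(m), tolerance = 1e-9)
})

test_that("axial coordinate parameterises base to apex", {
  m <- fixture_mesh(200)
  ax <- axial_coordinate(m)
  expect_equal(ax$fraction[m$apex], 1)
  expect_equal(ax$distance_from_apex[m$apex], 0)
  expect_equal(max(ax$fraction[m$annulus]), 0, tolerance = 1e-12)
  expect_true(all(ax$distance_from_apex >= 0))

  # analytic projection oracle: a vertex placed exactly at mid-axis height
  mid <- rv_mesh(rbind(c(0, 0, 20), c(10, 0, 0), c(-5, 8, 0), c(7, -2, 10)),
                 rbind(c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)),
                 apex = 1L, annulus = c(2L, 3L))
  axm <- axial_coordinate(mid)
  base <- colMeans(mid$vertices[2:3, ])
  expect_equal(axm$fraction[4],
               sum((mid$vertices[4, ] - base) * (mid$vertices[1, ] - base)) /
                 sum((mid$vertices[1, ] - base)^2),
               tolerance = 1e-9)

  # fractions invariant under rigid transformation
  set.seed(3)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  m2 <- m
  m2$vertices <- m$vertices %*% R + matrix(c(1, 2, 3), nrow(m$vertices), 3,
                                           byrow = TRUE)
  expect_equal(axial_coordinate(m2)$fraction, ax$fraction, tolerance = 1e-9)

  degenerate <- rv_mesh(rbind(c(0, 0, 0), c(1e-12, 0, 0), c(1, 0, 0)),
                        rbind(c(1, 2, 3)), apex = 1L, annulus = 2L)
  expect_error(axial_coordinate(degenerate), "zero-length")
})

test_that("plane vertices match a brute-force distance filter", {
  tri <- triangle_mesh()  # plane z = 0, all vertices on it
  expect_setequal(plane_vertices(tri, 2), 1:3)
  tri2 <- tri
  tri2$vertices[2, 3] <- 4  # 2 x tolerance away
  expect_false(2L %in% plane_vertices(tri2, 2))

  m <- fixture_mesh(300)
  tol <- 2
  idx <- plane_vertices(m, tol)
  oracle <- which(abs(m$vertices %*% m$plane$normal -
                        sum(m$plane$point * m$plane$normal)) <= tol)
  expect_setequal(idx, oracle)

  far <- rv_mesh(rbind(c(0, 0, 50), c(10, 0, 50), c(0, 10, 50)),
                 rbind(c(1, 2, 3)), apex = 1L, annulus = c(2L, 3L),
                 plane_point = c(0, 0, 0), plane_normal = c(0, 0, 1))
  expect_warning(res <- plane_vertices(far, 1), "no vertices")
  expect_length(res, 0)
})

test_that("correspondence distance summaries match a brute-force loop", {
  m <- fixture_mesh(150)
  same <- mean_correspondence_distance(m$vertices, m$vertices)
  expect_equal(same$mean, 0)
  expect_equal(same$sd, 0)

  shifted <- sweep(m$vertices, 2, c(-1, 0, 0))
  tr <- mean_correspondence_distance(m$vertices, shifted)
  expect_equal(tr$mean, 1)
  expect_equal(tr$sd, 0)

  set.seed(4)
  pert <- m$vertices + matrix(rnorm(length(m$vertices), 0, 0.5),
                              ncol = 3)
  res <- mean_correspondence_distance(m$vertices, pert)
  dists <- vapply(seq_len(nrow(m$vertices)), function(i) {
    sqrt(sum((m$vertices[i, ] - pert[i, ])^2))
  }, numeric(1))
  expect_equal(res$distances, dists)
  expect_equal(res$mean, mean(dists))
  expect_true(res$ci95[1] < res$mean && res$mean < res$ci95[2])

  expect_error(mean_correspondence_distance(m$vertices, m$vertices[-1, ]),
               "not corresponded")
})

test_that("VTK and PLY round-trips preserve geometry, landmarks and plane", {
  m <- fixture_mesh(120)
  tmp <- withr::local_tempdir()
  vtk <- file.path(tmp, "mesh.vtk")
  write_vtk(m, vtk, point_data = list(q = runif(nrow(m$vertices))))
  m2 <- read_vtk(vtk)
  expect_s3_class(m2, "rv_mesh")
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(m2$faces, m$faces)
  expect_identical(m2$apex, m$apex)
  expect_setequal(m2$annulus, m$annulus)
  expect_equal(m2$plane$normal, m$plane$normal, tolerance = 1e-9)

  ply <- file.path(tmp, "mesh.ply")
  write_ply(m, ply)
  m3 <- read_ply(ply)
  expect_equal(m3$vertices, m$vertices, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(m3$faces, m$faces)
})
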