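test_that("excursion vectors and norms match a per-vertex loop", {
  m <- fixture_mesh(150)
  still <- motion_field(m$vertices, m$vertices)
  exc0 <- compute_excursion(still)
  expect_equal(exc0$scalars, rep(0, nrow(m$vertices)))

  shifted <- motion_field(m$vertices, sweep(m$vertices, 2, c(-3, -4, 0)))
  expect_equal(compute_excursion(shifted)$scalars,
               rep(5, nrow(m$vertices)))  # 3-4-5

  set.seed(8)
  es <- m$vertices + matrix(rnorm(length(m$vertices)), ncol = 3)
  exc <- compute_excursion(motion_field(m$vertices, es))
  loop <- vapply(seq_len(nrow(m$vertices)), function(i) {
    sqrt(sum((es[i, ] - m$vertices[i, ])^2))
  }, numeric(1))
  expect_equal(exc$scalars, loop)

  bad <- es; bad[7, 2] <- NaN
  expect_error(compute_excursion(motion_field(m$vertices, bad)), "vertex")
})

test_that("local frames are orthonormal and anatomically oriented", {
  m <- fixture_mesh(200)
  fr <- local_frames(m)
  n <- nrow(m$vertices)
  expect_equal(rowSums(fr$longitudinal * fr$transverse), rep(0, n),
               tolerance = 1e-9)
  expect_equal(rowSums(fr$longitudinal * fr$circumferential), rep(0, n),
               tolerance = 1e-9)
  expect_equal(rowSums(fr$transverse * fr$circumferential), rep(0, n),
               tolerance = 1e-9)
  expect_equal(rowSums(fr$transverse^2), rep(1, n), tolerance = 1e-9)

  # axis is +z (base at z=0, apex above); a vertex on the +x side must have
  # transverse // +x, circumferential // +y, longitudinal // +z
  vx <- which.max(m$vertices[, 1] - abs(m$vertices[, 2]))
  expect_equal(fr$longitudinal[vx, ], c(0, 0, 1), tolerance = 1e-9)
  expect_equal(fr$transverse[vx, 1], 1, tolerance = 1e-6)
  expect_equal(abs(fr$circumferential[vx, 2]), 1, tolerance = 1e-6)

  # apex lies on the axis: flagged, arbitrary perpendicular frame
  expect_true(fr$on_axis[m$apex])

  # equivariance: rotating the mesh rotates the frames
  set.seed(9)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  m2 <- m
  m2$vertices <- m$vertices %*% R
  fr2 <- local_frames(m2)
  off_axis <- !fr$on_axis
  expect_equal(fr2$transverse[off_axis, ],
               (fr$transverse %*% R)[off_axis, ], tolerance = 1e-9)
  expect_equal(fr2$circumferential[off_axis, ],
               (fr$circumferential %*% R)[off_axis, ], tolerance = 1e-9)
})

test_that("directional decomposition recovers pure and mixed motion", {
  m <- fixture_mesh(200)
  fr <- local_frames(m)
  n <- nrow(m$vertices)

  axial_only <- 4 * fr$longitudinal
  comp <- decompose_excursion(axial_only, fr)
  expect_equal(unname(comp$composition),
               c(100, 0, 0))
  expect_equal(comp$components[, "longitudinal"], rep(4, n),
               tolerance = 1e-9)

  mixed <- 3 * fr$longitudinal + 3 * fr$transverse
  comp45 <- decompose_excursion(mixed, fr)
  expect_equal(comp45$composition[["longitudinal"]],
               comp45$composition[["transverse"]])

  # recomposition reproduces the displacement vectors
  set.seed(10)
  coefs <- matrix(rnorm(3 * n), n)
  v <- coefs[, 1] * fr$longitudinal + coefs[, 2] * fr$transverse +
    coefs[, 3] * fr$circumferential
  cc <- decompose_excursion(v, fr)$components
  rebuilt <- cc[, 1] * fr$longitudinal + cc[, 2] * fr$transverse +
    cc[, 3] * fr$circumferential
  expect_equal(rebuilt, v, tolerance = 1e-9)
})

test_that("generator round-trip recovers the planted directional mix", {
  co <- fixture_cohort(n_subjects = 300, n_vertices = 350, effect_size = 0.3,
                       seed = 21)
  comp <- decompose_excursion(lapply(co$motions, function(mo) mo$es - mo$ed),
                              co$frames, region = co$patch_vertices)
  # planted patch mix: 38 transverse / 35 longitudinal / 27 circumferential
  expect_equal(comp$composition[["transverse"]], 38, tolerance = 2 / 38)
  expect_equal(comp$composition[["longitudinal"]], 35, tolerance = 2 / 35)
  expect_equal(comp$composition[["circumferential"]], 27, tolerance = 2 / 27)

  # composition is invariant under a joint rigid transformation
  set.seed(11)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  m2 <- co$mesh
  m2$vertices <- co$mesh$vertices %*% R
  fr2 <- local_frames(m2)
  vec2 <- lapply(co$motions[1:30], function(mo) (mo$es - mo$ed) %*% R)
  vec1 <- lapply(co$motions[1:30], function(mo) mo$es - mo$ed)
  expect_equal(decompose_excursion(vec2, fr2, co$patch_vertices)$composition,
               decompose_excursion(vec1, co$frames,
                                   co$patch_vertices)$composition,
               tolerance = 1e-6)

  summ <- component_summary(co$motions[1:40] |>
                              lapply(function(mo) mo$es - mo$ed),
                            co$frames, co$patch_vertices)
  expect_identical(summ$component,
                   c("longitudinal", "transverse", "circumferential"))
  expect_true(all(summ$q25 <= summ$median & summ$median <= summ$q75))
})
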