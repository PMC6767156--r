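# Synthetic RV cohort generator. Emulates the statistical structure the
# discovery/validation pipeline assumes: a corresponded half-ellipsoid RV
# wall, a contiguous basal-freewall patch whose excursion is linearly
# coupled to RVEF under covariate confounding, spatially correlated
# residual motion noise, apex-to-base variation in directional motion
# composition, marker columns drawn jointly with RVEF from a Gaussian
# copula, and repeat scans with additive measurement noise.

split_seed <- function(seed, n) {
  # documented splitting scheme: one call to the base RNG seeded with the
  # global seed yields the sub-stream seeds, all < 2^31
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate a half-ellipsoid RV wall mesh
#'
#' A structured triangulation of an open half ellipsoid standing in for
#' the corresponded RV-wall atlas surface: apex pole at `(0, 0,
#' axis_length)`, tricuspid-annulus rim in the plane `z = 0`, long axis
#' along z. The four-chamber plane is the plane containing the long axis
#' and the freewall direction (+x), i.e. `y = 0`; the freewall is the
#' `x > 0` half. Fully deterministic; `seed` is accepted for interface
#' uniformity with the other generators.
#'
#' @param n_vertices approximate vertex count (>= 50); the realised count
#'   is `n_rings * n_cols + 1`.
#' @param axis_length apex-to-base length c (mm).
#' @param radius basal radius a (mm).
#' @param seed unused (determinism placeholder).
#' @return An [rv_mesh].
#' @export
generate_mesh <- function(n_vertices = 1000, axis_length = 85, radius = 30,
                          seed = 1) {
  if (n_vertices < 50) stop("n_vertices must be >= 50")
  if (axis_length <= 0 || radius <= 0) stop("infeasible mesh parameters")
  m <- max(8L, round(sqrt(2 * n_vertices)))
  nr <- max(4L, round((n_vertices - 1) / m))
  theta <- seq_len(nr) / nr * (pi / 2)  # ring nr = rim
  phi <- (seq_len(m) - 1) / m * 2 * pi  # column 1 lies exactly in y = 0, x > 0
  verts <- matrix(0, nr * m + 1, 3)
  verts[1, ] <- c(0, 0, axis_length)  # apex pole
  for (i in seq_len(nr)) {
    rows <- 1L + (i - 1L) * m + seq_len(m)
    verts[rows, ] <- cbind(radius * sin(theta[i]) * cos(phi),
                           radius * sin(theta[i]) * sin(phi),
                           axis_length * cos(theta[i]))
  }
  idx <- function(i, j) 1L + (i - 1L) * m + ((j - 1L) %% m) + 1L
  faces <- vector("list", nr)
  j <- seq_len(m)
  faces[[1]] <- cbind(1L, idx(1L, j), idx(1L, j + 1L))  # apex fan
  for (i in seq_len(nr - 1L)) {
    faces[[i + 1L]] <- rbind(cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
                             cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  }
  faces <- do.call(rbind, faces)
  rv_mesh(verts, faces, apex = 1L,
          annulus = 1L + (nr - 1L) * m + seq_len(m),
          plane_point = c(0, 0, 0), plane_normal = c(0, 1, 0))
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the emulated study conditions: covariate marginals from
#' a healthy adult volunteer cohort (age uniform 19--72 y, 55% female, BSA
#' N(1.80, 0.15) m^2, six race categories), RVEF normal with median 57%
#' and IQR 52--62% truncated to 40--73%, a basal-freewall signal patch of
#' geodesic radius 15 mm centred at 43% of the base-to-apex distance on
#' the four-chamber line, spatial noise SD 1 mm with squared-exponential
#' correlation length 10 mm, directional composition transitioning so the
#' patch mixes ~38/35/27% transverse/longitudinal/circumferential motion,
#' and marker--RVEF copula correlations 0.44/0.43/0.40/0.24/0.22 for
#' SPM-O/SFD-F/TAPSE-F/TAPSE/SFD with residual structure giving pairwise
#' marker correlations of about 0.5.
#'
#' @param n_subjects cohort size.
#' @param n_vertices approximate mesh size.
#' @param axis_length,radius mesh dimensions (mm).
#' @param patch_center_fraction base-to-apex fraction of the planted patch
#'   centre (0 = base, 1 = apex).
#' @param patch_radius geodesic radius of the planted patch (mm).
#' @param effect_size planted per-vertex partial correlation between patch
#'   excursion and RVEF given covariates (0 = null generator).
#' @param noise_sd,noise_length residual motion noise SD (mm) and
#'   squared-exponential correlation length (mm).
#' @param excursion_age_effect age confounding on excursion (mm per SD age).
#' @param rvef_age_effect,rvef_sex_effect standardised effects of age and
#'   male sex on latent RVEF.
#' @param rvef_mean,rvef_sd,rvef_range RVEF marginal (%): normal truncated
#'   to the range.
#' @param edv_index_mean,edv_index_sd end-diastolic volume index marginal
#'   (ml m^-2), multiplied by BSA to give EDV.
#' @param baseline_apex,baseline_base baseline excursion profile (mm) at
#'   apex and base; linear in the axial fraction.
#' @param marker_cor named target marker--RVEF correlations.
#' @param marker_marker_cor target pairwise correlation between markers.
#' @param marker_scale named list of `c(mean, sd)` clinical scales.
#' @param sex_p_female,age_range,bsa_mean,bsa_sd,race_probs covariate
#'   marginals.
#' @param with_motion build per-subject ED/ES motion fields (memory cost);
#'   the excursion matrix is always built.
#' @param seed global seed; sub-generators get seeds via a fixed
#'   splitting scheme.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_subjects = 300, n_vertices = 1000,
                             axis_length = 85, radius = 30,
                             patch_center_fraction = 0.43, patch_radius = 15,
                             effect_size = 0.3,
                             noise_sd = 1, noise_length = 10,
                             excursion_age_effect = -0.1,
                             rvef_age_effect = -0.24, rvef_sex_effect = 0.17,
                             rvef_mean = 57, rvef_sd = 7.4,
                             rvef_range = c(40, 73),
                             edv_index_mean = 78, edv_index_sd = 10,
                             baseline_apex = 3, baseline_base = 11,
                             marker_cor = c(SPM_O = 0.44, SFD_F = 0.43,
                                            TAPSE_F = 0.40, TAPSE = 0.24,
                                            SFD = 0.22),
                             marker_marker_cor = 0.5,
                             marker_scale = list(
                               SPM_O = c(14, 3), SFD_F = c(20, 5),
                               TAPSE_F = c(17, 3), TAPSE = c(24, 3.5),
                               SFD = c(12, 3)),
                             sex_p_female = 0.55, age_range = c(19, 72),
                             bsa_mean = 1.80, bsa_sd = 0.15,
                             race_probs = c(Caucasian = 0.75, Asian = 0.12,
                                            AfroCaribbean = 0.05,
                                            African = 0.03, Other = 0.03,
                                            Chinese = 0.02),
                             with_motion = TRUE, seed = 1) {
  stopifnot(noise_sd >= 0, noise_length > 0, patch_radius > 0,
            effect_size >= 0, effect_size < 1,
            all(abs(marker_cor) < 1))
  cfg <- as.list(environment())
  class(cfg) <- "generator_config"
  cfg
}

# residual correlation structure of the marker copula given RVEF; errors
# before sampling if the implied joint correlation matrix is not PSD
marker_residual_chol <- function(rho, target) {
  k <- length(rho)
  C <- diag(k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    C[i, j] <- C[j, i] <-
      (target - rho[i] * rho[j]) / sqrt((1 - rho[i]^2) * (1 - rho[j]^2))
  }
  full <- rbind(c(1, rho), cbind(rho, outer(rho, rho) +
                                   C * outer(sqrt(1 - rho^2), sqrt(1 - rho^2))))
  if (min(eigen(full, symmetric = TRUE, only.values = TRUE)$values) < 1e-10) {
    stop("target marker correlation matrix is not positive semi-definite")
  }
  chol(C)
}

# Cholesky factor of the squared-exponential spatial noise covariance;
# reusable across replicates that share a mesh
#' Spatial-noise Cholesky factor for a mesh
#'
#' Upper-triangular Cholesky factor of the squared-exponential covariance
#' `noise_sd^2 * exp(-d^2 / (2 * noise_length^2))` over inter-vertex
#' Euclidean distances. Expensive for large meshes; compute once and pass
#' to [generate_cohort()] when simulating many replicates on one mesh.
#'
#' @param mesh an [rv_mesh].
#' @param noise_sd,noise_length kernel parameters (mm).
#' @return Upper-triangular matrix `R` with `t(R) %*% R` the covariance.
#' @export
spatial_noise_chol <- function(mesh, noise_sd = 1, noise_length = 10) {
  d2 <- as.matrix(stats::dist(mesh$vertices))^2
  K <- noise_sd^2 * exp(-d2 / (2 * noise_length^2))
  chol(K + diag(1e-8, nrow(K)))
}

# planted-patch vertex set: geodesic ball around the vertex closest to the
# requested axial fraction on the freewall four-chamber line; chordal
# Euclidean distance approximates the surface geodesic on this gently
# curved shell (graph-path distance would overestimate it by the lattice
# factor and shrink the ball)
plant_patch <- function(mesh, adjacency, axial, center_fraction, radius_mm) {
  v <- mesh$vertices
  score <- (axial$fraction - center_fraction)^2 + (v[, 2] / max(abs(v[, 1])))^2
  score[v[, 1] <= 0] <- Inf  # freewall side only
  center <- which.min(score)
  d <- sqrt(rowSums((v - matrix(v[center, ], nrow(v), 3, byrow = TRUE))^2))
  ball <- which(d <= radius_mm)
  # keep the ball contiguous in mesh adjacency (it is, except in
  # pathological low-resolution meshes)
  sub <- igraph::induced_subgraph(adjacency$graph, ball)
  comp <- igraph::components(sub)
  keep <- comp$membership == comp$membership[match(center, ball)]
  list(center = center, vertices = ball[keep])
}

# apex-to-base directional weights: longitudinal share grows toward the
# base, circumferential roughly constant; at the patch centre fraction
# (0.43) the shares are 0.35/0.38/0.27 long/trans/circ
direction_weights <- function(fraction) {
  wl <- pmin(0.6, pmax(0.1, 0.5 - 0.35 * fraction))
  wc <- rep(0.27, length(fraction))
  wt <- 1 - wl - wc
  cbind(longitudinal = wl, transverse = wt, circumferential = wc)
}

#' Generate a synthetic cohort
#'
#' Draws covariates, latent RVEF, volumes, the subjects x vertices
#' excursion matrix with a planted RVEF-coupled patch and spatially
#' correlated noise, marker columns from the Gaussian copula, and
#' (optionally) per-subject ED/ES motion fields consistent with the
#' excursion matrix and directional weights.
#'
#' @param config a [generator_config()].
#' @param mesh optional precomputed [rv_mesh] (must match
#'   `config$n_vertices` parameters); generated when `NULL`.
#' @param noise_chol optional precomputed [spatial_noise_chol()] factor.
#' @return An object of class `rv_cohort`; see Details.
#' @details The returned list contains `mesh`, `axial`, `frames`,
#'   `adjacency`, `patch_vertices` and `patch_center` (the planted patch),
#'   `excursion` (n x V mm), `covariates` (data.frame: age, sex, race,
#'   bsa), `rvef`, `edv`, `esv`, `markers` (data.frame of the five marker
#'   columns), `direction` (V x 3 unit motion directions), `motions`
#'   (list of [motion_field] or `NULL`), and `config`.
#' @export
generate_cohort <- function(config, mesh = NULL, noise_chol = NULL) {
  cfg <- config
  seeds <- split_seed(cfg$seed, 6L)
  if (is.null(mesh)) {
    mesh <- generate_mesh(cfg$n_vertices, cfg$axis_length, cfg$radius,
                          seed = seeds[1])
  }
  V <- nrow(mesh$vertices)
  axial <- axial_coordinate(mesh)
  frames <- local_frames(mesh)
  adjacency <- build_adjacency(mesh)
  planted <- plant_patch(mesh, adjacency, axial,
                         cfg$patch_center_fraction, cfg$patch_radius)

  n <- cfg$n_subjects
  # --- covariates -----------------------------------------------------
  set.seed(seeds[2])
  age <- stats::runif(n, cfg$age_range[1], cfg$age_range[2])
  sex <- factor(ifelse(stats::runif(n) < cfg$sex_p_female, "F", "M"),
                levels = c("F", "M"))
  race <- factor(sample(names(cfg$race_probs), n, replace = TRUE,
                        prob = cfg$race_probs),
                 levels = names(cfg$race_probs))
  bsa <- stats::rnorm(n, cfg$bsa_mean, cfg$bsa_sd)
  bsa <- pmax(bsa, 1.2)
  covariates <- data.frame(age = age, sex = sex, race = race, bsa = bsa)

  # --- latent RVEF with covariate structure, truncated marginal -------
  set.seed(seeds[3])
  z_age <- as.numeric(scale(age))
  z_sex <- as.numeric(scale(as.integer(sex == "M")))
  a1 <- cfg$rvef_age_effect; a2 <- cfg$rvef_sex_effect
  s_resid <- sqrt(max(1e-6, 1 - a1^2 - a2^2))
  e <- stats::rnorm(n)
  z_r <- a1 * z_age + a2 * z_sex + s_resid * e
  rvef <- cfg$rvef_mean + cfg$rvef_sd * z_r
  # redraw the residual where RVEF falls outside the physiological range
  for (iter in 1:100) {
    out <- rvef < cfg$rvef_range[1] | rvef > cfg$rvef_range[2]
    if (!any(out)) break
    e[out] <- stats::rnorm(sum(out))
    z_r[out] <- a1 * z_age[out] + a2 * z_sex[out] + s_resid * e[out]
    rvef[out] <- cfg$rvef_mean + cfg$rvef_sd * z_r[out]
  }
  rvef <- pmin(pmax(rvef, cfg$rvef_range[1]), cfg$rvef_range[2])
  z_r <- (rvef - cfg$rvef_mean) / cfg$rvef_sd
  edv <- bsa * stats::rnorm(n, cfg$edv_index_mean, cfg$edv_index_sd)
  esv <- edv * (1 - rvef / 100)

  # --- excursion matrix ----------------------------------------------
  set.seed(seeds[4])
  if (is.null(noise_chol)) {
    noise_chol <- spatial_noise_chol(mesh, cfg$noise_sd, cfg$noise_length)
  }
  noise <- matrix(stats::rnorm(n * V), n, V) %*% noise_chol
  b <- cfg$baseline_apex +
    (cfg$baseline_base - cfg$baseline_apex) * (1 - axial$fraction)
  rho <- cfg$effect_size
  gamma <- if (rho > 0) cfg$noise_sd * rho / (s_resid * sqrt(1 - rho^2)) else 0
  excursion <- matrix(b, n, V, byrow = TRUE) +
    cfg$excursion_age_effect * outer(z_age, rep(1, V)) + noise
  if (gamma > 0) {
    excursion[, planted$vertices] <- excursion[, planted$vertices] +
      gamma * outer(z_r, rep(1, length(planted$vertices)))
  }
  excursion <- pmax(excursion, 0.01)  # excursion is a displacement norm
  dimnames(excursion) <- NULL

  # --- markers from the Gaussian copula -------------------------------
  set.seed(seeds[5])
  rho_m <- cfg$marker_cor
  Rc <- marker_residual_chol(rho_m, cfg$marker_marker_cor)
  U <- matrix(stats::rnorm(n * length(rho_m)), n) %*% Rc
  M <- outer(z_r, rho_m) + U %*% diag(sqrt(1 - rho_m^2))
  markers <- as.data.frame(mapply(function(col, sc) sc[1] + sc[2] * col,
                                  as.data.frame(M),
                                  cfg$marker_scale[names(rho_m)]))
  names(markers) <- names(rho_m)

  # --- motion fields consistent with the excursion matrix -------------
  w <- direction_weights(axial$fraction)
  u <- w[, "longitudinal"] * frames$longitudinal -
    w[, "transverse"] * frames$transverse +
    w[, "circumferential"] * frames$circumferential
  u <- u / sqrt(rowSums(u^2))
  motions <- NULL
  if (isTRUE(cfg$with_motion)) {
    motions <- lapply(seq_len(n), function(s) {
      motion_field(mesh$vertices, mesh$vertices + excursion[s, ] * u,
                   subject_id = sprintf("S%03d", s))
    })
  }

  structure(list(mesh = mesh, axial = axial, frames = frames,
                 adjacency = adjacency,
                 patch_vertices = planted$vertices,
                 patch_center = planted$center,
                 excursion = excursion, covariates = covariates,
                 rvef = rvef, edv = edv, esv = esv, markers = markers,
                 direction = u, motions = motions, config = cfg),
            class = "rv_cohort")
}

#' @export
print.rv_cohort <- function(x, ...) {
  cat("rv_cohort:", nrow(x$excursion), "subjects x", ncol(x$excursion),
      "vertices; planted patch:", length(x$patch_vertices),
      "vertices (effect size", x$config$effect_size, ")\n")
  invisible(x)
}

#' Generate a repeat-scan replicate
#'
#' A second acquisition of the same subjects: the excursion matrix plus
#' independent vertex-wise noise, and re-measured volumes with noise on
#' the BSA-indexed scale. Defaults emulate high test-retest fidelity of
#' volumetry and slightly lower fidelity of pointwise excursion.
#'
#' @param cohort an `rv_cohort`.
#' @param excursion_sd per-vertex replicate noise SD (mm).
#' @param volume_index_sd replicate noise SD of the EDV index (ml m^-2).
#' @param seed RNG seed.
#' @return List with `excursion` (replicate matrix), `edv`, `esv`,
#'   `rvef`, and `volume_index` (replicate EDV index).
#' @export
generate_repeat_scan <- function(cohort, excursion_sd = 0.28,
                                 volume_index_sd = 1, seed = 1) {
  stopifnot(excursion_sd >= 0, volume_index_sd >= 0)
  set.seed(seed)
  n <- nrow(cohort$excursion); V <- ncol(cohort$excursion)
  exc2 <- cohort$excursion + matrix(stats::rnorm(n * V, 0, excursion_sd), n, V)
  bsa <- cohort$covariates$bsa
  edv2 <- cohort$edv + bsa * stats::rnorm(n, 0, volume_index_sd)
  esv2 <- cohort$esv + bsa * stats::rnorm(n, 0, volume_index_sd)
  esv2 <- pmin(pmax(esv2, 0), edv2)
  list(excursion = exc2, edv = edv2, esv = esv2,
       rvef = 100 * (edv2 - esv2) / edv2,
       volume_index = edv2 / bsa)
}
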