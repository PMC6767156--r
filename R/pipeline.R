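# End-to-end orchestration: the discovery arm (pointwise map -> FDR ->
# patch -> PCA -> SPM-O) and the validation arm (marker comparison
# battery), with a run manifest for reproducibility.

#' Run the discovery pipeline
#'
#' Chains the pointwise covariate-adjusted regression, Freedman-Lane
#' permutation p-values, BH-FDR, contiguous-patch extraction, patch PCA,
#' PC1 reconstruction correlation, and SPM-O selection in the
#' four-chamber plane. An empty significance mask yields a result with
#' `patch$empty = TRUE` and no marker, not an error.
#'
#' @param cohort an `rv_cohort` (or a list with `mesh`, `excursion`,
#'   `covariates`, `rvef`).
#' @param alpha FDR significance level for the mask (default 0.05).
#' @param n_perm permutations (default 10,000).
#' @param n_boot bootstrap replicates for the pointwise CIs (default
#'   10,000; 0 skips them).
#' @param plane_tolerance point-plane distance tolerance in mm (default
#'   2, one acquisition voxel).
#' @param perm_seed,boot_seed RNG seeds for the two resampling stages.
#' @param out_dir optional directory for artefacts (per-vertex CSV, VTK
#'   scalar fields, patch/marker JSON, manifest).
#' @return List of class `rv_discovery`: `fit`, `perm`, `q`, `mask`,
#'   `patch`, `pca`, `reconstruction_r`, `marker`, `composition`,
#'   `pc1_rvef` (correlation and regression of RVEF on the PC1 score),
#'   `manifest`.
#' @export
run_discovery <- function(cohort, alpha = 0.05, n_perm = 10000,
                          n_boot = 10000, plane_tolerance = 2,
                          perm_seed = 11, boot_seed = 12, out_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  mesh <- cohort$mesh
  axial <- cohort$axial %||% axial_coordinate(mesh)
  adjacency <- cohort$adjacency %||% build_adjacency(mesh)
  fit <- fit_pointwise(cohort$excursion, cohort$covariates, cohort$rvef,
                       n_boot = n_boot, seed = boot_seed)
  perm <- permutation_pvalues(cohort$excursion, cohort$covariates,
                              cohort$rvef, n_perm = n_perm, seed = perm_seed)
  q <- fdr_adjust(perm$p)
  mask <- q < alpha
  patch <- extract_patch(mask, mesh, axial, adjacency)
  pca <- NULL; recon <- NULL; marker <- NULL
  composition <- NULL; pc1_rvef <- NULL
  if (!patch$empty && length(patch$vertices) >= 2) {
    xp <- cohort$excursion[, patch$vertices, drop = FALSE]
    pca <- patch_pca(xp)
    recon <- reconstruction_correlation(pca, xp, k = 1)
    plane_set <- plane_vertices(mesh, tolerance = plane_tolerance)
    marker <- tryCatch(
      select_spm_o(recon, patch, plane_set, axial),
      error = function(e) {
        warning(conditionMessage(e)); NULL
      })
    pc1 <- pca$scores[, 1]
    ct <- pearson_cor(pc1, cohort$rvef)
    reg <- covariate_regression(pc1, cohort$covariates, cohort$rvef,
                                n_boot = 0)
    pc1_rvef <- list(r = ct$r, p = ct$p, f_marker = reg$f_marker,
                     variance_fractions = reg$variance_fractions)
    composition <- patch_composition(cohort, patch$vertices)
  }
  manifest <- list(n_subjects = nrow(cohort$excursion),
                   n_vertices = ncol(cohort$excursion),
                   alpha = alpha, n_perm = n_perm, n_boot = n_boot,
                   plane_tolerance = plane_tolerance,
                   perm_seed = perm_seed, boot_seed = boot_seed,
                   generator_seed = cohort$config$seed %||% NA,
                   elapsed_s = proc.time()[["elapsed"]] - t0)
  res <- structure(list(fit = fit, perm = perm, q = q, mask = mask,
                        patch = patch, pca = pca,
                        reconstruction_r = recon, marker = marker,
                        composition = composition, pc1_rvef = pc1_rvef,
                        manifest = manifest),
                   class = "rv_discovery")
  if (!is.null(out_dir)) write_discovery(res, cohort, out_dir)
  res
}

# directional composition of motion over a vertex region, pooled across
# subjects; uses stored motion fields when present, otherwise rebuilds
# displacement vectors from the excursion matrix and direction field
patch_composition <- function(cohort, region) {
  frames <- cohort$frames %||% local_frames(cohort$mesh)
  if (!is.null(cohort$motions)) {
    vecs <- lapply(cohort$motions, function(m) m$es - m$ed)
  } else if (!is.null(cohort$direction)) {
    vecs <- lapply(seq_len(nrow(cohort$excursion)), function(s) {
      cohort$excursion[s, ] * cohort$direction
    })
  } else {
    return(NULL)
  }
  decompose_excursion(vecs, frames, region = region)$composition
}

#' @export
print.rv_discovery <- function(x, ...) {
  cat("rv_discovery (", x$manifest$n_subjects, "subjects,",
      x$manifest$n_vertices, "vertices )\n")
  print(x$patch)
  if (!is.null(x$marker)) print(x$marker)
  if (!is.null(x$pca)) {
    cat(sprintf("  PC1 explains %.1f%% of patch excursion variance\n",
                100 * x$pca$explained_variance_ratio[1]))
  }
  invisible(x)
}

write_discovery <- function(res, cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stats_df <- data.frame(vertex = seq_along(res$q),
                         slope = res$fit$slope,
                         ci_lo = res$fit$ci_lo, ci_hi = res$fit$ci_hi,
                         t = res$perm$t_obs, p = res$perm$p, q = res$q,
                         significant = res$mask)
  utils::write.csv(stats_df, file.path(out_dir, "pointwise_stats.csv"),
                   row.names = FALSE)
  write_vtk(cohort$mesh, file.path(out_dir, "map.vtk"),
            point_data = list(slope = ifelse(is.na(res$fit$slope), 0,
                                             res$fit$slope),
                              q = res$q,
                              significant = as.numeric(res$mask)))
  patch_json <- list(vertices = res$patch$vertices - 1L,
                     area_cm2 = res$patch$area_cm2,
                     fraction_of_surface = res$patch$fraction_of_surface,
                     apex_distance_range_cm = res$patch$apex_distance_range_cm,
                     empty = res$patch$empty)
  jsonlite::write_json(patch_json, file.path(out_dir, "patch.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(res$marker)) {
    write_marker_json(res$marker, file.path(out_dir, "marker.json"))
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Run the validation pipeline
#'
#' Evaluates every marker column against RVEF: Pearson correlation,
#' Steiger test against the reference marker, covariate-adjusted
#' bootstrapped regression with variance partitioning, leave-one-out
#' prediction errors (EF points and ml), and a Kruskal-Wallis comparison
#' of the absolute errors across markers.
#'
#' @param cohort an `rv_cohort` with a `markers` data.frame, `rvef`,
#'   `edv`, `covariates`.
#' @param reference marker column used as the Steiger reference
#'   (default `"SPM_O"`).
#' @param n_boot bootstrap replicates for regression CIs.
#' @param boot_seed bootstrap seed.
#' @param loo run the leave-one-out analysis (default TRUE).
#' @param out_dir optional artefact directory (JSON + CSV tables).
#' @return List of class `rv_validation`: `correlations` (data.frame),
#'   `steiger` (data.frame), `regressions` (list of `marker_fit`),
#'   `variance_fractions` (matrix), `loo` (list of `loo_result`),
#'   `loo_summary` (data.frame), `kruskal`, `manifest`.
#' @export
run_validation <- function(cohort, reference = "SPM_O", n_boot = 10000,
                           boot_seed = 21, loo = TRUE, out_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  markers <- cohort$markers
  if (!reference %in% names(markers)) {
    stop("missing marker column: ", reference)
  }
  nms <- names(markers)
  cors <- lapply(markers, pearson_cor, y = cohort$rvef)
  correlations <- data.frame(marker = nms,
                             r = vapply(cors, `[[`, 0, "r"),
                             p = vapply(cors, `[[`, 0, "p"),
                             row.names = NULL)
  n <- length(cohort$rvef)
  others <- setdiff(nms, reference)
  st <- lapply(others, function(m) {
    steiger_test(r_jk = correlations$r[correlations$marker == reference],
                 r_jh = correlations$r[correlations$marker == m],
                 r_kh = stats::cor(markers[[reference]], markers[[m]]),
                 n = n)
  })
  steiger <- data.frame(comparison = paste(reference, "vs", others),
                        z = vapply(st, `[[`, 0, "z"),
                        p = vapply(st, `[[`, 0, "p"), row.names = NULL)
  regressions <- lapply(nms, function(m) {
    covariate_regression(markers[[m]], cohort$covariates, cohort$rvef,
                         n_boot = n_boot, seed = boot_seed)
  })
  names(regressions) <- nms
  vf <- do.call(rbind, lapply(regressions, `[[`, "variance_fractions"))
  loo_res <- NULL; loo_summary <- NULL; kruskal <- NULL
  if (loo) {
    loo_res <- lapply(nms, function(m) {
      loo_predict(markers[[m]], cohort$covariates, cohort$rvef, cohort$edv)
    })
    names(loo_res) <- nms
    loo_summary <- do.call(rbind, lapply(nms, function(m) {
      s <- loo_res[[m]]$summary
      data.frame(marker = m,
                 median_ml = s["ml", "median"], q25_ml = s["ml", "q25"],
                 q75_ml = s["ml", "q75"], min_ml = s["ml", "min"],
                 max_ml = s["ml", "max"],
                 median_ef = s["ef_points", "median"])
    }))
    kruskal <- compare_errors_kruskal(lapply(loo_res, `[[`, "abs_error_ml"))
  }
  manifest <- list(n_subjects = n, reference = reference, n_boot = n_boot,
                   boot_seed = boot_seed,
                   generator_seed = cohort$config$seed %||% NA,
                   elapsed_s = proc.time()[["elapsed"]] - t0)
  res <- structure(list(correlations = correlations, steiger = steiger,
                        regressions = regressions,
                        variance_fractions = vf, loo = loo_res,
                        loo_summary = loo_summary, kruskal = kruskal,
                        manifest = manifest),
                   class = "rv_validation")
  if (!is.null(out_dir)) write_validation(res, out_dir)
  res
}

#' @export
print.rv_validation <- function(x, ...) {
  cat("rv_validation (", x$manifest$n_subjects, "subjects )\n")
  cat("Correlation with RVEF:\n")
  print(x$correlations[order(-x$correlations$r), ], row.names = FALSE)
  cat("Steiger tests vs", x$manifest$reference, ":\n")
  print(x$steiger, row.names = FALSE)
  if (!is.null(x$kruskal)) {
    cat(sprintf("Kruskal-Wallis on LOO |error| (ml): chi2 = %.2f, p = %.3g\n",
                x$kruskal$chi_squared, x$kruskal$p))
  }
  invisible(x)
}

write_validation <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$correlations,
                   file.path(out_dir, "marker_correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(res$steiger, file.path(out_dir, "steiger_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(marker = rownames(res$variance_fractions),
                              res$variance_fractions, row.names = NULL),
                   file.path(out_dir, "variance_fractions.csv"),
                   row.names = FALSE)
  if (!is.null(res$loo_summary)) {
    utils::write.csv(res$loo_summary, file.path(out_dir, "loo_errors.csv"),
                     row.names = FALSE)
  }
  report <- list(correlations = res$correlations, steiger = res$steiger,
                 variance_fractions = as.data.frame(res$variance_fractions),
                 loo_summary = res$loo_summary, kruskal = res$kruskal)
  jsonlite::write_json(report, file.path(out_dir, "validation_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
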