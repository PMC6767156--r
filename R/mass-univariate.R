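# Discovery stage: per-vertex covariate-adjusted association of systolic
# excursion with RVEF. All continuous variables are z-scored; categorical
# covariates are dummy-coded against their largest class. Per-vertex OLS
# is vectorised across vertices by Frisch-Waugh-Lovell residualisation:
# the excursion-term slope and t statistic of the full model equal those
# from regressing covariate-residualised RVEF on covariate-residualised
# excursion.

#' Standardised covariate design matrix
#'
#' z-scores continuous covariates and dummy-codes factors against their
#' largest class. Zero-variance columns (e.g. a single-level factor) are
#' dropped with a warning.
#'
#' @param covariates data.frame (e.g. age, sex, race, bsa).
#' @return Numeric matrix without intercept; column names follow
#'   `variable` or `variable.level`. Attribute `groups` maps columns back
#'   to source variables (used for variance partitioning).
#' @export
build_design <- function(covariates) {
  cols <- list(); groups <- character(0)
  for (nm in names(covariates)) {
    x <- covariates[[nm]]
    if (is.numeric(x)) {
      cols[[nm]] <- as.numeric(scale(x))
      groups <- c(groups, nm)
    } else {
      x <- droplevels(as.factor(x))
      if (nlevels(x) < 2) {
        warning("covariate '", nm, "' has a single level; dropped")
        next
      }
      ref <- names(which.max(table(x)))
      for (lev in setdiff(levels(x), ref)) {
        cols[[paste(nm, lev, sep = ".")]] <- as.numeric(x == lev)
        groups <- c(groups, nm)
      }
    }
  }
  X <- do.call(cbind, cols)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    drop <- which(sds == 0 | !is.finite(sds))
    warning("dropping zero-variance design columns: ",
            paste(colnames(X)[drop], collapse = ", "))
    groups <- groups[-drop]
    X <- X[, -drop, drop = FALSE]
  }
  attr(X, "groups") <- groups
  X
}

# shared FWL machinery: residualise y and the excursion columns on the
# covariates (with intercept), return per-vertex slopes and t statistics
fwl_stats <- function(E_res, e_y, df) {
  cx <- unname(colSums(E_res^2))
  num <- as.numeric(crossprod(E_res, e_y))
  slope <- num / cx
  sse <- sum(e_y^2) - slope^2 * cx
  sse[sse < 0] <- 0
  tval <- slope * sqrt(cx * df / pmax(sse, .Machine$double.eps))
  degenerate <- cx < 1e-12
  slope[degenerate] <- NA_real_
  tval[degenerate] <- NA_real_
  list(slope = slope, t = tval, cx = cx)
}

#' Pointwise bootstrapped regression of RVEF on vertex excursion
#'
#' For each vertex, OLS of standardised RVEF on standardised vertex
#' excursion plus the covariate design; the excursion-term slope is
#' retained with nonparametric subject-resampling percentile bootstrap
#' confidence intervals.
#'
#' @param excursion subjects x vertices matrix (mm).
#' @param covariates data.frame passed to [build_design()].
#' @param rvef numeric vector (%).
#' @param n_boot bootstrap replicates (default 10,000; set 0 to skip).
#' @param seed bootstrap RNG seed.
#' @param conf confidence level for the percentile interval.
#' @return List of class `pointwise_fit`: `slope`, `t`, `ci_lo`, `ci_hi`,
#'   `df`, `n`, `design` (the covariate matrix), `seed`.
#' @export
fit_pointwise <- function(excursion, covariates, rvef, n_boot = 10000,
                          seed = 1, conf = 0.95) {
  n <- nrow(excursion)
  if (any(is.na(excursion)) || any(is.na(rvef))) stop("missing values")
  Z <- cbind(`(Intercept)` = 1, build_design(covariates))
  if (n <= ncol(Z) + 2) stop("too few subjects for the covariate design")
  y <- as.numeric(scale(rvef))
  X <- scale(excursion)
  X[, attr(X, "scaled:scale") == 0] <- 0  # constant vertices -> NA slope
  qz <- qr(Z)
  e_y <- qr.resid(qz, y)
  E_res <- qr.resid(qz, X)
  df <- n - ncol(Z) - 1L
  obs <- fwl_stats(E_res, e_y, df)
  ci_lo <- ci_hi <- rep(NA_real_, ncol(X))
  if (n_boot > 0) {
    set.seed(seed)
    bs <- matrix(NA_real_, n_boot, ncol(X))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, replace = TRUE)
      qb <- qr(Z[idx, , drop = FALSE])
      eb <- qr.resid(qb, cbind(y[idx], X[idx, , drop = FALSE]))
      cxb <- colSums(eb[, -1, drop = FALSE]^2)
      bs[b, ] <- as.numeric(crossprod(eb[, -1, drop = FALSE], eb[, 1])) / cxb
    }
    a <- (1 - conf) / 2
    qs <- apply(bs, 2, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE,
                names = FALSE)
    ci_lo <- qs[1, ]; ci_hi <- qs[2, ]
  }
  structure(list(slope = obs$slope, t = obs$t, ci_lo = ci_lo, ci_hi = ci_hi,
                 df = df, n = n, n_boot = n_boot, seed = seed, conf = conf),
            class = "pointwise_fit")
}

#' Freedman-Lane permutation p-values for the excursion term
#'
#' Builds the null by regressing RVEF on the covariates alone, permuting
#' the residuals, adding them back to the reduced-model fit, and
#' recomputing the excursion-term |t| per vertex. The same permutation
#' sequence is shared across vertices, and
#' `p = (1 + #\{|t_perm| >= |t_obs|\}) / (1 + n_perm)`. Vertices with
#' (near-)constant excursion have undefined t and receive p = 1.
#'
#' @inheritParams fit_pointwise
#' @param n_perm number of permutations (>= 99).
#' @param block number of permutations processed per memory block.
#' @return List of class `pointwise_perm`: `p`, `t_obs`, `n_perm`, `seed`.
#' @export
permutation_pvalues <- function(excursion, covariates, rvef, n_perm = 10000,
                                seed = 1, block = 250) {
  if (n_perm < 99) warning("n_perm < 99 gives very coarse p-value resolution")
  n <- nrow(excursion)
  Z <- cbind(`(Intercept)` = 1, build_design(covariates))
  y <- as.numeric(scale(rvef))
  X <- scale(excursion)
  X[, attr(X, "scaled:scale") == 0] <- 0
  qz <- qr(Z)
  e_y <- qr.resid(qz, y)   # reduced-model residuals (fitted part is in span Z)
  E_res <- qr.resid(qz, X)
  df <- n - ncol(Z) - 1L
  obs <- fwl_stats(E_res, e_y, df)
  cx <- obs$cx
  degenerate <- cx < 1e-12
  exceed <- numeric(ncol(X))
  set.seed(seed)
  done <- 0L
  while (done < n_perm) {
    nb <- min(block, n_perm - done)
    P <- vapply(seq_len(nb), function(i) e_y[sample.int(n)], numeric(n))
    EP <- qr.resid(qz, P)                      # residualised pseudo-outcomes
    num <- crossprod(E_res, EP)                # V x nb
    ssy <- colSums(EP^2)
    denom <- outer(cx, ssy) - num^2
    tperm <- sqrt(df) * num / sqrt(pmax(denom, .Machine$double.eps))
    exceed <- exceed + rowSums(abs(tperm) >= abs(obs$t) - 1e-12)
    done <- done + nb
  }
  p <- unname((1 + exceed) / (1 + n_perm))
  p[degenerate] <- 1
  structure(list(p = p, t_obs = obs$t, n_perm = n_perm, seed = seed),
            class = "pointwise_perm")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p numeric p-values in \[0, 1\].
#' @return Step-up adjusted q-values (monotone).
#' @export
fdr_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Extract the significant contiguous patch
#'
#' Connected components of the significance mask under mesh adjacency;
#' the largest-area component (face-complete area rule) is the patch.
#' All components are reported. An empty mask yields an explicit
#' "no significant region" result rather than an error.
#'
#' @param mask logical per-vertex significance (e.g. `q < 0.05`).
#' @param mesh an [rv_mesh].
#' @param axial output of [axial_coordinate()] (computed when `NULL`).
#' @param adjacency output of [build_adjacency()] (computed when `NULL`).
#' @return Object of class `rv_patch`: `vertices`, `area_cm2`,
#'   `fraction_of_surface`, `apex_distance_range_cm`, `centroid`,
#'   `components` (data.frame of all components), `empty` flag.
#' @export
extract_patch <- function(mask, mesh, axial = NULL, adjacency = NULL) {
  if (is.null(axial)) axial <- axial_coordinate(mesh)
  if (is.null(adjacency)) adjacency <- build_adjacency(mesh)
  total <- surface_area(mesh)
  vids <- which(mask)
  if (length(vids) == 0L) {
    return(structure(list(vertices = integer(0), area_cm2 = 0,
                          fraction_of_surface = 0,
                          apex_distance_range_cm = c(NA_real_, NA_real_),
                          centroid = rep(NA_real_, 3),
                          components = data.frame(), empty = TRUE),
                     class = "rv_patch"))
  }
  sub <- igraph::induced_subgraph(adjacency$graph, vids)
  comp <- igraph::components(sub)
  members <- split(vids[seq_along(comp$membership)], comp$membership)
  areas <- unname(vapply(members, function(v) {
    suppressWarnings(surface_area(mesh, v))
  }, numeric(1)))
  ord <- order(-areas, vapply(members, min, integer(1)))
  components <- data.frame(
    component = seq_along(ord),
    n_vertices = vapply(members, length, integer(1))[ord],
    area_cm2 = areas[ord])
  best <- members[[ord[1]]]
  dr <- range(axial$distance_from_apex[best]) / 10  # mm -> cm
  structure(list(vertices = sort(best),
                 area_cm2 = areas[ord[1]],
                 fraction_of_surface = areas[ord[1]] / total,
                 apex_distance_range_cm = dr,
                 centroid = colMeans(mesh$vertices[best, , drop = FALSE]),
                 components = components, empty = FALSE),
            class = "rv_patch")
}

#' @export
print.rv_patch <- function(x, ...) {
  if (x$empty) {
    cat("rv_patch: no significant region\n")
  } else {
    cat(sprintf(paste0("rv_patch: %d vertices, %.2f cm^2 (%.1f%% of surface),",
                       " %.1f-%.1f cm from apex; %d component(s)\n"),
                length(x$vertices), x$area_cm2, 100 * x$fraction_of_surface,
                x$apex_distance_range_cm[1], x$apex_distance_range_cm[2],
                nrow(x$components)))
  }
  invisible(x)
}
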