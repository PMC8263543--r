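# Blood-free quantification: indirect BPND from VT ratios, the original
# multilinear reference tissue model (MRTMo) at ROI and voxel level, SUVR
# windows, and method-comparison statistics.

#' Indirect binding potential from distribution-volume ratios
#'
#' \eqn{BP_{ND} = V_T(target) / V_T(reference) - 1}. Negative values are
#' returned as-is (estimator transparency), not clipped.
#'
#' @param vt_target,vt_reference Total distribution volumes (mL/cm^3).
#' @return BPND (dimensionless).
#' @export
indirect_bpnd <- function(vt_target, vt_reference) {
  if (any(vt_reference <= 0)) stop("reference VT must be > 0")
  vt_target / vt_reference - 1
}

#' Original multilinear reference tissue model (MRTMo)
#'
#' Estimates BPND from target and reference TACs without blood data, by
#' OLS on the three-regressor multilinear rearrangement of the reference
#' Logan relation, over frames with mid-time beyond t*:
#' \deqn{\int_0^t C_T = \gamma_1 \int_0^t C_{ref} + \gamma_2 C_{ref}(t) +
#'   \gamma_3 C_T(t)}
#' The coefficient on the integrated reference curve is the
#' distribution-volume ratio, so \eqn{BP_{ND} = \gamma_1 - 1}.
#'
#' @param tc Target `tac`.
#' @param ref_tac Reference-region `tac` on the same schedule.
#' @param t_star Equilibrium time in seconds (default 1200).
#' @return An `mrtmo_fit` with `gamma` (3 coefficients), `bpnd`, `t_star`,
#'   `n_points`, `r_squared`, `ok`.
#' @export
mrtmo_fit <- function(tc, ref_tac, t_star = 1200) {
  stopifnot(inherits(tc, "tac"), inherits(ref_tac, "tac"))
  if (nrow(tc$schedule) != nrow(ref_tac$schedule) ||
      any(abs(tc$schedule$frame_mid - ref_tac$schedule$frame_mid) > 1e-9)) {
    stop("target and reference TACs must share a frame schedule")
  }
  X <- mrtmo_design(ref_tac, t_star)
  mrtmo_solve(tc, X, t_star)
}

# reference-side design pieces, computed once and reused across voxels
mrtmo_design <- function(ref_tac, t_star) {
  mid <- ref_tac$schedule$frame_mid
  use <- mid > t_star
  if (sum(use) < 4L) stop("insufficient points beyond t* (need >= 4)")
  list(use = use,
       int_ref = cum_tac_integral(ref_tac)[use],
       ref = ref_tac$activity[use])
}

mrtmo_solve <- function(tc, design, t_star) {
  use <- design$use
  y <- cum_tac_integral(tc)[use]
  X <- cbind(int_ref = design$int_ref, ref = design$ref, ct = tc$activity[use])
  qrX <- qr(X)
  if (qrX$rank < 3L) {
    # degenerate design (e.g. target identical to reference): take the
    # pivoted least-squares solution with aliased coefficients set to 0;
    # accept it only if it actually reproduces the data
    g <- qr.coef(qrX, y)
    g[is.na(g)] <- 0
    ok <- sum((y - X %*% g)^2) <= 1e-10 * max(sum(y^2), 1)
    return(structure(list(
      gamma = stats::setNames(as.numeric(g), c("gamma1", "gamma2", "gamma3")),
      bpnd = if (ok) unname(g[1] - 1) else NA_real_, t_star = t_star,
      n_points = sum(use), r_squared = NA_real_, ok = ok
    ), class = "mrtmo_fit"))
  }
  g <- qr.coef(qrX, y)
  fitted <- X %*% g
  ssr <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  structure(list(
    gamma = stats::setNames(as.numeric(g), c("gamma1", "gamma2", "gamma3")),
    bpnd = unname(g[1] - 1), t_star = t_star, n_points = sum(use),
    r_squared = if (sst > 0) 1 - ssr / sst else NA_real_, ok = TRUE
  ), class = "mrtmo_fit")
}

#' @export
print.mrtmo_fit <- function(x, ...) {
  cat(sprintf("MRTMo fit: BPND = %.4f (t* = %.0f min, %d points, R2 = %.5f)\n",
              x$bpnd, x$t_star / 60, x$n_points, x$r_squared))
  invisible(x)
}

#' Voxelwise parametric BPND mapping with MRTMo
#'
#' Fits MRTMo independently at every voxel of a labelled dynamic volume
#' against a single reference-region TAC; the reference-side design
#' columns are computed once and reused for all voxels.
#'
#' @param vol A `labelled_volume`.
#' @param ref_tac Reference `tac` on the volume's schedule.
#' @param t_star Equilibrium time (s).
#' @param mask Optional 3D logical array; voxels outside are skipped.
#'   Default: all labelled (nonzero) voxels.
#' @param fill Value written at failed/skipped voxels (default `NA`).
#' @return A list with `map` (3D array of BPND), `n_failed`, `n_fitted`.
#' @export
mrtmo_parametric <- function(vol, ref_tac, t_star = 1200, mask = NULL,
                             fill = NA_real_) {
  stopifnot(inherits(vol, "labelled_volume"))
  if (is.null(mask)) mask <- vol$labels != 0
  stopifnot(all(dim(mask) == dim(vol$labels)))
  design <- mrtmo_design(ref_tac, t_star)
  use <- design$use
  nframe <- nrow(vol$schedule)
  flat <- matrix(vol$data, ncol = nframe)
  idx <- which(mask)
  map <- array(fill, dim(vol$labels))
  n_failed <- 0L
  # shared integration weights for the cumulative frame trapezoid
  tt <- c(0, vol$schedule$frame_mid)
  Xref <- cbind(design$int_ref, design$ref)
  for (v in idx) {
    yfull <- flat[v, ]
    cum <- c(0, cumsum(diff(tt) * (c(0, yfull[-nframe]) + yfull) / 2))[-1]
    X <- cbind(Xref, yfull[use])
    y <- cum[use]
    co <- tryCatch(qr.coef(qr(X), y), error = function(e) NULL)
    if (!is.null(co) && any(is.na(co))) {
      # rank-deficient voxel (e.g. identical to the reference): pivoted
      # solution with aliased terms zeroed, accepted only if consistent
      co[is.na(co)] <- 0
      if (sum((y - X %*% co)^2) > 1e-10 * max(sum(y^2), 1)) co <- NULL
    }
    if (is.null(co) || any(!is.finite(co))) {
      n_failed <- n_failed + 1L
    } else {
      map[v] <- co[1] - 1
    }
  }
  if (n_failed > length(idx) / 2) {
    warning("more than half of the voxel fits failed")
  }
  list(map = map, n_failed = n_failed, n_fitted = length(idx) - n_failed)
}

#' SUVR - 1 over late time windows
#'
#' Activity is averaged over each window with frame-duration weighting
#' (frames partially overlapping a window contribute in proportion to the
#' overlap), divided by the reference-region window mean, minus 1.
#'
#' @param tacs Named list of `tac` objects sharing a schedule.
#' @param windows List of `c(start_s, end_s)` windows; default the four
#'   20-min windows from 40 to 90 min.
#' @param reference Name of the reference region in `tacs`.
#' @return A data frame with columns `region`, `window_start_s`,
#'   `window_end_s`, `mean_activity`, `ref_mean`, `suvr_minus_one`.
#' @export
suvr_minus_one <- function(tacs, windows = default_suvr_windows(),
                           reference = "cerebellar_cortex") {
  stopifnot(is.list(tacs), reference %in% names(tacs))
  sched <- tacs[[reference]]$schedule
  t_end <- max(sched$frame_end)
  if (is.numeric(windows) && length(windows) == 2L) windows <- list(windows)
  out <- list()
  for (w in windows) {
    if (w[1] < 0 || w[2] > t_end || w[1] >= w[2]) {
      stop("window [", w[1], ", ", w[2], "] must lie within the scan span")
    }
    overlap <- pmin(sched$frame_end, w[2]) - pmax(sched$frame_start, w[1])
    overlap <- pmax(overlap, 0)
    if (sum(overlap) <= 0) stop("window overlaps no frames")
    wmean <- function(tc) sum(tc$activity * overlap) / sum(overlap)
    ref_mean <- wmean(tacs[[reference]])
    if (ref_mean <= 0) stop("reference window mean must be > 0")
    for (nm in names(tacs)) {
      m <- wmean(tacs[[nm]])
      out[[length(out) + 1L]] <- data.frame(
        region = nm, window_start_s = w[1], window_end_s = w[2],
        mean_activity = m, ref_mean = ref_mean,
        suvr_minus_one = m / ref_mean - 1
      )
    }
  }
  do.call(rbind, out)
}

#' The default SUVR windows: 40-60, 50-70, 60-80 and 70-90 min
#' @return List of `c(start_s, end_s)` pairs.
#' @export
default_suvr_windows <- function() {
  list(c(2400, 3600), c(3000, 4200), c(3600, 4800), c(4200, 5400))
}

#' Method-comparison statistics (regression and Bland-Altman)
#'
#' Given paired estimates of the same quantity by two methods, returns the
#' OLS regression of B on A, Pearson correlation, and Bland-Altman
#' agreement statistics: mean difference, 1.96-SD limits of agreement, and
#' the proportional-bias slope from regressing (B - A) on (A + B)/2.
#'
#' @param a,b Numeric vectors of paired estimates (method A, method B).
#' @return A list of class `comparison_stats`.
#' @export
compare_methods <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3L) stop("need at least 3 finite pairs")
  if (stats::var(a) == 0) stop("zero variance in method A; regression undefined")
  fit <- stats::lm(b ~ a)
  r <- stats::cor(a, b)
  d <- b - a
  m <- (a + b) / 2
  prop <- if (stats::var(m) > 0) unname(stats::coef(stats::lm(d ~ m))[2]) else NA_real_
  structure(list(
    n = length(a),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    pearson_r = r, r_squared = r^2,
    ba_mean_diff = mean(d),
    ba_loa = mean(d) + c(-1.96, 1.96) * stats::sd(d),
    ba_prop_bias_slope = prop
  ), class = "comparison_stats")
}

#' @export
print.comparison_stats <- function(x, ...) {
  cat(sprintf(
    "Method comparison (n = %d): B = %.3f A %+0.3f, r^2 = %.4f\n",
    x$n, x$slope, x$intercept, x$r_squared))
  cat(sprintf("  Bland-Altman: mean diff %.4f, LoA [%.4f, %.4f], prop. bias slope %.3f\n",
              x$ba_mean_diff, x$ba_loa[1], x$ba_loa[2], x$ba_prop_bias_slope))
  invisible(x)
}
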