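# Graphical (linearized) plasma-input estimators of total distribution
# volume. Both become linear after an equilibrium time t*; frames are
# selected by mid-time strictly greater than t*.

# cumulative trapezoid of the TAC itself from time 0 at frame mid-times,
# with an implicit (0, 0) anchor
cum_tac_integral <- function(tc) {
  tt <- c(0, tc$schedule$frame_mid)
  yy <- c(0, tc$activity)
  c(0, cumsum(diff(tt) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2))[-1]
}

#' Remove the vascular signal from a measured TAC
#'
#' Plasma-input analyses model the tissue compartments; the measured
#' concentration also carries the fixed fractional blood volume Vb. This
#' returns `(C_measured - Vb * Cb) / (1 - Vb)`, the tissue-only
#' concentration, using frame averages of the whole-blood curve.
#'
#' @param tc A `tac`.
#' @param inf An `input_function` providing the whole-blood curve.
#' @param vb Fractional blood volume (default 0.05); 0 returns the TAC
#'   unchanged.
#' @return A corrected `tac`.
#' @export
vascular_correct <- function(tc, inf, vb = 0.05) {
  stopifnot(vb >= 0, vb < 1)
  if (vb == 0) return(tc)
  sched <- tc$schedule
  cb <- vapply(seq_len(nrow(sched)), function(i) {
    tt <- seq(sched$frame_start[i], sched$frame_end[i], length.out = 11L)
    y <- eval_input(inf, tt, "cb", warn_extrapolate = FALSE)
    sum(diff(tt) * (utils::head(y, -1) + utils::tail(y, -1)) / 2) /
      sched$frame_duration[i]
  }, numeric(1))
  tac(sched, (tc$activity - vb * cb) / (1 - vb), weights = tc$weights,
      label = tc$label)
}

#' Logan graphical estimate of total distribution volume
#'
#' Ordinary least squares of
#' \eqn{y(t) = \int_0^t C_T / C_T(t)} on
#' \eqn{x(t) = \int_0^t C_p / C_T(t)} over frames with mid-time beyond the
#' equilibrium time t*; the slope is VT. The tissue integral uses the
#' frame trapezoid; the plasma integral is exact for the piecewise-linear
#' input function.
#'
#' @param tc A `tac`.
#' @param inf An `input_function`.
#' @param t_star Equilibrium time in seconds (default 1200 s = 20 min).
#' @param vb Fixed fractional blood volume removed from the TAC before the
#'   transform (see [vascular_correct()]); default 0.05.
#' @return A `graphical_fit` with `method`, `vt`, `intercept`, `t_star`,
#'   `n_points`, `r_squared` and the transformed `points`.
#' @export
logan_vt <- function(tc, inf, t_star = 1200, vb = 0.05) {
  stopifnot(inherits(tc, "tac"), inherits(inf, "input_function"))
  tc <- vascular_correct(tc, inf, vb)
  mid <- tc$schedule$frame_mid
  int_ct <- cum_tac_integral(tc)
  int_cp <- integrate_input(inf, mid, "cp")
  use <- mid > t_star
  if (any(use & abs(tc$activity) < 1e-12)) {
    warning("near-zero tissue activity in late frames; points dropped")
    use <- use & abs(tc$activity) >= 1e-12
  }
  if (sum(use) < 3L) stop("insufficient points beyond t* (need >= 3)")
  x <- int_cp[use] / tc$activity[use]
  y <- int_ct[use] / tc$activity[use]
  fit <- stats::lm(y ~ x)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  structure(list(
    method = "logan", vt = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]), t_star = t_star,
    n_points = sum(use), r_squared = r2,
    points = data.frame(t_mid = mid[use], x = x, y = y)
  ), class = "graphical_fit")
}

#' MA1 multilinear estimate of total distribution volume
#'
#' The multilinear rearrangement of the Logan relation with the noisy
#' tissue term moved to the response side, reducing noise-induced bias:
#' \deqn{C_T(t) = -\frac{V_T}{b}\int_0^t C_p + \frac{1}{b}\int_0^t C_T,
#'   \quad t > t^*}
#' fitted by OLS on the two integral regressors (no intercept);
#' `VT = -coef1 / coef2`.
#'
#' @inheritParams logan_vt
#' @return A `graphical_fit` (slot `b` holds the intercept-like
#'   coefficient 1/coef2).
#' @export
ma1_vt <- function(tc, inf, t_star = 1200, vb = 0.05) {
  stopifnot(inherits(tc, "tac"), inherits(inf, "input_function"))
  tc <- vascular_correct(tc, inf, vb)
  mid <- tc$schedule$frame_mid
  use <- mid > t_star
  if (sum(use) < 3L) stop("insufficient points beyond t* (need >= 3)")
  int_ct <- cum_tac_integral(tc)[use]
  int_cp <- integrate_input(inf, mid[use], "cp")
  y <- tc$activity[use]
  X <- cbind(int_cp, int_ct)
  qrX <- qr(X)
  if (qrX$rank < 2L) stop("singular MA1 design (collinear regressors)")
  co <- qr.coef(qrX, y)
  if (abs(co[2]) < 1e-14) stop("degenerate MA1 fit: 1/b coefficient ~ 0")
  fitted <- X %*% co
  ssr <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  structure(list(
    method = "ma1", vt = unname(-co[1] / co[2]), b = unname(1 / co[2]),
    intercept = NA_real_, t_star = t_star, n_points = sum(use),
    r_squared = if (sst > 0) 1 - ssr / sst else NA_real_,
    points = data.frame(t_mid = mid[use], int_cp = int_cp, int_ct = int_ct,
                        ct = y)
  ), class = "graphical_fit")
}

#' @export
print.graphical_fit <- function(x, ...) {
  cat(sprintf("%s fit: VT = %.3f mL/cm^3 (t* = %.0f min, %d points, R2 = %.4f)\n",
              toupper(x$method), x$vt, x$t_star / 60, x$n_points, x$r_squared))
  invisible(x)
}

#' Sensitivity of graphical VT to the equilibrium time t*
#'
#' Re-estimates VT over a grid of t* values and reports the maximum
#' relative spread, to check that the estimate is insensitive to the
#' choice of equilibrium time.
#'
#' @param tc A `tac`.
#' @param inf An `input_function`.
#' @param method `"logan"` or `"ma1"`.
#' @param t_star_grid t* values in seconds (default 20-60 min by 10).
#' @param vb Fixed fractional blood volume (applied once before the grid).
#' @return A list with data frame `table` (`t_star`, `vt`) and
#'   `max_rel_spread` = (max - min)/median of VT over the grid.
#' @export
tstar_sensitivity <- function(tc, inf, method = c("logan", "ma1"),
                              t_star_grid = seq(1200, 3600, by = 600),
                              vb = 0.05) {
  method <- match.arg(method)
  if (any(t_star_grid < 0 | t_star_grid >= max(tc$schedule$frame_end))) {
    stop("t* grid must lie within the scan span")
  }
  f <- if (method == "logan") logan_vt else ma1_vt
  tc <- vascular_correct(tc, inf, vb)
  vt <- vapply(t_star_grid, function(ts) f(tc, inf, ts, vb = 0)$vt, numeric(1))
  list(
    table = data.frame(t_star = t_star_grid, vt = vt),
    max_rel_spread = if (length(vt) > 1L) {
      (max(vt) - min(vt)) / stats::median(vt)
    } else 0
  )
}
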