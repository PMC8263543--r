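# Analytic solution of the compartment ODEs against a piecewise-linear
# plasma input. The tissue impulse response of the 2TCM is a sum of two
# exponentials; its convolution with a piecewise-linear Cp has a closed
# form per segment, accumulated by the recursion
#   I(t_{k+1}) = I(t_k) exp(-theta dt) + segment integral,
# which is exact (no quadrature error beyond the linear Cp representation).

# I(t_j) = int_0^{t_j} exp(-theta (t_j - s)) y(s) ds for piecewise-linear
# y given at knots (t, y); returns the integral at every knot.
exp_conv_plin <- function(theta, t, y) {
  n <- length(t)
  out <- numeric(n)
  if (n < 2L) return(out)
  for (k in seq_len(n - 1L)) {
    dt <- t[k + 1L] - t[k]
    b <- (y[k + 1L] - y[k]) / dt
    if (theta * dt > 1e-10) {
      E <- exp(-theta * dt)
      em <- -expm1(-theta * dt)          # 1 - E, accurate for small theta*dt
      seg <- y[k] * em / theta + (b / theta) * (dt - em / theta)
      out[k + 1L] <- out[k] * E + seg
    } else {
      out[k + 1L] <- out[k] * (1 - theta * dt) + y[k] * dt + 0.5 * b * dt^2
    }
  }
  out
}

# Eigen-decomposition of the 2TCM system for rates in s^-1.
# Returns amplitudes (phi) and decay rates (theta) of the impulse response
# of C1 + C2: h(t) = phi1 exp(-theta1 t) + phi2 exp(-theta2 t).
tissue_impulse <- function(K1, k2, k3, k4) {
  if (k3 <= 0) {
    return(list(phi = K1, theta = k2))
  }
  s <- k2 + k3 + k4
  disc <- s^2 - 4 * k2 * k4
  if (disc < 0) disc <- 0
  root <- sqrt(disc)
  if (root < 1e-9 * max(s, 1e-12)) root <- 1e-9 * max(s, 1e-12)  # repeated-root guard
  a1 <- (s - root) / 2
  a2 <- (s + root) / 2
  phi1 <- K1 * (k3 + k4 - a1) / (a2 - a1)
  phi2 <- K1 * (a2 - k3 - k4) / (a2 - a1)
  list(phi = c(phi1, phi2), theta = c(a1, a2))
}

# Continuous model tissue concentration (incl. blood volume) at arbitrary
# times, given rates in min^-1. `times` in seconds, sorted ascending.
model_tissue_cont <- function(params, inf, times) {
  K1 <- params[["K1"]] / 60
  k2 <- params[["k2"]] / 60
  k3 <- if (!is.null(params[["k3"]])) params[["k3"]] / 60 else 0
  k4 <- if (!is.null(params[["k4"]])) params[["k4"]] / 60 else 0
  Vb <- if (!is.null(params[["Vb"]])) params[["Vb"]] else 0.05
  grid <- sort(unique(c(inf$time[inf$time <= max(times)], times)))
  cpg <- eval_input(inf, grid, "cp", warn_extrapolate = FALSE)
  ir <- tissue_impulse(K1, k2, k3, k4)
  ct <- numeric(length(grid))
  for (j in seq_along(ir$theta)) {
    ct <- ct + ir$phi[j] * exp_conv_plin(ir$theta[j], grid, cpg)
  }
  cbt <- eval_input(inf, grid, "cb", warn_extrapolate = FALSE)
  total <- (1 - Vb) * ct + Vb * cbt
  total[match(times, grid)]
}

#' Forward-model a tissue time-activity curve
#'
#' Solves the one/two-tissue compartment system
#' \deqn{dC_1/dt = K_1 C_p - (k_2 + k_3) C_1 + k_4 C_2, \quad
#'       dC_2/dt = k_3 C_1 - k_4 C_2}
#' analytically (bi-exponential impulse response convolved in closed form
#' with the piecewise-linear plasma input) and returns frame averages of
#' the total model concentration
#' \eqn{C_{model}(t) = (1 - V_b)(C_1 + C_2) + V_b C_b(t)}.
#' Setting `k3 = 0` gives the one-tissue model. Repeated eigenvalues are
#' handled by a tiny eigenvalue perturbation, never returning NaN.
#'
#' @param params Named list/vector with `K1` (mL·cm^-3·min^-1), `k2`, `k3`,
#'   `k4` (min^-1) and `Vb` (fraction, default 0.05).
#' @param inf An `input_function`.
#' @param schedule A `frame_schedule`.
#' @param label Label for the returned TAC.
#' @param n_sub Sub-samples per frame used for the frame average
#'   (trapezoid; default 10 intervals).
#' @return A `tac` of frame-averaged model concentrations.
#' @export
model_tissue_curve <- function(params, inf, schedule, label = "model",
                               n_sub = 10L) {
  validate_frame_schedule(schedule)
  n_sub <- max(2L, as.integer(n_sub))
  sub <- seq(0, 1, length.out = n_sub + 1L)
  times <- unlist(lapply(seq_len(nrow(schedule)), function(i) {
    schedule$frame_start[i] + sub * schedule$frame_duration[i]
  }))
  times <- sort(unique(times))
  ct <- model_tissue_cont(params, inf, times)
  if (any(!is.finite(ct))) stop("non-finite model tissue values; check parameters")
  vals <- vapply(seq_len(nrow(schedule)), function(i) {
    tt <- schedule$frame_start[i] + sub * schedule$frame_duration[i]
    y <- ct[match(tt, times)]
    sum(diff(tt) * (utils::head(y, -1) + utils::tail(y, -1)) / 2) /
      schedule$frame_duration[i]
  }, numeric(1))
  tac(schedule, vals, label = label)
}

#' Fit a compartment model to a time-activity curve
#'
#' Weighted nonlinear least squares on (K1, k2) for the one-tissue model
#' or (K1, k2, k3, k4) for the two-tissue model, with the fractional blood
#' volume Vb held fixed. Multi-start: the supplied initial values plus
#' `n_restarts - 1` seeded log-normal jitters, keeping the solution with
#' the lowest weighted SSR. The parameter covariance is
#' \eqn{\hat\sigma^2 (J^T W J)^{-1}} with
#' \eqn{\hat\sigma^2 = SSR_w / (n - p)}; percent standard errors are
#' 100·SE/estimate, and the SE of the macro-parameter VT is propagated by
#' the delta method.
#'
#' @param tc A `tac` (measured or simulated).
#' @param inf An `input_function`.
#' @param kind `"2tcm"` or `"1tcm"`.
#' @param weights Per-frame weights; default `frame_weights(tc, "duration")`
#'   unless the TAC carries its own.
#' @param init Named initial values (K1, k2, k3, k4) in min^-1 units.
#' @param lower,upper Box bounds applied to all rate constants.
#' @param Vb Fixed fractional blood volume (default 0.05).
#' @param n_restarts Number of starts (first is `init` itself).
#' @param seed Integer seed controlling the jittered restarts.
#' @return A `compartment_fit` with elements `kind`, `params`, `vt`, `vnd`,
#'   `vs`, `se_percent` (per parameter and `VT`), `ssr`, `n_frames`,
#'   `n_params`, `fitted` (a `tac`), `converged`.
#' @export
fit_compartment <- function(tc, inf, kind = c("2tcm", "1tcm"),
                            weights = NULL,
                            init = c(K1 = 0.2, k2 = 0.1, k3 = 0.05, k4 = 0.05),
                            lower = 1e-6, upper = 10,
                            Vb = 0.05, n_restarts = 5L, seed = 42L) {
  kind <- match.arg(kind)
  stopifnot(inherits(tc, "tac"), inherits(inf, "input_function"))
  sched <- tc$schedule
  y <- tc$activity
  if (is.null(weights)) {
    weights <- if (!is.null(tc$weights)) tc$weights else frame_weights(sched, "duration")
  }
  stopifnot(length(weights) == length(y), all(weights >= 0))
  sw <- sqrt(weights)
  pn <- if (kind == "1tcm") c("K1", "k2") else c("K1", "k2", "k3", "k4")
  p0 <- pmin(pmax(unlist(init)[pn], lower), upper)

  predict_frames <- function(p) {
    pars <- as.list(p)
    names(pars) <- pn
    if (kind == "1tcm") { pars$k3 <- 0; pars$k4 <- 0 }
    pars$Vb <- Vb
    model_tissue_curve(pars, inf, sched)$activity
  }
  resid_fn <- function(p) sw * (y - predict_frames(p))

  starts <- list(p0)
  if (n_restarts > 1L) {
    jit <- with_seed(seed, {
      lapply(seq_len(n_restarts - 1L), function(i) {
        pmin(pmax(p0 * exp(stats::rnorm(length(p0), 0, 0.5)), lower), upper)
      })
    })
    starts <- c(starts, jit)
  }

  best <- NULL
  for (st in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = st, lower = rep(lower, length(pn)), upper = rep(upper, length(pn)),
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-12)
    ), silent = TRUE)
    if (inherits(fit, "try-error")) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }

  n <- length(y); p <- length(pn)
  if (is.null(best)) {
    warning("compartment fit failed to converge from any start")
    se <- stats::setNames(rep(Inf, p + 1L), c(pn, "VT"))
    est <- stats::setNames(rep(NA_real_, 4L), c("K1", "k2", "k3", "k4"))
    return(structure(list(
      kind = kind, params = est, Vb = Vb, vt = NA_real_, vnd = NA_real_,
      vs = NA_real_, se_percent = se, ssr = NA_real_, n_frames = n,
      n_params = p, weights = weights, fitted = NULL, converged = FALSE
    ), class = "compartment_fit"))
  }

  est <- best$fit$par
  names(est) <- pn
  full <- c(K1 = est[["K1"]], k2 = est[["k2"]],
            k3 = if (kind == "2tcm") est[["k3"]] else 0,
            k4 = if (kind == "2tcm") est[["k4"]] else 0)
  vnd <- full[["K1"]] / full[["k2"]]
  vs <- if (kind == "2tcm" && full[["k4"]] > 0) {
    vnd * full[["k3"]] / full[["k4"]]
  } else 0
  vt <- vnd + vs

  # numeric Jacobian of the frame predictions at the optimum
  J <- numeric_jacobian(predict_frames, est)
  WJ <- sw * J
  ssr <- best$ssr
  sigma2 <- ssr / max(n - p, 1L)
  JtJ <- crossprod(WJ)
  cov <- try(solve(JtJ) * sigma2, silent = TRUE)
  if (inherits(cov, "try-error") || any(!is.finite(cov))) {
    se <- stats::setNames(rep(NA_real_, p + 1L), c(pn, "VT"))
  } else {
    se_par <- sqrt(pmax(diag(cov), 0))
    sep <- 100 * se_par / abs(est)
    # delta method for VT
    g <- vt_gradient(full, kind)[pn]
    se_vt <- sqrt(max(t(g) %*% cov %*% g, 0))
    se <- stats::setNames(c(sep, 100 * se_vt / abs(vt)), c(pn, "VT"))
  }

  fitted <- tac(sched, predict_frames(est), label = paste0(tc$label, "_", kind))
  structure(list(
    kind = kind, params = full, Vb = Vb, vt = unname(vt), vnd = unname(vnd),
    vs = unname(vs), se_percent = se, ssr = ssr, n_frames = n, n_params = p,
    weights = weights, fitted = fitted,
    converged = best$fit$info %in% 1:4
  ), class = "compartment_fit")
}

# gradient of VT = K1/k2 (1 + k3/k4) w.r.t. micro-parameters
vt_gradient <- function(p, kind) {
  K1 <- p[["K1"]]; k2 <- p[["k2"]]; k3 <- p[["k3"]]; k4 <- p[["k4"]]
  if (kind == "1tcm" || k4 <= 0) {
    return(c(K1 = 1 / k2, k2 = -K1 / k2^2, k3 = 0, k4 = 0))
  }
  c(K1 = (1 + k3 / k4) / k2,
    k2 = -K1 * (1 + k3 / k4) / k2^2,
    k3 = K1 / (k2 * k4),
    k4 = -K1 * k3 / (k2 * k4^2))
}

numeric_jacobian <- function(f, p, rel_h = 1e-6) {
  f0 <- f(p)
  J <- matrix(0, length(f0), length(p))
  for (j in seq_along(p)) {
    h <- rel_h * max(abs(p[j]), 1e-4)
    pp <- p; pp[j] <- p[j] + h
    pm <- p; pm[j] <- max(p[j] - h, 0)
    J[, j] <- (f(pp) - f(pm)) / (pp[j] - pm[j])
  }
  J
}

#' @export
print.compartment_fit <- function(x, ...) {
  cat(sprintf("%s fit: VT = %.3f mL/cm^3 (SE %.2f%%), SSR = %.4g, %s\n",
              toupper(x$kind), x$vt, x$se_percent[["VT"]], x$ssr,
              if (x$converged) "converged" else "NOT converged"))
  pr <- x$params[x$params > 0 | names(x$params) %in% c("K1", "k2")]
  cat("  ", paste(sprintf("%s = %.4f", names(pr), pr), collapse = ", "), "\n")
  invisible(x)
}

# run an expression under a temporary RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
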