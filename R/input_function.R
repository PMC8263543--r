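#' Fit a parent-fraction curve to HPLC measurements
#'
#' The fraction of plasma radioactivity attributable to the unmetabolized
#' radioligand (parent fraction) declines over the scan as radiometabolites
#' appear. Three curve families are supported:
#' \describe{
#'   \item{hill}{`f(t) = 1 - (1 - plateau) * t^h / (t50^h + t^h)`; a
#'     decreasing sigmoid anchored at f(0) = 1 with a nonzero asymptote.}
#'   \item{power}{`f(t) = (1 + a t)^(-b)`; decays towards 0.}
#'   \item{linear_interp}{monotone-safe piecewise-linear interpolation of
#'     the measured fractions, anchored at f(0) = 1, constant after the
#'     last sample.}
#' }
#' Parametric fits are unweighted least squares; if a parametric fit ever
#' leaves \[0, 1\] on the data span it falls back to clipped interpolation
#' with a warning, so the pipeline stays total.
#'
#' @param hplc Data frame with columns `time_s` and `parent_fraction`
#'   (fractions in \[0, 1\]).
#' @param kind One of `"hill"`, `"power"`, `"linear_interp"`.
#' @return An object of class `parent_fraction`: call it as a function of
#'   time (seconds) or inspect `$coefficients`.
#' @export
fit_parent_fraction <- function(hplc, kind = c("hill", "power", "linear_interp")) {
  kind <- match.arg(kind)
  stopifnot(all(c("time_s", "parent_fraction") %in% names(hplc)))
  tt <- as.numeric(hplc$time_s)
  ff <- as.numeric(hplc$parent_fraction)
  ord <- order(tt)
  tt <- tt[ord]; ff <- ff[ord]
  if (any(ff < 0 | ff > 1)) stop("parent fractions must lie in [0, 1]")
  n_min <- if (kind == "linear_interp") 2L else 3L
  if (length(tt) < n_min) stop("need at least ", n_min, " HPLC samples for kind '", kind, "'")

  make_interp <- function() {
    # anchor at (0, 1), enforce non-increasing via running minimum, clip
    kt <- c(0, tt[tt > 0])
    kf <- pmin(pmax(cummin(c(1, ff[tt > 0])), 0), 1)
    fun <- function(t) {
      stats::approx(kt, kf, xout = pmin(t, max(kt)), rule = 2)$y
    }
    structure(list(kind = "linear_interp", coefficients = NULL,
                   knots = data.frame(time_s = kt, parent_fraction = kf),
                   fun = fun),
              class = "parent_fraction")
  }

  if (kind == "linear_interp") return(make_interp())

  fit <- try(switch(kind,
    hill = {
      res <- minpack.lm::nls.lm(
        par = c(plateau = 0.5, t50 = stats::median(tt), shape = 1.5),
        lower = c(1e-6, 1e-3, 0.05), upper = c(1 - 1e-6, 1e6, 20),
        fn = function(p) ff - (1 - (1 - p[1]) * tt^p[3] / (p[2]^p[3] + tt^p[3]))
      )
      p <- res$par
      list(coef = p, fun = function(t) {
        t <- pmax(t, 0)
        1 - (1 - p[[1]]) * t^p[[3]] / (p[[2]]^p[[3]] + t^p[[3]])
      })
    },
    power = {
      res <- minpack.lm::nls.lm(
        par = c(a = 1 / stats::median(tt), b = 0.5),
        lower = c(1e-12, 1e-6), upper = c(1e3, 50),
        fn = function(p) ff - (1 + p[1] * tt)^(-p[2])
      )
      p <- res$par
      list(coef = p, fun = function(t) (1 + p[[1]] * pmax(t, 0))^(-p[[2]]))
    }
  ), silent = TRUE)

  if (inherits(fit, "try-error")) {
    warning("parametric parent-fraction fit failed; falling back to interpolation")
    return(make_interp())
  }
  chk <- fit$fun(seq(0, max(tt), length.out = 200))
  if (any(!is.finite(chk)) || any(chk < -1e-9 | chk > 1 + 1e-9)) {
    warning("parametric parent-fraction fit leaves [0, 1]; falling back to interpolation")
    return(make_interp())
  }
  structure(list(kind = kind, coefficients = fit$coef, knots = NULL, fun = fit$fun),
            class = "parent_fraction")
}

#' Evaluate a parent-fraction curve
#' @param x A `parent_fraction` object.
#' @param t Times in seconds.
#' @return Fractions in \[0, 1\].
#' @export
eval_parent_fraction <- function(x, t) {
  stopifnot(inherits(x, "parent_fraction"))
  pmin(pmax(x$fun(t), 0), 1)
}

#' @export
print.parent_fraction <- function(x, ...) {
  cat(sprintf("Parent-fraction curve (%s); f(90 min) = %.3f\n",
              x$kind, eval_parent_fraction(x, 5400)))
  invisible(x)
}

#' Metabolite-correct measured plasma activity
#'
#' Multiplies each total-plasma sample by the parent fraction at its sample
#' time, yielding parent-only (metabolite-corrected) plasma activity. The
#' whole-blood column is passed through untouched.
#'
#' @param blood Data frame with columns `time_s`, `whole_blood_kBq_ml`,
#'   `plasma_kBq_ml`.
#' @param pf A `parent_fraction` object.
#' @return The blood table with an added `plasma_parent_kBq_ml` column.
#' @export
metabolite_correct <- function(blood, pf) {
  stopifnot(all(c("time_s", "plasma_kBq_ml") %in% names(blood)),
            inherits(pf, "parent_fraction"))
  blood$plasma_parent_kBq_ml <- blood$plasma_kBq_ml *
    eval_parent_fraction(pf, blood$time_s)
  blood
}

#' Build a continuous arterial input function from blood samples
#'
#' Constructs evaluable metabolite-corrected plasma `Cp(t)` and whole-blood
#' `Cb(t)` curves by piecewise-linear interpolation between samples, forced
#' through (0, 0) (the tracer appears only after injection). With
#' `interp = "loglinear_tail"` the curve beyond the last third of samples
#' is replaced by a fitted mono-exponential, giving physically sensible
#' extrapolation past the last sample; with `"linear"`, evaluation beyond
#' the last sample returns the last value (with a warning).
#'
#' Integrals of Cp from 0 are computed exactly for the piecewise-linear
#' representation (trapezoid on the knots plus the partial segment).
#'
#' @param blood Blood table with `time_s`, `whole_blood_kBq_ml` and a
#'   metabolite-corrected `plasma_parent_kBq_ml` column (see
#'   [metabolite_correct()]); `plasma_kBq_ml` is used if no corrected
#'   column is present.
#' @param interp `"linear"` or `"loglinear_tail"`.
#' @param delay_s Constant appearance delay subtracted from sample times
#'   (default 0; exposed for sensitivity studies only).
#' @return An object of class `input_function` with elements `time`, `cp`,
#'   `cb` (the knots) usable via [eval_input()] and [integrate_input()].
#' @export
build_input_function <- function(blood, interp = c("linear", "loglinear_tail"),
                                 delay_s = 0) {
  interp <- match.arg(interp)
  stopifnot(all(c("time_s", "whole_blood_kBq_ml") %in% names(blood)))
  pcol <- if ("plasma_parent_kBq_ml" %in% names(blood)) {
    "plasma_parent_kBq_ml"
  } else "plasma_kBq_ml"
  ord <- order(blood$time_s)
  tt <- as.numeric(blood$time_s)[ord] - delay_s
  cp <- as.numeric(blood[[pcol]])[ord]
  cb <- as.numeric(blood$whole_blood_kBq_ml)[ord]
  keep <- tt > 0
  tt <- tt[keep]; cp <- cp[keep]; cb <- cb[keep]
  if (length(tt) < 3L) stop("need at least 3 blood samples after t = 0")
  if (anyDuplicated(tt)) stop("blood sample times must be strictly increasing")
  if (any(cp < 0) || any(cb < 0)) {
    warning("negative blood activities clipped to 0")
    cp <- pmax(cp, 0); cb <- pmax(cb, 0)
  }
  tt <- c(0, tt); cp <- c(0, cp); cb <- c(0, cb)

  tail_fit <- NULL
  if (interp == "loglinear_tail") {
    ipk <- which.max(cp)
    idx <- seq(max(ipk + 1L, length(tt) - 4L), length(tt))
    idx <- idx[cp[idx] > 0]
    if (length(idx) >= 2L) {
      co <- stats::coef(stats::lm(log(cp[idx]) ~ tt[idx]))
      if (co[2] < 0) tail_fit <- c(a = exp(unname(co[1])), k = -unname(co[2]))
    }
    if (is.null(tail_fit)) {
      warning("mono-exponential tail fit failed; using constant extrapolation")
    }
  }
  structure(
    list(time = tt, cp = cp, cb = cb, interp = interp, tail_fit = tail_fit,
         t_end = max(tt)),
    class = "input_function"
  )
}

#' @export
print.input_function <- function(x, ...) {
  cat(sprintf(
    "Input function: %d samples to %.1f min, peak Cp %.3g kBq/mL (%s)\n",
    length(x$time) - 1L, x$t_end / 60, max(x$cp), x$interp))
  invisible(x)
}

#' Evaluate an input function
#'
#' @param inf An `input_function`.
#' @param t Times in seconds.
#' @param what `"cp"` (metabolite-corrected plasma) or `"cb"` (whole blood).
#' @param warn_extrapolate Warn when `t` exceeds the last sample under
#'   linear interpolation.
#' @return Activity concentrations (kBq/mL).
#' @export
eval_input <- function(inf, t, what = c("cp", "cb"), warn_extrapolate = TRUE) {
  stopifnot(inherits(inf, "input_function"))
  what <- match.arg(what)
  y <- inf[[what]]
  out <- stats::approx(inf$time, y, xout = pmax(pmin(t, inf$t_end), 0), rule = 2)$y
  beyond <- t > inf$t_end
  if (any(beyond)) {
    if (what == "cp" && !is.null(inf$tail_fit)) {
      out[beyond] <- inf$tail_fit[["a"]] * exp(-inf$tail_fit[["k"]] * t[beyond])
    } else if (warn_extrapolate) {
      warning("evaluating input function beyond last sample (",
              round(inf$t_end), " s); constant extrapolation used")
    }
  }
  out
}

#' Cumulative integral of the plasma input function
#'
#' Returns the running integral of Cp from time 0 to each requested time,
#' exact for the piecewise-linear curve (and for the mono-exponential tail
#' when present).
#'
#' @param inf An `input_function`.
#' @param t Nonnegative times in seconds.
#' @param what `"cp"` or `"cb"`.
#' @return Integrals in kBq·s/mL.
#' @export
integrate_input <- function(inf, t, what = c("cp", "cb")) {
  stopifnot(inherits(inf, "input_function"))
  what <- match.arg(what)
  kt <- inf$time
  ky <- inf[[what]]
  # cumulative trapezoid at the knots
  cum <- c(0, cumsum(diff(kt) * (utils::head(ky, -1) + utils::tail(ky, -1)) / 2))
  vapply(as.numeric(t), function(ti) {
    if (ti <= 0) return(0)
    if (ti <= inf$t_end) {
      i <- findInterval(ti, kt)
      yi <- stats::approx(kt, ky, xout = ti, rule = 2)$y
      cum[i] + (ti - kt[i]) * (ky[i] + yi) / 2
    } else if (what == "cp" && !is.null(inf$tail_fit)) {
      a <- inf$tail_fit[["a"]]; k <- inf$tail_fit[["k"]]
      cum[length(cum)] + a / k * (exp(-k * inf$t_end) - exp(-k * ti))
    } else {
      cum[length(cum)] + (ti - inf$t_end) * ky[length(ky)]
    }
  }, numeric(1))
}

#' Summarise plasma free-fraction replicates
#'
#' The plasma free fraction (percent of plasma radioligand not bound to
#' protein, measured by ultrafiltration) is carried as study metadata; it
#' does not enter any kinetic model here.
#'
#' @param replicates Numeric vector of replicate measurements in percent.
#' @return A list with `values`, `mean`, `sd` (0 when n = 1) and `n`.
#' @export
free_fraction <- function(replicates) {
  replicates <- as.numeric(replicates)
  if (length(replicates) < 1L) stop("need at least one replicate")
  if (any(!is.finite(replicates)) || any(replicates < 0 | replicates > 100)) {
    stop("free-fraction replicates must lie in [0, 100] percent")
  }
  list(
    values = replicates,
    mean = mean(replicates),
    sd = if (length(replicates) > 1L) stats::sd(replicates) else 0,
    n = length(replicates)
  )
}

#' Read / write blood and HPLC tables
#'
#' Blood CSV columns: `time_s,whole_blood_kBq_ml,plasma_kBq_ml`.
#' HPLC CSV columns: `time_s,parent_fraction`.
#'
#' @param path CSV file path.
#' @export
read_blood_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "whole_blood_kBq_ml", "plasma_kBq_ml")
  if (!all(need %in% names(df))) {
    stop("blood table must have columns ", paste(need, collapse = ", "))
  }
  df[order(df$time_s), ]
}

#' @rdname read_blood_table
#' @param x Data frame to write.
#' @export
write_blood_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_blood_table
#' @export
read_hplc_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "parent_fraction") %in% names(df))) {
    stop("HPLC table must have columns time_s, parent_fraction")
  }
  df[order(df$time_s), ]
}
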