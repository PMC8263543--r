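# Model-selection statistics for nested least-squares kinetic fits, scan
# time-stability (truncation) analysis, and dispersion summaries.

#' Least-squares Akaike information criterion
#'
#' `AIC = n log(SSR/n) + 2k` (least-squares form, no additive constant;
#' only differences between models on the same data are meaningful).
#' Lower is better. With `correct = TRUE` the small-sample (AICc) term
#' `2k(k+1)/(n-k-1)` is added.
#'
#' @param ssr Weighted residual sum of squares (> 0; an exact fit returns
#'   `-Inf` with attribute `exact_fit`).
#' @param n Number of data points.
#' @param k Number of fitted parameters (n > k).
#' @param correct Apply the small-sample correction.
#' @return AIC value.
#' @export
aic_ls <- function(ssr, n, k, correct = FALSE) {
  stopifnot(n > k, ssr >= 0)
  if (ssr == 0) {
    out <- -Inf
    attr(out, "exact_fit") <- TRUE
    return(out)
  }
  out <- n * log(ssr / n) + 2 * k
  if (correct) out <- out + 2 * k * (k + 1) / (n - k - 1)
  out
}

#' Model selection criterion (weighted form)
#'
#' \deqn{MSC = \ln\frac{\sum_i w_i (y_i - \bar y_w)^2}
#'   {\sum_i w_i (y_i - \hat y_i)^2} - \frac{2k}{n}}
#' with \eqn{\bar y_w} the weighted mean of the observations. Higher is
#' better; the value is invariant to rescaling all weights by a constant.
#'
#' @param weights Nonnegative fit weights.
#' @param observed,fitted Data and model values.
#' @param k Number of fitted parameters.
#' @return MSC value (`Inf` with attribute `exact_fit` for a perfect fit).
#' @export
msc <- function(weights, observed, fitted, k) {
  stopifnot(length(weights) == length(observed),
            length(observed) == length(fitted))
  n <- length(observed)
  ybar <- sum(weights * observed) / sum(weights)
  sst <- sum(weights * (observed - ybar)^2)
  if (sst <= 0) stop("weighted total variance must be > 0")
  ssr <- sum(weights * (observed - fitted)^2)
  if (ssr == 0) {
    out <- Inf
    attr(out, "exact_fit") <- TRUE
    return(out)
  }
  log(sst / ssr) - 2 * k / n
}

#' F test between nested least-squares fits
#'
#' \deqn{F = \frac{(SSR_s - SSR_c)/(k_c - k_s)}{SSR_c/(n - k_c)}}
#' with p-value from the F(k_c - k_s, n - k_c) distribution. If optimizer
#' noise leaves the complex model with the larger SSR, F is clipped to 0
#' and p = 1 with a warning.
#'
#' @param fit_simple,fit_complex `compartment_fit` objects (same data and
#'   weights), or lists with `ssr`, `n_frames`, `n_params`.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
f_test <- function(fit_simple, fit_complex) {
  ss <- fit_simple$ssr; sc <- fit_complex$ssr
  ks <- fit_simple$n_params; kc <- fit_complex$n_params
  n <- fit_complex$n_frames
  if (fit_simple$n_frames != n) stop("fits must use the same data")
  if (kc <= ks) stop("complex model must have more parameters")
  if (sc > ss) {
    warning("complex model has larger SSR than simple model; F clipped to 0")
    return(list(F = 0, df1 = kc - ks, df2 = n - kc, p = 1))
  }
  Fv <- ((ss - sc) / (kc - ks)) / (sc / (n - kc))
  list(F = Fv, df1 = kc - ks, df2 = n - kc,
       p = stats::pf(Fv, kc - ks, n - kc, lower.tail = FALSE))
}

#' Compare one- vs two-tissue fits of the same TAC
#'
#' Convenience wrapper reporting AIC, MSC and the F test for both models
#' fit to a single TAC, and the model each criterion prefers.
#'
#' @param tc A `tac`.
#' @param inf An `input_function`.
#' @param ... Passed to [fit_compartment()] (weights, seeds, ...).
#' @return A list of class `model_comparison` with both fits and the
#'   per-criterion preferences.
#' @export
compare_compartment_models <- function(tc, inf, ...) {
  f1 <- fit_compartment(tc, inf, kind = "1tcm", ...)
  f2 <- fit_compartment(tc, inf, kind = "2tcm", ...)
  a1 <- aic_ls(f1$ssr, f1$n_frames, f1$n_params)
  a2 <- aic_ls(f2$ssr, f2$n_frames, f2$n_params)
  m1 <- msc(f1$weights, tc$activity, f1$fitted$activity, f1$n_params)
  m2 <- msc(f2$weights, tc$activity, f2$fitted$activity, f2$n_params)
  ft <- f_test(f1, f2)
  structure(list(
    fit_1tcm = f1, fit_2tcm = f2,
    aic = c(`1tcm` = a1, `2tcm` = a2),
    msc = c(`1tcm` = m1, `2tcm` = m2),
    f_test = ft,
    preferred = c(
      aic = if (a2 < a1) "2tcm" else "1tcm",
      msc = if (m2 > m1) "2tcm" else "1tcm",
      f = if (ft$p < 0.05) "2tcm" else "1tcm"
    )
  ), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison: AIC %0.2f (1TCM) vs %0.2f (2TCM); MSC %0.2f vs %0.2f\n",
              x$aic[1], x$aic[2], x$msc[1], x$msc[2]))
  cat(sprintf("  F = %.2f (df %d, %d), p = %.3g; preferred: AIC %s, MSC %s, F %s\n",
              x$f_test$F, x$f_test$df1, x$f_test$df2, x$f_test$p,
              x$preferred["aic"], x$preferred["msc"], x$preferred["f"]))
  invisible(x)
}

#' Time-stability (scan truncation) analysis
#'
#' Refits the model on progressively truncated data (keeping frames whose
#' end time does not exceed each duration) and reports VT, its percent SE
#' and the ratio to the full-length estimate. The default grid steps the
#' 90-min scan down to 40 min in 10-min steps.
#'
#' @param tc A `tac`.
#' @param inf An `input_function`.
#' @param durations Truncation durations in seconds, full length first
#'   (default `seq(5400, 2400, by = -600)`).
#' @param kind Compartment model kind.
#' @param ... Passed to [fit_compartment()].
#' @return A `stability_table` data frame with columns `duration_s`, `vt`,
#'   `vt_se_percent`, `ratio_to_full`, `converged`.
#' @export
truncate_and_refit <- function(tc, inf, durations = seq(5400, 2400, by = -600),
                               kind = "2tcm", ...) {
  stopifnot(inherits(tc, "tac"))
  t_end <- max(tc$schedule$frame_end)
  if (any(durations <= 0 | durations > t_end + 1e-9)) {
    stop("durations must lie in (0, scan length]")
  }
  durations <- sort(durations, decreasing = TRUE)
  rows <- lapply(durations, function(d) {
    keep <- tc$schedule$frame_end <= d + 1e-9
    kmin <- if (kind == "2tcm") 4L else 2L
    if (sum(keep) < kmin + 2L) {
      return(data.frame(duration_s = d, vt = NA_real_,
                        vt_se_percent = NA_real_, ratio_to_full = NA_real_,
                        converged = FALSE))
    }
    sched <- tc$schedule[keep, ]
    class(sched) <- c("frame_schedule", "data.frame")
    sub <- tac(sched, tc$activity[keep],
               weights = if (!is.null(tc$weights)) tc$weights[keep] else NULL,
               label = tc$label)
    fit <- tryCatch(fit_compartment(sub, inf, kind = kind, ...),
                    error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(duration_s = d, vt = NA_real_,
                        vt_se_percent = NA_real_, ratio_to_full = NA_real_,
                        converged = FALSE))
    }
    data.frame(duration_s = d, vt = fit$vt,
               vt_se_percent = unname(fit$se_percent[["VT"]]),
               ratio_to_full = NA_real_, converged = fit$converged)
  })
  out <- do.call(rbind, rows)
  out$ratio_to_full <- out$vt / out$vt[1]
  class(out) <- c("stability_table", "data.frame")
  out
}

#' Coefficient of variation in percent
#'
#' `100 * sd(x) / mean(x)` (sample SD); used to summarise between-subject
#' dispersion of VT and BPND estimates.
#'
#' @param values Numeric vector, n >= 2, nonzero mean.
#' @return CV in percent.
#' @export
cov_percent <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("mean is zero; CV undefined")
  100 * stats::sd(values) / m
}
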