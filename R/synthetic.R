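# Synthetic-subject generator. Emulates a 90-min dynamic brain PET study
# of a reversible radioligand: a fast-peaking arterial plasma curve with
# multi-exponential washout, a parent fraction declining to just above 0.5
# at 90 min, 15 regional TACs whose ground-truth total distribution
# volumes span 2.7-4.2 mL/cm^3 (cerebellar cortex the non-displaceable
# reference), and frame-duration-dependent Gaussian noise. Everything is
# seeded so each estimator can be validated by parameter recovery.

#' Parameters of the tri-exponential (Feng) arterial plasma model
#'
#' The metabolite-corrected plasma concentration follows the standard
#' bolus-input form
#' \deqn{C_p(t) = (A_1 (t - \tau) - A_2 - A_3) e^{\lambda_1 (t-\tau)} +
#'       A_2 e^{\lambda_2 (t-\tau)} + A_3 e^{\lambda_3 (t-\tau)}}
#' for `t > tau`, zero before the appearance time `tau`: a rapid linear
#' rise to a sharp peak followed by tri-exponential washout. Defaults give
#' a peak of roughly 80 kBq/mL at about 45 s and a slow tail of a few
#' kBq/mL, typical of a bolus-injected carbon-11 ligand at ~350 MBq.
#'
#' The default amplitudes put the plasma peak near 150 kBq/mL (about
#' 350 MBq injected into 70 kg) so that regional tissue peaks reach SUV
#' 4-8. The washout is two-phase over the scan: an intermediate clearance
#' phase (`lambda2`, half-time ~4 min) that is over by ~20 min, after
#' which the slow terminal tail (`lambda3`, half-time of hours) lets
#' tissue reach and hold transient equilibrium - the regime in which
#' graphical analyses of a reversible ligand are linear beyond t* = 20 min
#' and late-window uptake ratios approach the distribution-volume ratio
#' from above.
#'
#' @param A1 Slope of the peak term (kBq·mL^-1·s^-1).
#' @param A2,A3 Amplitudes of the washout exponentials (kBq/mL).
#' @param lambda1,lambda2,lambda3 Negative rates (s^-1), lambda1 < lambda2
#'   < lambda3 < 0.
#' @param delay_tau Appearance time after injection (s).
#' @param blood_to_plasma Whole-blood to total-plasma activity ratio.
#' @return A list of class `input_function_params`.
#' @export
input_function_params <- function(A1 = 36, A2 = 24, A3 = 4,
                                  lambda1 = -0.09, lambda2 = -0.003,
                                  lambda3 = -0.00005,
                                  delay_tau = 20, blood_to_plasma = 0.85) {
  stopifnot(lambda1 < lambda2, lambda2 < lambda3, lambda3 < 0,
            A1 > 0, A2 >= 0, A3 >= 0, delay_tau >= 0, blood_to_plasma > 0)
  structure(list(A1 = A1, A2 = A2, A3 = A3,
                 lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 delay_tau = delay_tau, blood_to_plasma = blood_to_plasma),
            class = "input_function_params")
}

#' Evaluate the model parent-plasma curve
#' @param p An `input_function_params`.
#' @param t Times in seconds (post injection).
#' @return Parent plasma activity (kBq/mL), zero before `delay_tau`.
#' @export
eval_feng <- function(p, t) {
  tt <- pmax(t - p$delay_tau, 0)
  y <- (p$A1 * tt - p$A2 - p$A3) * exp(p$lambda1 * tt) +
    p$A2 * exp(p$lambda2 * tt) + p$A3 * exp(p$lambda3 * tt)
  y[t <= p$delay_tau] <- 0
  pmax(y, 0)
}

#' Parameters of the synthetic parent-fraction (metabolism) model
#'
#' Parent fraction follows a decreasing Hill sigmoid with a nonzero
#' plateau, `f(t) = 1 - (1 - plateau) t^h / (t50^h + t^h)`; defaults give
#' f(90 min) = 0.55, i.e. slightly more than half the plasma activity
#' still parent at scan end, with the metabolite signal split between two
#' more-hydrophilic radiometabolites.
#'
#' @param plateau Asymptotic parent fraction, in (0, 1).
#' @param t50 Half-transition time (s).
#' @param shape Hill exponent (> 0).
#' @param metabolite_split Fraction of metabolite activity assigned to
#'   metabolite 1 (the rest is metabolite 2).
#' @return A list of class `parent_fraction_params`.
#' @export
parent_fraction_params <- function(plateau = 0.5, t50 = 865, shape = 1.2,
                                   metabolite_split = 0.65) {
  stopifnot(plateau > 0, plateau < 1, t50 > 0, shape > 0,
            metabolite_split >= 0, metabolite_split <= 1)
  structure(list(plateau = plateau, t50 = t50, shape = shape,
                 metabolite_split = metabolite_split),
            class = "parent_fraction_params")
}

#' @rdname parent_fraction_params
#' @param p A `parent_fraction_params`.
#' @param t Times in seconds.
#' @export
eval_parent_model <- function(p, t) {
  t <- pmax(t, 0)
  1 - (1 - p$plateau) * t^p$shape / (p$t50^p$shape + t^p$shape)
}

#' Ground-truth regional kinetic parameters
#'
#' @param name Region name.
#' @param K1 Plasma-to-tissue influx (mL·cm^-3·min^-1).
#' @param k2,k3,k4 Rate constants (min^-1); `k3 = 0` encodes a pure
#'   one-tissue (non-displaceable-only) region.
#' @param Vb Fractional blood volume (default 0.05).
#' @return A list of class `region_truth` with derived `vnd = K1/k2`,
#'   `vs = K1 k3/(k2 k4)` and `vt = vnd + vs`.
#' @export
region_truth <- function(name, K1, k2, k3 = 0, k4 = 0.05, Vb = 0.05) {
  stopifnot(K1 > 0, k2 > 0, k3 >= 0, k4 >= 0, Vb >= 0, Vb < 1)
  if (k3 > 0 && k4 <= 0) stop("k4 must be > 0 when k3 > 0")
  vnd <- K1 / k2
  vs <- if (k3 > 0) K1 * k3 / (k2 * k4) else 0
  structure(list(name = name, K1 = K1, k2 = k2, k3 = k3, k4 = k4, Vb = Vb,
                 vnd = vnd, vs = vs, vt = vnd + vs),
            class = "region_truth")
}

# Table of target total distribution volumes for the 15 default regions
# (means of a six-subject arterial cohort; cerebellar cortex is the
# non-displaceable reference with the lowest value).
default_vt_table <- function() {
  c(frontal_cortex = 2.9, temporal_cortex = 2.9, parietal_cortex = 3.0,
    occipital_cortex = 2.9, anterior_cingulate_cortex = 3.0,
    posterior_cingulate_cortex = 3.2, insula = 3.0, thalamus = 3.5,
    caudate = 3.4, putamen = 3.9, pallidum = 4.2, amygdala = 2.9,
    hippocampus = 3.0, cerebellar_cortex = 2.7, pons = 3.8)
}

#' Default 15-region ground truth
#'
#' All regions share K1 = 0.30 mL·cm^-3·min^-1, k2 = K1/2.7 min^-1 (so the
#' non-displaceable volume is 2.7 everywhere) and k4 = 0.05 min^-1; k3 is
#' set per region so that VT = K1/k2·(1 + k3/k4) hits the regional target
#' (2.7 for the cerebellar cortex, generated with k3 = 0 as a pure
#' non-displaceable reference, up to 4.2 for the pallidum). Only the
#' macro-parameters are constrained by the emulated study; the shared
#' micro-parameters are a modelling choice.
#'
#' @param reference Name of the reference region (gets `k3 = 0`).
#' @return Named list of `region_truth` objects.
#' @export
make_default_truth <- function(reference = "cerebellar_cortex") {
  vt <- default_vt_table()
  if (!reference %in% names(vt)) stop("unknown reference region: ", reference)
  vnd <- vt[[reference]]
  K1 <- 0.30
  k2 <- K1 / vnd
  k4 <- 0.05
  out <- lapply(names(vt), function(nm) {
    if (nm == reference) {
      region_truth(nm, K1, k2, k3 = 0, k4 = 0)
    } else {
      region_truth(nm, K1, k2, k3 = k4 * (vt[[nm]] / vnd - 1), k4 = k4)
    }
  })
  stats::setNames(out, names(vt))
}

#' True binding potential of a region against a reference
#' @param truth,ref_truth `region_truth` objects.
#' @return `vt(target)/vt(reference) - 1`.
#' @export
true_bpnd <- function(truth, ref_truth) truth$vt / ref_truth$vt - 1

#' Default arterial and HPLC sampling schedules
#'
#' Arterial sampling: 10-s intervals to 120 s, 30-s to 3 min, 1-min to
#' 10 min, then sparse late samples to 90 min. HPLC parent-fraction
#' sampling at 3, 10, 20, 30, 60 and 90 min.
#'
#' @return Times in seconds.
#' @export
default_blood_times <- function() {
  c(seq(10, 120, by = 10), seq(150, 180, by = 30), seq(240, 600, by = 60),
    c(12, 15, 20, 25, 30, 45, 60, 75, 90) * 60)
}

#' @rdname default_blood_times
#' @export
default_hplc_times <- function() c(3, 10, 20, 30, 60, 90) * 60

#' Generate blood-sample and HPLC tables from the synthetic models
#'
#' Total plasma is parent / f(t) (metabolites add activity on top of the
#' parent curve); whole blood is total plasma times the blood-to-plasma
#' ratio. Optional Gaussian noise (SD = `noise_sd` x current value) is
#' seeded and applied to the measured columns only.
#'
#' @param if_params An `input_function_params`.
#' @param pf_params A `parent_fraction_params`.
#' @param times Blood sample times (s), within the 5400-s scan.
#' @param hplc_times HPLC sample times (s).
#' @param noise_sd Relative noise SD (0 = noise-free).
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return List with data frames `blood` (`time_s`, `whole_blood_kBq_ml`,
#'   `plasma_kBq_ml`) and `hplc` (`time_s`, `parent_fraction`, plus the
#'   two metabolite fractions).
#' @export
sample_blood <- function(if_params = input_function_params(),
                         pf_params = parent_fraction_params(),
                         times = default_blood_times(),
                         hplc_times = default_hplc_times(),
                         noise_sd = 0, seed = 1L) {
  if (any(times < 0 | times > 5400) || any(hplc_times < 0 | hplc_times > 5400)) {
    stop("sample times must lie within the scan span [0, 5400] s")
  }
  parent <- eval_feng(if_params, times)
  f <- eval_parent_model(pf_params, times)
  plasma <- parent / f
  wb <- plasma * if_params$blood_to_plasma
  fh <- eval_parent_model(pf_params, hplc_times)
  if (noise_sd > 0) {
    noisy <- with_seed(seed, {
      list(plasma = plasma * (1 + stats::rnorm(length(plasma), 0, noise_sd)),
           wb = wb * (1 + stats::rnorm(length(wb), 0, noise_sd)),
           fh = pmin(pmax(fh + stats::rnorm(length(fh), 0, noise_sd), 0), 1))
    })
    plasma <- pmax(noisy$plasma, 0); wb <- pmax(noisy$wb, 0); fh <- noisy$fh
  }
  met <- 1 - fh
  list(
    blood = data.frame(time_s = times, whole_blood_kBq_ml = wb,
                       plasma_kBq_ml = plasma),
    hplc = data.frame(time_s = hplc_times, parent_fraction = fh,
                      metabolite1_fraction = met * pf_params$metabolite_split,
                      metabolite2_fraction = met * (1 - pf_params$metabolite_split))
  )
}

#' Simulate one regional time-activity curve
#'
#' Frame values are averages of the continuous model curve
#' `(1 - Vb)(C1 + C2) + Vb Cb` over each frame (>= 10 sub-samples per
#' frame). Additive Gaussian noise emulates count statistics on
#' decay-corrected data:
#' \deqn{SD_i = scale \sqrt{C_{model}(t_{mid,i})
#'       e^{\lambda_{phys} t_{mid,i}} / \Delta t_i}}
#' with `lambda_phys = log(2) / (20.4 * 60)` s^-1 (carbon-11): undoing the
#' decay correction recovers the counted activity whose relative variance
#' grows in late, short-count frames.
#'
#' @param truth A `region_truth`.
#' @param inf An `input_function` (typically noise-free synthetic).
#' @param schedule A `frame_schedule`.
#' @param noise_scale Noise magnitude (0 = noise-free); default 0.
#' @param seed Integer seed for the noise draws.
#' @return A `tac`.
#' @export
simulate_region_tac <- function(truth, inf, schedule, noise_scale = 0,
                                seed = 1L) {
  stopifnot(inherits(truth, "region_truth"))
  pars <- list(K1 = truth$K1, k2 = truth$k2, k3 = truth$k3, k4 = truth$k4,
               Vb = truth$Vb)
  tc <- model_tissue_curve(pars, inf, schedule, label = truth$name)
  if (noise_scale > 0) {
    lam <- log(2) / (20.4 * 60)
    cmid <- model_tissue_cont(pars, inf, schedule$frame_mid)
    sdv <- noise_scale *
      sqrt(pmax(cmid, 0) * exp(lam * schedule$frame_mid) / schedule$frame_duration)
    noisy <- with_seed(seed, tc$activity + stats::rnorm(length(sdv), 0, sdv))
    tc <- tac(schedule, noisy, label = truth$name)
  }
  tc
}

#' Simulate a complete synthetic subject
#'
#' Bundles seeded blood and HPLC tables, all regional TACs from the
#' default (or supplied) ground truth, and optionally a small labelled 4D
#' volume in which every voxel is an independent noisy realisation of its
#' region's model curve.
#'
#' @param truth Named list of `region_truth` (default [make_default_truth()]).
#' @param if_params,pf_params Synthetic blood models.
#' @param schedule Frame schedule (default the 33-frame 90-min protocol).
#' @param noise_scale TAC noise magnitude (default 0.1; 0 = noise-free).
#' @param blood_noise_sd Relative noise on blood samples (default 0).
#' @param seed Master integer seed; per-region seeds are derived from it.
#' @param volume `FALSE`, or a length-3 integer vector of volume
#'   dimensions (e.g. `c(16, 16, 8)`); each region occupies a block of
#'   voxels.
#' @param free_fraction_mean,free_fraction_sd Plasma free-fraction
#'   triplicate generator (percent), carried as metadata only.
#' @return A list of class `synthetic_subject` with `blood`, `hplc`,
#'   `tacs`, `truth`, `input` (the noise-free generating `input_function`),
#'   `volume` (or NULL), `free_fraction`, `seed`, `noise_scale`.
#' @export
simulate_subject <- function(truth = make_default_truth(),
                             if_params = input_function_params(),
                             pf_params = parent_fraction_params(),
                             schedule = default_frame_schedule(),
                             noise_scale = 0.1, blood_noise_sd = 0,
                             seed = 1L, volume = FALSE,
                             free_fraction_mean = 23.3,
                             free_fraction_sd = 2.2) {
  seed <- as.integer(seed)
  tables <- sample_blood(if_params, pf_params, noise_sd = blood_noise_sd,
                         seed = derive_seed(seed, "blood"))
  # the generating (noise-free, truth) input function on a dense grid
  inf <- dense_input_function(if_params)
  tacs <- list()
  for (nm in names(truth)) {
    tacs[[nm]] <- simulate_region_tac(truth[[nm]], inf, schedule,
                                      noise_scale = noise_scale,
                                      seed = derive_seed(seed, nm))
  }
  vol <- NULL
  if (!identical(volume, FALSE)) {
    vol <- simulate_volume(truth, inf, schedule, dims = volume,
                           noise_scale = noise_scale,
                           seed = derive_seed(seed, "volume"))
  }
  fp <- with_seed(derive_seed(seed, "fp"), {
    pmin(pmax(stats::rnorm(3, free_fraction_mean, free_fraction_sd), 0), 100)
  })
  structure(list(
    blood = tables$blood, hplc = tables$hplc, tacs = tacs, truth = truth,
    input = inf, volume = vol, free_fraction = free_fraction(fp),
    if_params = if_params, pf_params = pf_params,
    seed = seed, noise_scale = noise_scale
  ), class = "synthetic_subject")
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf(
    "Synthetic subject (seed %d): %d regions, noise scale %g, %s volume\n",
    x$seed, length(x$tacs), x$noise_scale,
    if (is.null(x$volume)) "no" else paste(dim(x$volume$data)[1:3], collapse = "x")))
  invisible(x)
}

# noise-free continuous input function sampled on a dense grid so the
# piecewise-linear representation error is negligible
dense_input_function <- function(if_params, t_end = 5400) {
  tt <- sort(unique(c(seq(0, 180, by = 1), seq(182, 600, by = 2),
                      seq(605, t_end, by = 5), t_end)))
  cp <- eval_feng(if_params, tt)
  structure(list(time = tt, cp = cp, cb = cp * if_params$blood_to_plasma,
                 interp = "linear", tail_fit = NULL, t_end = t_end),
            class = "input_function")
}

# labelled 4D volume: one voxel block per region, independent noise per voxel
simulate_volume <- function(truth, inf, schedule, dims = c(16, 16, 8),
                            noise_scale = 0.1, seed = 1L) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 4L))
  nreg <- length(truth)
  nframe <- nrow(schedule)
  labels <- array(0L, dims)
  data <- array(0, c(dims, nframe))
  # block size: split x-y plane into a grid with enough cells for all regions
  nx <- ceiling(sqrt(nreg))
  ny <- ceiling(nreg / nx)
  bx <- max(dims[1] %/% nx, 1L); by <- max(dims[2] %/% ny, 1L)
  lam <- log(2) / (20.4 * 60)
  flat_frames <- matrix(0, prod(dims), nframe)
  reg_names <- names(truth)
  for (r in seq_len(nreg)) {
    ix <- (r - 1L) %% nx
    iy <- (r - 1L) %/% nx
    xs <- (ix * bx + 1L):min((ix + 1L) * bx, dims[1])
    ys <- (iy * by + 1L):min((iy + 1L) * by, dims[2])
    zs <- seq_len(dims[3])
    tr <- truth[[r]]
    pars <- list(K1 = tr$K1, k2 = tr$k2, k3 = tr$k3, k4 = tr$k4, Vb = tr$Vb)
    mu <- model_tissue_curve(pars, inf, schedule)$activity
    cmid <- model_tissue_cont(pars, inf, schedule$frame_mid)
    sdv <- noise_scale *
      sqrt(pmax(cmid, 0) * exp(lam * schedule$frame_mid) / schedule$frame_duration)
    vox <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
    lin <- vox[, 1] + (vox[, 2] - 1L) * dims[1] + (vox[, 3] - 1L) * dims[1] * dims[2]
    labels[lin] <- r
    nv <- length(lin)
    noise <- if (noise_scale > 0) {
      with_seed(derive_seed(seed, reg_names[r]), {
        matrix(stats::rnorm(nv * nframe, 0, rep(sdv, each = nv)), nv, nframe)
      })
    } else matrix(0, nv, nframe)
    flat_frames[lin, ] <- matrix(mu, nv, nframe, byrow = TRUE) + noise
  }
  data <- array(flat_frames, c(dims, nframe))
  labelled_volume(data, labels, schedule,
                  stats::setNames(reg_names, as.character(seq_len(nreg))))
}

#' Simulate a cohort of subjects with between-subject variability
#'
#' Subjects share the default kinetics up to a per-subject multiplier on
#' K1 (lognormal, coefficient of variation `vt_cv`), which scales every
#' regional VT proportionally — a simple model of between-subject spread
#' in total distribution volume.
#'
#' @param n Number of subjects.
#' @param vt_cv Between-subject coefficient of variation of VT (default
#'   0.10).
#' @param seed Master seed.
#' @param ... Passed to [simulate_subject()].
#' @return List of `synthetic_subject`.
#' @export
simulate_cohort <- function(n = 7L, vt_cv = 0.10, seed = 1L, ...) {
  seed <- as.integer(seed)
  mult <- with_seed(derive_seed(seed, "cohort"), {
    sdlog <- sqrt(log(1 + vt_cv^2))
    exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
  })
  lapply(seq_len(n), function(s) {
    base <- make_default_truth()
    truth <- lapply(base, function(tr) {
      region_truth(tr$name, tr$K1 * mult[s], tr$k2, tr$k3, tr$k4, tr$Vb)
    })
    simulate_subject(truth = stats::setNames(truth, names(base)),
                     seed = derive_seed(seed, paste0("subject", s)), ...)
  })
}

#' Peak standardized uptake value of a TAC
#'
#' SUV = activity / (injected dose / body weight); the defaults (350 MBq
#' into a 70-kg subject) put regional peaks of the default synthetic
#' kinetics in the physiologic 4-8 range.
#'
#' @param tc A `tac` (kBq/mL).
#' @param injected_dose_MBq Injected activity in MBq.
#' @param body_weight_kg Body weight in kg.
#' @return Peak SUV (dimensionless, density 1 g/mL assumed).
#' @export
peak_suv <- function(tc, injected_dose_MBq = 350, body_weight_kg = 70) {
  dose_kBq <- injected_dose_MBq * 1000
  weight_g <- body_weight_kg * 1000
  max(tc$activity) / (dose_kBq / weight_g)
}

# stable per-stage seed derivation from a master seed
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}
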