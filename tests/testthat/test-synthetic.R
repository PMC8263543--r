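test_that("default ground truth hits the regional VT targets", {
  truth <- default_truth_cached()
  expect_length(truth, 15L)
  expect_equal(truth$pallidum$vt, 4.2)
  expect_equal(truth$cerebellar_cortex$vt, 2.7)
  expect_equal(truth$cerebellar_cortex$k3, 0)
  expect_equal(true_bpnd(truth$pallidum, truth$cerebellar_cortex),
               4.2 / 2.7 - 1)
  # VT computed from micro-parameters equals vnd + vs exactly, every region
  for (tr in truth) {
    vt_macro <- tr$K1 / tr$k2 * (1 + if (tr$k4 > 0) tr$k3 / tr$k4 else 0)
    expect_equal(tr$vt, vt_macro)
    expect_equal(tr$vt, tr$vnd + tr$vs)
  }
  # non-displaceable volume is shared (same K1/k2 everywhere)
  expect_equal(unique(vapply(truth, function(x) x$vnd, numeric(1))), 2.7)
})

test_that("blood sampling follows the generator models and the seed contract", {
  pp_none <- parent_fraction_params(plateau = 1 - 1e-9)
  sb <- sample_blood(pf_params = pp_none)
  # no metabolism: total plasma equals the parent curve
  expect_equal(sb$blood$plasma_kBq_ml,
               eval_feng(input_function_params(), sb$blood$time_s),
               tolerance = 1e-6)

  # default metabolism leaves > 50% parent at scan end
  sb2 <- sample_blood()
  expect_gt(min(sb2$hplc$parent_fraction), 0.5)
  expect_equal(sb2$hplc$parent_fraction +
                 sb2$hplc$metabolite1_fraction + sb2$hplc$metabolite2_fraction,
               rep(1, nrow(sb2$hplc)))

  # seeds: noise-free columns identical, noisy columns differ across seeds
  a <- sample_blood(noise_sd = 0.03, seed = 1L)
  b <- sample_blood(noise_sd = 0.03, seed = 2L)
  expect_identical(a$blood$time_s, b$blood$time_s)
  expect_false(identical(a$blood$plasma_kBq_ml, b$blood$plasma_kBq_ml))
  expect_identical(sample_blood(noise_sd = 0.03, seed = 5L),
                   sample_blood(noise_sd = 0.03, seed = 5L))

  expect_error(sample_blood(times = c(100, 6000)), "scan span")
})

test_that("simulated TACs match the forward model and its limits", {
  subj <- noise_free_subject()
  inf <- subj$input
  sched <- subj$tacs[[1]]$schedule
  truth <- default_truth_cached()

  # pure blood voxel: Vb = 1 reproduces frame-averaged whole blood
  tr_blood <- region_truth("blood", K1 = 0.3, k2 = 0.1, Vb = 1 - 1e-12)
  tb <- simulate_region_tac(tr_blood, inf, sched)
  cb_frames <- vapply(seq_len(nrow(sched)), function(i) {
    tt <- seq(sched$frame_start[i], sched$frame_end[i], length.out = 11)
    y <- eval_input(inf, tt, "cb")
    sum(diff(tt) * (y[-length(y)] + y[-1]) / 2) / sched$frame_duration[i]
  }, numeric(1))
  expect_equal(tb$activity, cb_frames, tolerance = 1e-9)

  # noise-free k3 = 0 solution agrees with a fine-grid RK4 integration < 0.1%
  cer <- truth$cerebellar_cortex
  pars <- list(K1 = cer$K1, k2 = cer$k2, k3 = 0, k4 = 0, Vb = 0)
  ct <- petkin:::model_tissue_cont(pars, inf, sched$frame_mid)
  oracle <- ode_tissue_oracle(pars, inf, sched$frame_mid)
  expect_lt(max(abs(ct - oracle)) / max(oracle), 0.001)

  # binding regions retain activity: pallidum washes out slower than the
  # reference after the early peak
  pal <- subj$tacs$pallidum$activity
  crb <- subj$tacs$cerebellar_cortex$activity
  late <- sched$frame_mid > 1800
  expect_true(all(pal[late] / crb[late] > 1))
  expect_gt(utils::tail(pal, 1) / utils::tail(crb, 1), 1.3)
})

test_that("increasing k3 increases VT and late-time retention", {
  subj <- noise_free_subject()
  sched <- subj$tacs[[1]]$schedule
  k3s <- c(0.01, 0.02, 0.04, 0.08)
  vts <- numeric(0); lates <- numeric(0)
  for (k3 in k3s) {
    tr <- region_truth("r", K1 = 0.3, k2 = 0.3 / 2.7, k3 = k3, k4 = 0.05)
    vts <- c(vts, tr$vt)
    lates <- c(lates, utils::tail(simulate_region_tac(tr, subj$input,
                                                      sched)$activity, 1))
  }
  expect_true(all(diff(vts) > 0))
  expect_true(all(diff(lates) > 0))
})

test_that("subject generation is reproducible bit-for-bit from its seed", {
  s1 <- simulate_subject(noise_scale = 0.1, seed = 77L)
  s2 <- simulate_subject(noise_scale = 0.1, seed = 77L)
  expect_identical(s1$blood, s2$blood)
  expect_identical(lapply(s1$tacs, `[[`, "activity"),
                   lapply(s2$tacs, `[[`, "activity"))
  expect_identical(s1$free_fraction, s2$free_fraction)
  s3 <- simulate_subject(noise_scale = 0.1, seed = 78L)
  expect_false(identical(s1$tacs$pallidum$activity,
                         s3$tacs$pallidum$activity))
})

test_that("regional peaks land in the physiologic SUV range", {
  subj <- noise_free_subject()
  suvs <- vapply(subj$tacs, peak_suv, numeric(1))
  expect_true(all(suvs >= 4 & suvs <= 8))
})

test_that("volume voxels realise the regional model and converge to it", {
  subj <- noise_free_subject()
  vol0 <- simulate_subject(noise_scale = 0, seed = 5L,
                           volume = c(8, 8, 4))$volume
  rois <- extract_roi_tacs(vol0)
  # noise-free voxel means equal the regional model curve
  expect_equal(rois$pallidum$activity, subj$tacs$pallidum$activity,
               tolerance = 1e-9)
  # label blocks cover every region
  expect_length(rois, 15L)

  # noisy voxels average towards the model curve
  voln <- simulate_subject(noise_scale = 0.3, seed = 5L,
                           volume = c(8, 8, 4))$volume
  roin <- extract_roi_tacs(voln)
  expect_false(identical(roin$pallidum$activity, subj$tacs$pallidum$activity))
  late <- subj$tacs$pallidum$schedule$frame_mid > 600
  relerr <- abs(roin$pallidum$activity - subj$tacs$pallidum$activity) /
    subj$tacs$pallidum$activity
  expect_lt(stats::median(relerr[late]), 0.05)
})

test_that("noise-free self-fits recover the generating micro-parameters", {
  subj <- noise_free_subject()
  truth <- default_truth_cached()
  for (nm in c("pallidum", "cerebellar_cortex")) {
    tr <- truth[[nm]]
    kind <- if (tr$k3 > 0) "2tcm" else "1tcm"
    init <- c(K1 = tr$K1, k2 = tr$k2, k3 = max(tr$k3, 0.01), k4 = max(tr$k4, 0.01))
    fit <- fit_compartment(subj$tacs[[nm]], subj$input, kind, init = init,
                           n_restarts = 1)
    expect_lt(abs(fit$vt - tr$vt) / tr$vt, 0.002)
    expect_lt(abs(fit$params[["K1"]] - tr$K1) / tr$K1, 1e-3)
    expect_lt(abs(fit$params[["k2"]] - tr$k2) / tr$k2, 1e-3)
  }
})

test_that("cohort generation spreads VT with the requested between-subject CV", {
  cohort <- simulate_cohort(n = 7, vt_cv = 0.10, seed = 4L, noise_scale = 0)
  vts <- vapply(cohort, function(s) s$truth$pallidum$vt, numeric(1))
  cv <- cov_percent(vts)
  # n = 7 estimate of a 10% CV: wide sampling band
  expect_gt(cv, 4)
  expect_lt(cv, 16)
})
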