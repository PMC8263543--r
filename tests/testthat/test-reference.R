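test_that("indirect BPND is the distribution-volume ratio minus one", {
  expect_equal(indirect_bpnd(3.3, 3.3), 0)
  expect_equal(indirect_bpnd(4.2, 2.7), 4.2 / 2.7 - 1)
  expect_equal(indirect_bpnd(2.7, 4.2), 2.7 / 4.2 - 1)  # negative allowed
  expect_error(indirect_bpnd(3, 0), "> 0")
})

test_that("MRTMo returns BPND = 0 for a region identical to the reference", {
  subj <- noise_free_subject()
  cer <- subj$tacs$cerebellar_cortex
  fit <- mrtmo_fit(cer, cer)
  expect_true(fit$ok)
  expect_equal(fit$bpnd, 0, tolerance = 1e-9)
})

test_that("MRTMo recovers synthetic binding potentials from TACs alone", {
  subj <- noise_free_subject()
  truth <- default_truth_cached()
  cer <- subj$tacs$cerebellar_cortex
  bp_true <- true_bpnd(truth$pallidum, truth$cerebellar_cortex)
  fit <- mrtmo_fit(subj$tacs$pallidum, cer)
  expect_lt(abs(fit$bpnd - bp_true) / bp_true, 0.05)
  expect_gt(fit$r_squared, 0.999)
  expect_error(mrtmo_fit(subj$tacs$pallidum, cer, t_star = 5300),
               "insufficient")
})

test_that("MRTMo noise bias is negative and small at low binding", {
  subj <- noise_free_subject()
  truth <- default_truth_cached()
  sched <- subj$tacs[[1]]$schedule
  cer <- subj$tacs$cerebellar_cortex
  for (region in c("frontal_cortex", "pallidum")) {
    bp0 <- mrtmo_fit(subj$tacs[[region]], cer)$bpnd
    bps <- vapply(1:100, function(i) {
      tc <- simulate_region_tac(truth[[region]], subj$input, sched,
                                noise_scale = 1.0, seed = 9000 + i)
      mrtmo_fit(tc, cer)$bpnd
    }, numeric(1))
    expect_lte(stats::median(bps) - bp0, 0)
  }
  # the low-binding bias is small in absolute terms
  bp0f <- mrtmo_fit(subj$tacs$frontal_cortex, cer)$bpnd
  bpsf <- vapply(1:100, function(i) {
    tc <- simulate_region_tac(truth$frontal_cortex, subj$input, sched,
                              noise_scale = 1.0, seed = 9000 + i)
    mrtmo_fit(tc, cer)$bpnd
  }, numeric(1))
  expect_lt(abs(stats::median(bpsf) - bp0f), 0.02)
})

test_that("parametric MRTMo maps agree with ROI fits and honour the mask", {
  subj <- noise_free_subject()
  vol <- simulate_subject(noise_scale = 0, seed = 5L,
                          volume = c(8, 8, 4))$volume
  cer <- extract_roi_tacs(vol)$cerebellar_cortex
  res <- mrtmo_parametric(vol, cer)
  expect_equal(res$n_failed, 0L)
  # per-region map means match the ROI-level fits to < 1%
  rois <- extract_roi_tacs(vol)
  for (nm in c("pallidum", "putamen", "thalamus")) {
    lab <- which(vol$region_names == nm)
    roi_bp <- mrtmo_fit(rois[[nm]], cer)$bpnd
    map_bp <- mean(res$map[vol$labels == as.integer(names(vol$region_names)[lab])])
    expect_lt(abs(map_bp - roi_bp) / max(abs(roi_bp), 0.05), 0.01)
  }

  # a volume where every voxel equals the reference maps to zeros
  nframe <- nrow(vol$schedule)
  flat <- array(rep(cer$activity, each = 4 * 4 * 2), c(4, 4, 2, nframe))
  labs <- array(1L, c(4, 4, 2))
  vol0 <- labelled_volume(flat, labs, vol$schedule, c("1" = "ref_copy"))
  res0 <- mrtmo_parametric(vol0, cer)
  expect_equal(max(abs(res0$map)), 0, tolerance = 1e-9)

  # masked-out voxels keep the fill value, never fitted
  mask <- vol$labels != 0
  mask[1:4, , ] <- FALSE
  resm <- mrtmo_parametric(vol, cer, mask = mask, fill = -99)
  expect_true(all(resm$map[1:4, , ] == -99))
})

test_that("SUVR windows are duration-weighted and behave as expected", {
  subj <- noise_free_subject()
  expect_equal(default_suvr_windows(),
               list(c(2400, 3600), c(3000, 4200), c(3600, 4800), c(4200, 5400)))

  st <- suvr_minus_one(subj$tacs)
  # the reference region scores 0 in every window
  ref_rows <- st[st$region == "cerebellar_cortex", ]
  expect_equal(ref_rows$suvr_minus_one, rep(0, 4))

  # high-binding region: late-window SUVR-1 exceeds the true BPND
  bp_pal <- true_bpnd(default_truth_cached()$pallidum,
                      default_truth_cached()$cerebellar_cortex)
  pal_late <- st$suvr_minus_one[st$region == "pallidum" &
                                  st$window_start_s == 4200]
  expect_gt(pal_late, bp_pal)

  # across regions, the SUVR-1 slope on true BPND declines window by window
  bp_true <- true_bpnd_vector()
  nz <- names(bp_true)[bp_true > 0]
  slopes <- vapply(c(2400, 3000, 3600, 4200), function(ws) {
    s <- st[st$window_start_s == ws & st$region %in% nz, ]
    unname(stats::coef(stats::lm(s$suvr_minus_one ~ bp_true[s$region]))[2])
  }, numeric(1))
  expect_true(all(diff(slopes) < 0))
  expect_true(all(slopes > 1))

  expect_error(suvr_minus_one(subj$tacs, windows = list(c(5000, 6000))),
               "scan span")
})

test_that("method comparison reproduces closed-form regression identities", {
  a <- c(0.1, 0.25, 0.3, 0.45, 0.6)

  same <- compare_methods(a, a)
  expect_equal(same$slope, 1)
  expect_equal(same$intercept, 0)
  expect_equal(same$r_squared, 1)
  expect_equal(same$ba_mean_diff, 0)
  expect_equal(same$ba_loa, c(0, 0))

  dbl <- compare_methods(a, 2 * a)
  expect_equal(dbl$slope, 2)
  expect_equal(dbl$intercept, 0)
  # (B - A) on (A + B)/2 with B = 2A: slope A / (1.5 A) = 2/3
  expect_equal(dbl$ba_prop_bias_slope, 2 / 3)

  # three hand-picked pairs vs hand-computed least squares
  x <- c(1, 2, 3); y <- c(2, 2.5, 4)
  hand_slope <- sum((x - 2) * (y - mean(y))) / sum((x - 2)^2)
  hand_int <- mean(y) - hand_slope * 2
  cs <- compare_methods(x, y)
  expect_equal(cs$slope, hand_slope)
  expect_equal(cs$intercept, hand_int)

  expect_error(compare_methods(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(compare_methods(c(1, 2), c(1, 2)), "at least 3")
})
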