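test_that("parent-fraction fitting recovers known curves and edge cases", {
  tt <- default_hplc_times()

  # fully unmetabolized tracer: f stays 1 everywhere
  pf1 <- fit_parent_fraction(data.frame(time_s = tt, parent_fraction = 1),
                             "linear_interp")
  expect_equal(eval_parent_fraction(pf1, c(0, 1000, 5400)), rep(1, 3))

  # samples generated from a known Hill curve are recovered to < 1e-6
  pp <- parent_fraction_params()
  hplc <- data.frame(time_s = tt, parent_fraction = eval_parent_model(pp, tt))
  pf <- fit_parent_fraction(hplc, "hill")
  grid <- seq(0, 5400, by = 20)
  expect_lt(max(abs(eval_parent_fraction(pf, grid) -
                      eval_parent_model(pp, grid))), 1e-6)
  expect_equal(eval_parent_fraction(pf, 0), 1)

  # slow metabolism: more than half the activity still parent at 90 min
  expect_gt(eval_parent_fraction(pf, 5400), 0.5)

  # interpolation kind is monotone-safe, anchored at 1, constant after end
  wob <- data.frame(time_s = c(300, 1200, 3000),
                    parent_fraction = c(0.9, 0.95, 0.6))
  pfi <- fit_parent_fraction(wob, "linear_interp")
  v <- eval_parent_fraction(pfi, seq(0, 5400, by = 60))
  expect_true(all(diff(v) <= 1e-12))
  expect_equal(eval_parent_fraction(pfi, 5400),
               eval_parent_fraction(pfi, 3000))

  expect_error(fit_parent_fraction(
    data.frame(time_s = c(60, 600), parent_fraction = c(1, 1.2)), "hill"),
    "\\[0, 1\\]")
})

test_that("metabolite correction scales plasma by the parent fraction", {
  sb <- sample_blood()
  pf1 <- fit_parent_fraction(
    data.frame(time_s = default_hplc_times(), parent_fraction = 1),
    "linear_interp")
  out <- metabolite_correct(sb$blood, pf1)
  expect_equal(out$plasma_parent_kBq_ml, sb$blood$plasma_kBq_ml)
  expect_equal(out$whole_blood_kBq_ml, sb$blood$whole_blood_kBq_ml)

  half <- fit_parent_fraction(
    data.frame(time_s = c(0, 2700, 5400), parent_fraction = 0.5),
    "linear_interp")
  # interpolation anchors f(0) = 1; check the constant part only
  out2 <- metabolite_correct(sb$blood[sb$blood$time_s >= 2700, ], half)
  expect_equal(out2$plasma_parent_kBq_ml, out2$plasma_kBq_ml * 0.5)
})

test_that("fitted parent model recovers the generator's parent curve", {
  sb <- sample_blood()
  pf <- fit_parent_fraction(sb$hplc, "hill")
  corr <- metabolite_correct(sb$blood, pf)
  truthp <- eval_feng(input_function_params(), sb$blood$time_s)
  late <- sb$blood$time_s > 60
  expect_lt(max(abs(corr$plasma_parent_kBq_ml - truthp)[late] / truthp[late]),
            0.01)
})

test_that("input-function interpolation and integration are exact for lines", {
  # samples on a straight line through the origin region
  tt <- c(30, 60, 120, 300)
  blood <- data.frame(time_s = tt, whole_blood_kBq_ml = 0.8 * tt,
                      plasma_kBq_ml = tt)
  inf <- build_input_function(blood)
  expect_equal(eval_input(inf, c(45, 90, 210)), c(45, 90, 210))

  # triangle-shaped curve: integral has a closed form
  tri <- data.frame(time_s = c(60, 120, 180),
                    whole_blood_kBq_ml = c(10, 0, 0),
                    plasma_kBq_ml = c(10, 0, 0))
  inf_t <- build_input_function(tri)
  # triangle (0,0)-(60,10)-(120,0): area = 0.5 * 120 * 10 = 600
  expect_equal(integrate_input(inf_t, 120), 600)
  expect_equal(integrate_input(inf_t, 60), 300)
  expect_equal(integrate_input(inf_t, 180), 600)

  # evaluation beyond the last sample: constant with a warning
  expect_warning(v <- eval_input(inf, 400), "beyond last sample")
  expect_equal(v, 300)
})

test_that("input-function construction is order-insensitive and clips negatives", {
  sb <- sample_blood()
  inf1 <- build_input_function(sb$blood)
  perm <- sb$blood[sample.int(nrow(sb$blood)), ]
  inf2 <- build_input_function(perm)
  expect_identical(inf1$cp, inf2$cp)
  expect_identical(inf1$time, inf2$time)

  neg <- sb$blood
  neg$plasma_kBq_ml[5] <- -1
  expect_warning(inf3 <- build_input_function(neg), "clipped")
  expect_true(all(inf3$cp >= 0))
})

test_that("plasma integral is monotone and matches a 10x finer grid", {
  sb <- sample_blood()
  pf <- fit_parent_fraction(sb$hplc, "hill")
  inf <- build_input_function(metabolite_correct(sb$blood, pf))
  Ts <- seq(120, 5400, by = 120)
  ints <- integrate_input(inf, Ts)
  expect_true(all(diff(ints) > 0))
  fine <- seq(0, 5400, by = 0.5)
  cpv <- eval_input(inf, fine)
  cumfine <- cumsum(c(0, diff(fine) * (cpv[-length(cpv)] + cpv[-1]) / 2))
  expect_lt(max(abs(ints - stats::approx(fine, cumfine, Ts)$y) / ints), 0.005)
})

test_that("loglinear tail extrapolates a decaying exponential sensibly", {
  tt <- seq(600, 5400, by = 600)
  blood <- data.frame(time_s = tt, whole_blood_kBq_ml = 8 * exp(-tt / 3000),
                      plasma_kBq_ml = 10 * exp(-tt / 3000))
  inf <- build_input_function(blood, interp = "loglinear_tail")
  # beyond the last sample the mono-exponential continues to decay
  v <- eval_input(inf, c(6000, 7200))
  expect_true(all(diff(v) < 0))
  expect_equal(v[1], 10 * exp(-6000 / 3000), tolerance = 0.01)
})

test_that("free-fraction summaries follow the two-pass formula", {
  r <- free_fraction(c(23.3, 23.3, 23.3))
  expect_equal(r$mean, 23.3)
  expect_equal(r$sd, 0)

  one <- free_fraction(21)
  expect_equal(one$sd, 0)
  expect_equal(one$n, 1L)

  x <- c(20.9, 23.3, 25.1)
  m <- (20.9 + 23.3 + 25.1) / 3
  s <- sqrt(((20.9 - m)^2 + (23.3 - m)^2 + (25.1 - m)^2) / 2)
  r3 <- free_fraction(x)
  expect_equal(r3$mean, m)
  expect_equal(r3$sd, s)

  expect_error(free_fraction(c(50, 120)), "\\[0, 100\\]")
})
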