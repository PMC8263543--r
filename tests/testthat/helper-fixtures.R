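# Shared fixtures, built once per test run. Everything is generated in
# code from the seeded synthetic models; no data files are involved.

.fixtures <- new.env(parent = emptyenv())

# noise-free default synthetic subject plus its generating input function
noise_free_subject <- function() {
  if (is.null(.fixtures$subj0)) {
    .fixtures$subj0 <- simulate_subject(noise_scale = 0, seed = 1L)
  }
  .fixtures$subj0
}

default_truth_cached <- function() {
  if (is.null(.fixtures$truth)) .fixtures$truth <- make_default_truth()
  .fixtures$truth
}

true_vt_vector <- function() {
  vapply(default_truth_cached(), function(x) x$vt, numeric(1))
}

true_bpnd_vector <- function() {
  truth <- default_truth_cached()
  vapply(truth, function(x) true_bpnd(x, truth$cerebellar_cortex), numeric(1))
}

# fine-grid RK4 integration of the compartment ODEs against the same
# piecewise-linear plasma input: the independent oracle for the analytic
# convolution solver (rates in min^-1, times in seconds)
ode_tissue_oracle <- function(pars, inf, times, dt = 0.25) {
  cpf <- stats::approxfun(inf$time, inf$cp, rule = 2)
  rhs <- function(t, y, p) {
    cp <- cpf(t)
    list(c(p[["K1"]] * cp - (p[["k2"]] + p[["k3"]]) * y[1] + p[["k4"]] * y[2],
           p[["k3"]] * y[1] - p[["k4"]] * y[2]))
  }
  p <- c(K1 = pars$K1 / 60, k2 = pars$k2 / 60,
         k3 = pars$k3 / 60, k4 = pars$k4 / 60)
  grid <- seq(0, max(times), by = dt)
  out <- deSolve::ode(c(0, 0), grid, rhs, p, method = "rk4")
  ct <- out[, 2] + out[, 3]
  stats::approx(grid, ct, xout = times)$y
}
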