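# Forward temporal model: gate integrals, wrap-around, IRF convolution,
# t0 and background estimation.

test_that("delta-IRF gate counts match the analytic closed form", {
  sch <- gate_scheme()
  for (tau in c(800, 2000, 2500, 4000)) {
    W <- wrap_factor(tau, sch$rep_period)
    expected <- 3 * tau * exp(-sch$delays / tau) *
      (1 - exp(-sch$width / tau)) * W
    got <- model_gate_signal(3, tau, 1, irf_delta(), sch)
    expect_equal(got, expected, tolerance = 1e-12)
  }
  # pure-exponential gate ratio: delays 0 and 2000 ps at tau = 2000 ps
  sch2 <- gate_scheme(delays = c(0, 2000))
  y <- model_gate_signal(1, 2000, 1, irf_delta(), sch2)
  expect_equal(y[2] / y[1], exp(-1), tolerance = 1e-12)
})

test_that("wrap factor equals the geometric sum over preceding pulses", {
  P <- 1e6 / 60
  for (tau in c(1000, 2500, 4000)) {
    oracle <- sum(exp(-(0:50) * P / tau))
    expect_equal(wrap_factor(tau, P), oracle, tolerance = 1e-12)
  }
  expect_equal(wrap_factor(2500, 50000 / 3), 1 / (1 - exp(-6.66667)),
               tolerance = 1e-5)
})

test_that("degenerate mixture fractions reduce to the single component", {
  sch <- gate_scheme()
  single <- model_gate_signal(2, 1500, 1, irf_delta(), sch)
  mixed <- model_gate_signal(2, c(3100, 1500), c(0, 1), irf_delta(), sch)
  expect_equal(mixed, single, tolerance = 1e-14)
})

test_that("invalid fractions and lifetimes are rejected", {
  sch <- gate_scheme()
  expect_error(model_gate_signal(1, c(1000, 2000), c(0.6, 0.5),
                                 irf_delta(), sch), "sum to 1")
  expect_error(model_gate_signal(1, c(1000, 2000), c(1.2, -0.2),
                                 irf_delta(), sch), "non-negative")
  expect_error(model_gate_signal(1, -5, 1, irf_delta(), sch), "> 0")
})

test_that("gate signal is linear in amplitude and background", {
  sch <- gate_scheme()
  base <- model_gate_signal(1, 2200, 1, irf_delta(), sch)
  expect_equal(model_gate_signal(7, 2200, 1, irf_delta(), sch), 7 * base,
               tolerance = 1e-12)
  bg <- c(5, 4, 3, 2, 1)
  expect_equal(model_gate_signal(1, 2200, 1, irf_delta(), sch, bg),
               base + bg, tolerance = 1e-12)
})

test_that("one gate spanning the whole period collects amplitude * tau", {
  P <- 1e6 / 60
  for (delay in c(0, 3000, 12000)) {
    sch <- gate_scheme(delays = delay, width = P, rep_period = P)
    got <- model_gate_signal(2, 2500, 1, irf_delta(), sch)
    expect_equal(got, 2 * 2500, tolerance = 1e-10)
  }
})

test_that("narrow IRF convolution converges to the delta closed form", {
  # the IRF sits away from the gate edges (decay onset at 300 ps), where
  # the gate integral is smooth; an equivalent delta IRF is a t0 shift
  tau <- 2500
  sch_d <- gate_scheme(t0 = 300)
  sch <- gate_scheme()
  delta <- model_gate_signal(1, tau, 1, irf_delta(), sch_d)
  narrow <- model_gate_signal(1, tau, 1, irf_gaussian(300, tau / 100), sch)
  expect_lt(max(abs(narrow - delta) / delta), 1e-3)
  # a measured IRF sampled from the same narrow Gaussian behaves alike
  tgrid <- seq(150, 450, by = 5)
  amp <- dnorm(tgrid, 300, (tau / 100) / 2.3548)
  meas <- model_gate_signal(1, tau, 1, irf_measured(tgrid, amp), sch)
  expect_lt(max(abs(meas - delta) / delta), 1e-3)
})

test_that("measured IRF construction validates and normalises", {
  expect_error(irf_measured(c(0, 10, 20), c(1, -1, 1)), ">= 0")
  expect_error(irf_measured(c(0, 10, 15), c(1, 1, 1)), "uniform")
  irf <- irf_measured(seq(0, 100, by = 10), rep(2, 11))
  expect_equal(sum(irf$amplitudes) * 10, 1)
})

test_that("t0 is recovered from a reference-dye decay", {
  irf <- irf_gaussian(0, 120)
  tau_ref <- 4080
  for (t0_true in c(0, 300)) {
    sch <- gate_scheme(t0 = t0_true)
    y <- model_gate_signal(50, tau_ref, 1, irf, sch, background = 2)
    sch0 <- gate_scheme(t0 = 0)
    est <- estimate_t0_from_reference(y, tau_ref, sch0, irf, background = 2)
    expect_lt(abs(est$t0 - t0_true), 1)
    expect_false(est$flagged)
  }
})

test_that("a wrong reference lifetime inflates the misfit and flags", {
  irf <- irf_gaussian(0, 120)
  sch <- gate_scheme(t0 = 300)
  y <- model_gate_signal(50, 4080, 1, irf, sch, background = 2)
  sch0 <- gate_scheme(t0 = 0)
  good <- estimate_t0_from_reference(y, 4080, sch0, irf, background = 2)
  bad <- estimate_t0_from_reference(y, 2 * 4080, sch0, irf, background = 2)
  expect_gt(bad$chisq_red, 100 * max(good$chisq_red, 1e-12))
  expect_true(bad$flagged)
})

test_that("background estimation is exact for deterministic blanks", {
  blank <- array(10, c(20, 20, 5))
  expect_equal(estimate_background(blank), rep(10, 5))
  ramp <- c(1.2, 1.1, 1.0, 0.9, 0.8)
  blank2 <- array(rep(ramp, each = 400), c(20, 20, 5))
  expect_equal(estimate_background(blank2), ramp)
})

test_that("background estimation from Poisson blanks is within sampling error", {
  set.seed(42)
  b <- 9
  n <- 1e4
  blank <- array(rpois(n * 5, b), c(100, 100, 5))
  est <- estimate_background(blank)
  # median ~ mean for Poisson at this rate; allow 3 standard errors
  expect_true(all(abs(est - b) <= 3 * sqrt(b / n) + 0.5))
})
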