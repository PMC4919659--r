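# Binding equilibrium algebra, intensity calibration and K_D estimation.

test_that("equilibrium solver returns the admissible quadratic root", {
  # closed-form oracle: smaller root of the mass-action quadratic
  quad_root <- function(d, a, kd) {
    s <- d + a + kd
    (s - sqrt(s^2 - 4 * d * a)) / 2
  }
  expect_equal(solve_binding_equilibrium(1000, 1000, 500),
               quad_root(1000, 1000, 500))
  expect_equal(solve_binding_equilibrium(1000, 1000, 500), 500)
  expect_equal(solve_binding_equilibrium(1, 1, 0), 1)   # stoichiometric
  expect_equal(solve_binding_equilibrium(0, 123, 7), 0)
  expect_equal(solve_binding_equilibrium(100, 200, Inf), 0)
  expect_error(solve_binding_equilibrium(-1, 1, 1), "non-negative")
})

test_that("generated equilibria satisfy mass action to 1e-10", {
  set.seed(5)
  d <- 10^runif(200, 1, 4); a <- 10^runif(200, 1, 4)
  kd <- 10^runif(200, 0, 4)
  da <- solve_binding_equilibrium(d, a, kd)
  expect_true(all(da >= 0 & da <= pmin(d, a)))
  resid <- abs((d - da) * (a - da) / da - kd) / kd
  expect_lt(max(resid), 1e-10)
})

test_that("bound-fraction identity beta*D_total = gamma*A_total is exact", {
  set.seed(6)
  d <- 10^runif(50, 1, 4); a <- 10^runif(50, 1, 4)
  da <- solve_binding_equilibrium(d, a, 300)
  beta <- da / d
  g <- compute_gamma(beta, d, a)
  expect_equal(beta * d, g$gamma * a, tolerance = 1e-12)
  expect_true(all(g$gamma <= 1 + 1e-12))
})

test_that("compute_gamma handles boundaries and bad input", {
  expect_equal(compute_gamma(0.5, 2, 1)$gamma, 1)
  expect_false(compute_gamma(0.5, 2, 1)$out_of_range)
  expect_equal(compute_gamma(0, 5, 1)$gamma, 0)
  expect_equal(compute_gamma(0.25, 1, 2)$gamma, 0.125)
  expect_true(compute_gamma(0.9, 10, 1)$out_of_range)
  expect_error(compute_gamma(0.5, 1, 0), "> 0")
  expect_error(compute_gamma(1.2, 1, 1), "beta")
})

test_that("intensity calibration fits an exact line exactly", {
  cal <- suppressWarnings(
    fit_intensity_calibration(c(0, 1, 2) * 1000, c(0, 100, 200)))
  expect_equal(cal$slope, 0.1)
  expect_equal(cal$intercept, 0)
  expect_equal(cal$r_squared, 1)
})

test_that("noisy calibration slope is within its sampling error", {
  set.seed(9)
  x <- seq(100, 5000, length.out = 10)
  reps <- replicate(200, {
    y <- 0.1 * x + rnorm(10, 0, 1)
    fit <- lm(y ~ x)
    c(coef(fit)[2], summary(fit)$coefficients[2, 2])
  })
  # the package estimator agrees with lm and lies within 3 SE of truth
  y <- 0.1 * x + rnorm(10, 0, 1)
  cal <- fit_intensity_calibration(x, y)
  expect_equal(cal$slope, unname(coef(lm(y ~ x))[2]))
  expect_lt(abs(cal$slope - 0.1), 3 * median(reps[2, ]))
})

test_that("degenerate calibration inputs error or degrade gracefully", {
  expect_error(fit_intensity_calibration(c(1, 2), c(1, 2)), ">= 3")
  expect_error(fit_intensity_calibration(rep(5, 4), 1:4), "variance")
  cal <- suppressWarnings(
    fit_intensity_calibration(c(100, 100, 5000), c(9, 11, 500)))
  expect_lt(cal$r_squared, 1)
})

test_that("K_D estimate inverts the binding equilibrium exactly", {
  set.seed(10)
  cfg_gain_d <- 0.02; cfg_gain_a <- 0.3
  cal_d <- suppressWarnings(fit_intensity_calibration(
    c(100, 1000, 5000), c(100, 1000, 5000) * cfg_gain_d))
  cal_a <- suppressWarnings(fit_intensity_calibration(
    c(100, 1000, 5000), c(100, 1000, 5000) * cfg_gain_a))
  d <- 10^runif(100, 1.7, 3.7); a <- 10^runif(100, 1.7, 3.7)
  kd_true <- 500
  da <- solve_binding_equilibrium(d, a, kd_true)
  beta <- da / d
  est <- estimate_kd_per_cell(beta, cfg_gain_d * d, cfg_gain_a * a,
                              cal_d, cal_a)
  expect_true(all(est$flag == "ok"))
  expect_lt(max(abs(est$kd - kd_true) / kd_true), 1e-10)
})

test_that("K_D flags follow the validity taxonomy", {
  cal <- suppressWarnings(fit_intensity_calibration(
    c(100, 1000, 5000), c(100, 1000, 5000)))
  # stoichiometric limit: beta -> 1 with equal totals drives kd -> 0
  est <- estimate_kd_per_cell(c(0.999, 0.5, 0, 1),
                              i_d0 = c(1000, 2000, 1000, 1000),
                              i_a = c(1000, 800, 1000, 1000), cal, cal)
  expect_lt(est$kd[1], 2)
  expect_equal(est$flag[2], "negative_free_acceptor")
  expect_equal(est$flag[3], "beta_degenerate")
  expect_equal(est$flag[4], "beta_degenerate")
  expect_true(all(is.na(est$kd[2:4])))
})

test_that("K_D is invariant under joint intensity/gain rescaling", {
  mk_cal <- function(g) suppressWarnings(fit_intensity_calibration(
    c(100, 1000, 5000), c(100, 1000, 5000) * g))
  for (s in c(0.1, 4)) {
    a <- estimate_kd_per_cell(0.4, 10, 300, mk_cal(0.01), mk_cal(0.3))
    b <- estimate_kd_per_cell(0.4, 10 * s, 300, mk_cal(0.01 * s), mk_cal(0.3))
    expect_equal(a$kd, b$kd, tolerance = 1e-10)
  }
})

test_that("K_D decreases monotonically in beta below a_total/d_total", {
  cal <- suppressWarnings(fit_intensity_calibration(
    c(100, 1000, 5000), c(100, 1000, 5000)))
  betas <- seq(0.05, 0.75, by = 0.05)  # a/d = 0.8
  est <- estimate_kd_per_cell(betas, 1000, 800, cal, cal)
  expect_true(all(est$flag == "ok"))
  expect_true(all(diff(est$kd) < 0))
})

test_that("aggregation reports medians over ok cells and withholds small groups", {
  tab <- data.frame(kd = c(rep(500, 12), NA, 1e5, rep(450, 3)),
                    flag = c(rep("ok", 12), "beta_degenerate",
                             "gamma_out_of_range", rep("ok", 3)))
  cond <- c(rep("A", 14), rep("B", 3))
  agg <- suppressWarnings(aggregate_kd(tab, cond))
  a <- agg[agg$condition == "A", ]
  expect_equal(a$kd_median, 500)
  expect_equal(a$kd_iqr, 0)
  expect_equal(a$n_ok, 12)
  expect_equal(a$n_beta_degenerate, 1)
  b <- agg[agg$condition == "B", ]
  expect_true(is.na(b$kd_median))  # below min_cells, withheld
  expect_warning(aggregate_kd(tab, cond), "withheld")
})
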