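# Monoexponential and global biexponential (variable projection) fitting.

test_that("two noiseless gates give the closed-form lifetime", {
  sch <- gate_scheme(delays = c(0, 1000), width = 1000)
  fit <- fit_monoexponential(c(1000, 1000 * exp(-1)), sch)
  expect_equal(fit$tau, 1000, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("noiseless 5-gate decays with a measured IRF recover tau", {
  sch <- gate_scheme()
  tgrid <- seq(-100, 500, by = 10)
  irf <- irf_measured(tgrid, dnorm(tgrid, 150, 60))
  for (tau in c(1500, 2200, 3000)) {
    y <- model_gate_signal(4, tau, 1, irf, sch, background = 1)
    fit <- fit_monoexponential(y, sch, irf, background = 1)
    expect_lt(abs(fit$tau - tau) / tau, 1e-3)
    expect_equal(fit$i0, 4, tolerance = 1e-4)
  }
})

test_that("a mixture decay yields an effective lifetime between components", {
  sch <- gate_scheme()
  y <- mixture_decay(0.5, 1e4, tau_da = 1200, tau_d = 2400, scheme = sch)
  fit <- fit_monoexponential(y, sch)
  expect_gt(fit$tau, 1200)
  expect_lt(fit$tau, 2400)
})

test_that("monoexponential tau is invariant to count rescaling", {
  sch <- gate_scheme()
  y <- model_gate_signal(2, 1800, 1, irf_delta(), sch)
  ref <- fit_monoexponential(y, sch)$tau
  for (c in c(0.5, 3, 50)) {
    expect_equal(fit_monoexponential(c * y, sch)$tau, ref,
                 tolerance = 1e-7)
  }
})

test_that("decays at or below background are flagged not fittable", {
  sch <- gate_scheme()
  fit <- fit_monoexponential(rep(2, 5), sch, background = 2)
  expect_false(fit$fittable)
  expect_true(is.na(fit$tau))
})

test_that("pixel-wise lifetime maps fit only masked pixels", {
  sch <- gate_scheme()
  y1 <- model_gate_signal(10, 2000, 1, irf_delta(), sch)
  y2 <- model_gate_signal(10, 1200, 1, irf_delta(), sch)
  stack <- array(0, c(2, 2, 5))
  stack[1, 1, ] <- y1; stack[2, 2, ] <- y2
  mask <- matrix(c(1, 0, 0, 1), 2, 2)
  map <- fit_flim_image(stack, sch, mask = mask)
  expect_equal(map[1, 1], 2000, tolerance = 1e-4)
  expect_equal(map[2, 2], 1200, tolerance = 1e-4)
  expect_true(is.na(map[1, 2]) && is.na(map[2, 1]))
})

test_that("global fit with no quenched component flags unidentifiability", {
  sch <- gate_scheme()
  Y <- t(sapply(c(5, 10, 20), function(a)
    model_gate_signal(a, 2400, 1, irf_delta(), sch)))
  gf <- fit_global_biexponential(Y, tau_d = 2400, scheme = sch)
  expect_true(all(gf$beta < 0.02))
  expect_true("tau_da_unidentifiable" %in% gf$flags)
})

test_that("variable projection matches an exhaustive-grid full fit", {
  # 3 cells x 5 gates, noiseless; oracle: dense tau_DA grid with
  # per-cell unconstrained lm amplitudes, then full 7-parameter
  # nonlinear least squares from the grid optimum.
  sch <- gate_scheme()
  irf <- irf_delta()
  tau_d <- 2400; tau_da_true <- 1300
  betas <- c(0.25, 0.5, 0.75)
  amps <- c(8, 15, 30)
  Y <- t(mapply(function(b, a)
    model_gate_signal(a, c(tau_da_true, tau_d), c(b, 1 - b), irf, sch),
    betas, amps))
  W <- 1 / pmax(Y, 1)

  md <- model_gate_signal(1, tau_d, 1, irf, sch)
  rss_full <- function(par) {
    mq <- model_gate_signal(1, par[1], 1, irf, sch)
    sum(vapply(1:3, function(i) {
      r <- Y[i, ] - par[2 * i] * md - par[2 * i + 1] * mq
      sum(W[i, ] * r^2)
    }, numeric(1)))
  }
  grid <- seq(900, 1800, by = 0.5)
  grid_rss <- vapply(grid, function(tq) {
    mq <- model_gate_signal(1, tq, 1, irf, sch)
    sum(vapply(1:3, function(i) {
      co <- lm.fit(cbind(md, mq) * sqrt(W[i, ]), Y[i, ] * sqrt(W[i, ]))
      sum(co$residuals^2)
    }, numeric(1)))
  }, numeric(1))
  tq0 <- grid[which.min(grid_rss)]
  mq0 <- model_gate_signal(1, tq0, 1, irf, sch)
  a0 <- unlist(lapply(1:3, function(i) {
    co <- coef(lm.fit(cbind(md, mq0) * sqrt(W[i, ]), Y[i, ] * sqrt(W[i, ])))
    co
  }))
  oracle <- optim(c(tq0, a0), rss_full, method = "L-BFGS-B",
                  lower = c(200, rep(0, 6)), upper = c(2300, rep(Inf, 6)),
                  control = list(factr = 10, maxit = 500))
  oracle_tau <- oracle$par[1]
  oracle_beta <- oracle$par[c(3, 5, 7)] /
    (oracle$par[c(2, 4, 6)] + oracle$par[c(3, 5, 7)])

  gf <- fit_global_biexponential(Y, tau_d = tau_d, scheme = sch, irf = irf)
  expect_lt(abs(gf$tau_da - oracle_tau), 1)
  expect_lt(max(abs(gf$beta - oracle_beta)), 1e-6)
})

test_that("pooled residual at the optimum beats any fixed grid tau", {
  sch <- gate_scheme()
  set.seed(7)
  Y <- t(sapply(c(0.3, 0.6), function(b)
    rpois(5, mixture_decay(b, 2e4, scheme = sch))))
  gf <- fit_global_biexponential(Y, tau_d = 2400, scheme = sch)
  md <- model_gate_signal(1, 2400, 1, irf_delta(), sch)
  mq_opt <- model_gate_signal(1, gf$tau_da, 1, irf_delta(), sch)
  fitm <- (gf$i0 * (1 - gf$beta)) %o% md + (gf$i0 * gf$beta) %o% mq_opt
  W <- 1 / pmax(fitm, 1)  # weights fixed at the fitted model
  rss_at <- function(tq) {
    mq <- model_gate_signal(1, tq, 1, irf_delta(), sch)
    sum(vapply(seq_len(nrow(Y)), function(i) {
      co <- lm.fit(cbind(md, mq) * sqrt(W[i, ]), Y[i, ] * sqrt(W[i, ]))
      sum(co$residuals^2)
    }, numeric(1)))
  }
  opt_rss <- rss_at(gf$tau_da)
  for (tq in seq(400, 2200, by = 200))
    expect_gte(rss_at(tq), opt_rss - 1e-8 * abs(opt_rss))
})

test_that("global fit recovers tau_DA and per-cell beta from mixtures", {
  sch <- gate_scheme()
  set.seed(11)
  betas <- rep(c(0.2, 0.5, 0.8), each = 3)
  Y <- t(sapply(betas, function(b) rpois(5, mixture_decay(b, 5e4,
                                                          scheme = sch))))
  gf <- fit_global_biexponential(Y, tau_d = 2400, scheme = sch)
  expect_lt(abs(gf$tau_da - 1300), 50)
  expect_lt(max(abs(gf$beta - betas)), 0.05)
})

test_that("mean lifetime summaries follow the amplitude-weighted rule", {
  sch <- gate_scheme()
  y <- model_gate_signal(5, 2000, 1, irf_delta(), sch)
  mono <- fit_monoexponential(y, sch)
  expect_equal(summarize_lifetime(mono), mono$tau)

  gf <- list(tau_d = 2400, tau_da = 1200, beta = c(0, 1, 0.5))
  class(gf) <- "flim_globalfit"
  expect_equal(summarize_lifetime(gf), c(2400, 1200, 1800))

  # monotone decrease with beta at fixed lifetimes
  gf$beta <- seq(0, 1, by = 0.1)
  expect_true(all(diff(summarize_lifetime(gf)) < 0))
})
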