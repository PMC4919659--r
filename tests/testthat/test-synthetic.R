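# Synthetic plate generator: ground truth, determinism, noise model.

test_that("cell fields are reproducible and respect geometry", {
  cfg <- quick_config()
  f1 <- generate_cell_field(cfg, seed = 21)
  f2 <- generate_cell_field(cfg, seed = 21)
  expect_identical(f1, f2)
  f3 <- generate_cell_field(cfg, seed = 22)
  expect_false(identical(f1$labels, f3$labels))

  expect_equal(sort(unique(as.vector(f1$labels))), 0:cfg$cells_per_fov)
  # disks must not touch: pairwise centre distance >= r_i + r_j + gap
  tr <- f1$truth
  for (i in seq_len(nrow(tr) - 1)) {
    dd <- sqrt((tr$x[-(1:i)] - tr$x[i])^2 + (tr$y[-(1:i)] - tr$y[i])^2)
    expect_true(all(dd >= tr$r[-(1:i)] + tr$r[i] + cfg$min_gap - 1e-9))
  }
})

test_that("zero-cell configuration yields empty field and truth", {
  cfg <- quick_config(cells_per_fov = 0)
  f <- generate_cell_field(cfg, seed = 1)
  expect_true(all(f$labels == 0))
  expect_equal(nrow(f$truth), 0)
  ren <- render_time_gated_stack(f, config = cfg, seed = 2)
  expect_equal(dim(ren$donor), c(96, 96, 5))
})

test_that("infeasible packing raises a descriptive error", {
  cfg <- plate_config(image_size = c(32, 32), cells_per_fov = 30,
                      radius_range = c(6, 6))
  expect_error(generate_cell_field(cfg, seed = 1), "could not place")
})

test_that("generated truth satisfies the equilibrium and fraction identities", {
  cfg <- plate_config(image_size = c(256, 256), cells_per_fov = 50,
                      radius_range = c(4, 6), kd_true = 500)
  tr <- generate_cell_field(cfg, seed = 31)$truth
  expect_true(all(tr$da >= 0 & tr$da <= pmin(tr$d_total, tr$a_total)))
  resid <- abs((tr$d_total - tr$da) * (tr$a_total - tr$da) / tr$da - 500) / 500
  expect_lt(max(resid), 1e-10)
  expect_equal(tr$beta_true * tr$d_total, tr$gamma_true * tr$a_total,
               tolerance = 1e-12)
  # log-spread expression: acceptor/donor ratio varies >= 10-fold
  ratio <- tr$a_total / tr$d_total
  expect_gte(max(ratio) / min(ratio), 10)
})

test_that("noiseless rendering equals the analytic gate expectations", {
  cfg <- quick_config(noise = "none")
  f <- generate_cell_field(cfg, seed = 41)
  ren <- render_time_gated_stack(f, config = cfg)
  expect_identical(ren$donor, ren$expected_donor)
  tr <- f$truth
  for (i in c(1, nrow(tr))) {
    px <- f$labels == i
    expected <- model_gate_signal(
      cfg$c_d * tr$d_total[i], c(cfg$tau_da, cfg$tau_d),
      c(tr$beta_true[i], 1 - tr$beta_true[i]), cfg$irf, cfg$scheme,
      background = cfg$background_donor)
    for (g in 1:5)
      expect_equal(unique(ren$donor[, , g][px]), expected[g],
                   tolerance = 1e-12)
    expect_equal(unique(ren$acceptor[px]),
                 cfg$c_a * tr$a_total[i] + cfg$background_acceptor,
                 tolerance = 1e-12)
  }
})

test_that("expected donor counts scale linearly with the donor gain", {
  cfg1 <- quick_config(noise = "none")
  cfg2 <- quick_config(noise = "none", c_d = 3 * cfg1$c_d)
  f <- generate_cell_field(cfg1, seed = 51)
  r1 <- render_time_gated_stack(f, config = cfg1)
  r2 <- render_time_gated_stack(f, config = cfg2)
  bg <- array(rep(cfg1$background_donor, each = 96 * 96), c(96, 96, 5))
  expect_equal(r2$expected_donor - bg, 3 * (r1$expected_donor - bg),
               tolerance = 1e-12)
})

test_that("Poisson-noised stacks converge to the analytic expectation", {
  cfg <- plate_config(image_size = c(24, 24), cells_per_fov = 1,
                      radius_range = c(7, 7))
  f <- generate_cell_field(cfg, seed = 61)
  set.seed(62)
  n_rep <- 1000
  sums <- matrix(0, n_rep, 5)
  ren0 <- render_time_gated_stack(f, config = cfg)
  for (r in seq_len(n_rep)) {
    ren <- render_time_gated_stack(f, config = cfg)
    sums[r, ] <- apply(ren$donor, 3, sum)
  }
  expected <- apply(ren0$expected_donor, 3, sum)
  se <- sqrt(expected / n_rep)  # SE of the mean of Poisson totals
  expect_true(all(abs(colMeans(sums) - expected) <= 3 * se))
})

test_that("fixed-fraction conditions carry the requested beta", {
  cfg <- quick_config(beta_fixed = 0.4)
  tr <- generate_cell_field(cfg, seed = 71)$truth
  expect_true(all(tr$beta_true == 0.4))
  cfg0 <- quick_config(beta_fixed = 0, acceptor_present = FALSE)
  tr0 <- generate_cell_field(cfg0, seed = 72)$truth
  expect_true(all(tr0$beta_true == 0 & tr0$a_total == 0))
})

test_that("plates simulate deterministically from one master seed", {
  cfg <- quick_config()
  lay <- plate_layout("X", kd = 500, n_fov = 1)
  p1 <- simulate_plate(lay, cfg, seed = 81)
  p2 <- simulate_plate(lay, cfg, seed = 81)
  expect_identical(p1, p2)
  p3 <- simulate_plate(lay, cfg, seed = 82)
  expect_false(identical(p1$fovs[[1]]$donor, p3$fovs[[1]]$donor))
})
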