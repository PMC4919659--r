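#' Configuration of a synthetic FLIM-FRET plate
#'
#' Collects every parameter of the synthetic-data generator: plate/FOV
#' geometry, the per-cell expression model, the donor decay model, the
#' gated-detection model and noise. Defaults describe a realistic
#' co-transfection FRET screen: cells expressing donor- and
#' acceptor-labelled partners from separate plasmids (hence independently
#' log-uniform expression over \[50, 5000\] nM, not a 1:1 stoichiometry),
#' an unquenched donor lifetime of 2400 ps (EGFP-like) quenched to 1300 ps
#' in complex, five 1-ns gates under 60 MHz excitation, and pure Poisson
#' photon noise over a time-varying background.
#'
#' Binding per cell follows the bimolecular equilibrium with `kd_true`
#' unless `beta_fixed` is given, in which case every cell has that
#' interacting donor fraction (used e.g. for non-interacting negative
#' conditions with `beta_fixed = 0`).
#'
#' @param image_size FOV size in pixels `c(rows, cols)`.
#' @param cells_per_fov Number of cells per field of view.
#' @param radius_range Cell disk radius range (px).
#' @param min_gap Minimum edge-to-edge separation between cells (px); the
#'   default keeps neighbouring cells separable after segmentation
#'   smoothing.
#' @param expression_range Log-uniform range (nM) for `d_total` and
#'   `a_total`, drawn independently per cell.
#' @param tau_d,tau_da Unquenched / FRET-quenched donor lifetimes (ps),
#'   `tau_da < tau_d`.
#' @param scheme [gate_scheme()] of the simulated acquisition.
#' @param irf Instrument response used in the forward model.
#' @param c_d,c_a Detection gains: donor counts px^-1 ps^-1 per nM
#'   (amplitude gain) and acceptor counts px^-1 per nM.
#' @param background_donor Per-gate donor background counts (vector of
#'   gate length or scalar); default a mild ramp across gates emulating a
#'   time-varying background.
#' @param background_acceptor Acceptor background counts per pixel.
#' @param noise `"poisson"` or `"none"`.
#' @param excess_variance Multiplicative excess-variance factor for the
#'   intensifier (1 = pure Poisson; > 1 uses a negative-binomial draw with
#'   that variance inflation).
#' @param kd_true True dissociation constant (nM) for equilibrium binding.
#' @param beta_fixed Optional fixed interacting fraction overriding the
#'   equilibrium model.
#' @param acceptor_present Whether cells carry the acceptor construct
#'   (FALSE for donor-only conditions: `a_total = 0`).
#' @param ref_lifetime Reference-dye lifetime (ps) for t0 calibration
#'   wells (rhodamine 6G-like default).
#' @return A `plate_config` list.
#' @export
plate_config <- function(image_size = c(192, 192), cells_per_fov = 20,
                         radius_range = c(6, 10), min_gap = 8,
                         expression_range = c(50, 5000),
                         tau_d = 2400, tau_da = 1300,
                         scheme = gate_scheme(), irf = irf_delta(),
                         c_d = 0.01, c_a = 0.2,
                         background_donor = NULL, background_acceptor = 1,
                         noise = c("poisson", "none"),
                         excess_variance = 1,
                         kd_true = 500, beta_fixed = NULL,
                         acceptor_present = TRUE,
                         ref_lifetime = 4080) {
  noise <- match.arg(noise)
  stopifnot(all(image_size >= 16), cells_per_fov >= 0,
            radius_range[1] > 0, diff(radius_range) >= 0, min_gap >= 0,
            expression_range[1] > 0, diff(expression_range) > 0,
            tau_d > 0, tau_da > 0, c_d > 0, c_a > 0,
            excess_variance >= 1, kd_true >= 0, ref_lifetime > 0)
  if (tau_da >= tau_d) stop("tau_da must be smaller than tau_d")
  if (!is.null(beta_fixed) && (beta_fixed < 0 || beta_fixed > 1))
    stop("beta_fixed must lie in [0, 1]")
  if (is.null(background_donor))
    background_donor <- seq(1.2, 0.8, length.out = n_gates(scheme))
  background_donor <- rep_len(background_donor, n_gates(scheme))
  structure(list(
    image_size = image_size, cells_per_fov = cells_per_fov,
    radius_range = radius_range, min_gap = min_gap,
    expression_range = expression_range,
    tau_d = tau_d, tau_da = tau_da, scheme = scheme, irf = irf,
    c_d = c_d, c_a = c_a,
    background_donor = background_donor,
    background_acceptor = background_acceptor,
    noise = noise, excess_variance = excess_variance,
    kd_true = kd_true, beta_fixed = beta_fixed,
    acceptor_present = acceptor_present,
    ref_lifetime = ref_lifetime), class = "plate_config")
}

#' @export
print.plate_config <- function(x, ...) {
  cat(sprintf(
    "<plate_config> %dx%d px, %d cells/FOV, tau_D %.0f / tau_DA %.0f ps, %s noise\n",
    x$image_size[1], x$image_size[2], x$cells_per_fov, x$tau_d, x$tau_da,
    x$noise))
  invisible(x)
}

#' Generate one labelled cell field with binding ground truth
#'
#' Places non-overlapping disk cells in an empty field, draws per-cell
#' donor and acceptor expression independently from the configured
#' log-uniform distribution, and solves the bimolecular equilibrium (or
#' applies the fixed fraction) for each cell, yielding the full binding
#' ground truth.
#'
#' @param config [plate_config()].
#' @param seed Integer seed; runs with the same seed are bit-identical.
#' @return List with `labels` (integer matrix, 0 = background) and `truth`
#'   (data.frame: cell, x, y, r, d_total, a_total, da, beta_true,
#'   gamma_true).
#' @export
generate_cell_field <- function(config, seed) {
  stopifnot(inherits(config, "plate_config"))
  set.seed(seed)
  H <- config$image_size[1]; W <- config$image_size[2]
  n <- config$cells_per_fov
  labels <- matrix(0L, H, W)
  if (n == 0) {
    truth <- data.frame(cell = integer(0), x = numeric(0), y = numeric(0),
                        r = numeric(0), d_total = numeric(0),
                        a_total = numeric(0), da = numeric(0),
                        beta_true = numeric(0), gamma_true = numeric(0))
    return(list(labels = labels, truth = truth))
  }
  margin <- 5  # keeps threshold halos clear of the border-exclusion rule
  xs <- ys <- rs <- numeric(n)
  tries <- 0; max_tries <- 2000 * n
  placed <- 0
  while (placed < n) {
    tries <- tries + 1
    if (tries > max_tries)
      stop(sprintf(
        "could not place %d cells of radius %.0f-%.0f in a %dx%d field (gap %.0f)",
        n, config$radius_range[1], config$radius_range[2], H, W,
        config$min_gap))
    r <- stats::runif(1, config$radius_range[1], config$radius_range[2])
    x <- stats::runif(1, r + margin, W - r - margin)
    y <- stats::runif(1, r + margin, H - r - margin)
    if (placed > 0) {
      dd <- sqrt((xs[1:placed] - x)^2 + (ys[1:placed] - y)^2)
      if (any(dd < rs[1:placed] + r + config$min_gap)) next
    }
    placed <- placed + 1
    xs[placed] <- x; ys[placed] <- y; rs[placed] <- r
  }
  # rasterise disks (pixel centre inside radius)
  col_ix <- matrix(rep(seq_len(W), each = H), H, W)
  row_ix <- matrix(rep(seq_len(H), W), H, W)
  for (i in seq_len(n)) {
    inside <- (col_ix - xs[i])^2 + (row_ix - ys[i])^2 <= rs[i]^2
    labels[inside] <- i
  }
  lu <- log(config$expression_range)
  d_total <- exp(stats::runif(n, lu[1], lu[2]))
  a_total <- if (config$acceptor_present)
    exp(stats::runif(n, lu[1], lu[2])) else rep(0, n)
  if (!is.null(config$beta_fixed)) {
    beta_true <- rep(config$beta_fixed, n)
    da <- beta_true * d_total
    if (config$acceptor_present && any(da > a_total))
      a_total <- pmax(a_total, da)  # fixed-fraction mode: ensure feasibility
  } else {
    da <- solve_binding_equilibrium(d_total, a_total, config$kd_true)
    beta_true <- ifelse(d_total > 0, da / d_total, 0)
  }
  gamma_true <- ifelse(a_total > 0, da / a_total, 0)
  truth <- data.frame(cell = seq_len(n), x = xs, y = ys, r = rs,
                      d_total = d_total, a_total = a_total, da = da,
                      beta_true = beta_true, gamma_true = gamma_true)
  list(labels = labels, truth = truth)
}

# draw counts from the configured noise model around expectation `lambda`
draw_counts <- function(lambda, config) {
  if (config$noise == "none") return(lambda)
  n <- length(lambda)
  if (config$excess_variance > 1) {
    f <- config$excess_variance
    size <- lambda / (f - 1)
    out <- numeric(n)
    pos <- lambda > 0
    out[pos] <- stats::rnbinom(sum(pos), size = size[pos], mu = lambda[pos])
    out
  } else {
    stats::rpois(n, lambda)
  }
}

#' Render gated donor and acceptor images for a cell field
#'
#' Forward-simulates the gated acquisition of one field of view: every cell
#' emits a two-component donor decay with fractions
#' `(beta_true, 1 - beta_true)` and lifetimes `(tau_da, tau_d)`, amplitude
#' `c_d * d_total` per pixel, convolved with the configured IRF, integrated
#' over the gates, over the per-gate time-varying background; the acceptor
#' channel is a single intensity image with expectation
#' `c_a * a_total + background`. Counts are then drawn from the configured
#' noise model (Poisson by default; `noise = "none"` returns the analytic
#' expectations exactly).
#'
#' @param field Output of [generate_cell_field()] (`labels` + `truth`), or
#'   a label matrix with `truth` supplied separately.
#' @param truth Ground-truth table (defaults to `field$truth`).
#' @param config [plate_config()].
#' @param seed Optional seed for the noise draws.
#' @return List: `donor` (`H x W x G` counts), `acceptor` (`H x W`),
#'   `expected_donor`, `expected_acceptor`, `scheme`.
#' @export
render_time_gated_stack <- function(field, truth = NULL, config,
                                    seed = NULL) {
  stopifnot(inherits(config, "plate_config"))
  labels <- if (is.list(field)) field$labels else field
  if (is.null(truth)) truth <- field$truth
  if (!is.null(seed)) set.seed(seed)
  H <- nrow(labels); W <- ncol(labels); G <- n_gates(config$scheme)
  n <- nrow(truth)
  sig <- matrix(0, n, G)
  for (i in seq_len(n)) {
    sig[i, ] <- model_gate_signal(
      amplitude = config$c_d * truth$d_total[i],
      lifetimes = c(config$tau_da, config$tau_d),
      fractions = c(truth$beta_true[i], 1 - truth$beta_true[i]),
      irf = config$irf, scheme = config$scheme)
  }
  lut <- rbind(0, sig)                    # row 1 = background label 0
  expected_donor <- array(0, c(H, W, G))
  for (g in seq_len(G))
    expected_donor[, , g] <- config$background_donor[g] +
      matrix(lut[labels + 1L, g], H, W)
  a_lut <- c(0, config$c_a * truth$a_total)
  expected_acceptor <- config$background_acceptor +
    matrix(a_lut[labels + 1L], H, W)
  donor <- array(draw_counts(expected_donor, config), c(H, W, G))
  acceptor <- matrix(draw_counts(expected_acceptor, config), H, W)
  list(donor = donor, acceptor = acceptor,
       expected_donor = expected_donor,
       expected_acceptor = expected_acceptor,
       scheme = config$scheme)
}

#' Default layout for a synthetic screening plate
#'
#' One row per well: `well`, `condition`, `role` (one of `donor_only`,
#' `negative_control`, `test`, `blank`, `reference_dye`), `n_fov`, and the
#' binding truth for the condition (`kd` in nM, or `beta` for
#' fixed-fraction conditions; NA fields fall back to the plate config).
#'
#' @param conditions Character vector of test condition names.
#' @param kd Per-condition true dissociation constants (nM); `Inf` or a
#'   `beta` of 0 makes a non-interacting condition.
#' @param beta Optional per-condition fixed interacting fractions
#'   (overrides `kd` where not NA).
#' @param n_fov Fields of view per well.
#' @param blank Include a blank (buffer-only) well.
#' @param reference Include a reference-dye well for t0 calibration.
#' @return data.frame plate layout.
#' @export
plate_layout <- function(conditions, kd = NULL, beta = NULL, n_fov = 2,
                         blank = TRUE, reference = FALSE) {
  k <- length(conditions)
  kd <- if (is.null(kd)) rep(NA_real_, k) else rep_len(kd, k)
  beta <- if (is.null(beta)) rep(NA_real_, k) else rep_len(beta, k)
  rows <- list()
  for (i in seq_len(k)) {
    rows[[length(rows) + 1]] <- data.frame(
      condition = conditions[i], role = "donor_only",
      kd = NA_real_, beta = NA_real_, n_fov = n_fov)
    rows[[length(rows) + 1]] <- data.frame(
      condition = conditions[i], role = "negative_control",
      kd = NA_real_, beta = 0, n_fov = n_fov)
    rows[[length(rows) + 1]] <- data.frame(
      condition = conditions[i], role = "test",
      kd = kd[i], beta = beta[i], n_fov = n_fov)
  }
  if (blank)
    rows[[length(rows) + 1]] <- data.frame(
      condition = "blank", role = "blank", kd = NA_real_, beta = NA_real_,
      n_fov = 1)
  if (reference)
    rows[[length(rows) + 1]] <- data.frame(
      condition = "reference", role = "reference_dye", kd = NA_real_,
      beta = NA_real_, n_fov = 1)
  out <- do.call(rbind, rows)
  out$well <- sprintf("%s%02d", LETTERS[(seq_len(nrow(out)) - 1) %/% 12 + 1],
                      (seq_len(nrow(out)) - 1) %% 12 + 1)
  out[, c("well", "condition", "role", "kd", "beta", "n_fov")]
}

# Per-condition config derived from a layout row.
condition_config <- function(config, row) {
  cfg <- config
  if (row$role == "donor_only") {
    cfg$acceptor_present <- FALSE
    cfg$beta_fixed <- 0
  } else if (row$role %in% c("test", "negative_control")) {
    if (!is.na(row$beta)) {
      cfg$beta_fixed <- row$beta
    } else if (!is.na(row$kd)) {
      cfg$beta_fixed <- NULL
      cfg$kd_true <- row$kd
    }
  }
  cfg
}

#' Simulate a full synthetic screening plate
#'
#' Generates every field of view of a plate described by a layout
#' (see [plate_layout()]): cell fields with binding ground truth for
#' cell-bearing wells, empty background stacks for blank wells, and a
#' uniform reference-dye decay for t0-calibration wells. One master seed
#' drives deterministic per-FOV seeds so individual FOVs are independently
#' reproducible.
#'
#' @param layout Plate layout data.frame.
#' @param config [plate_config()].
#' @param seed Master integer seed.
#' @param keep_expectation Keep the analytic expectation images on each FOV
#'   (memory-heavier; useful for validation).
#' @return A `flim_plate`: list with `layout`, `config`, `seed`, and
#'   `fovs` — each FOV holding `well`, `condition`, `role`, `fov`,
#'   `labels`, `truth`, `donor`, `acceptor`.
#' @export
simulate_plate <- function(layout, config = plate_config(), seed = 1,
                           keep_expectation = FALSE) {
  stopifnot(is.data.frame(layout),
            all(c("well", "condition", "role", "n_fov") %in% names(layout)))
  set.seed(seed)
  total_fov <- sum(layout$n_fov)
  fov_seeds <- sample.int(.Machine$integer.max - 1L, 2 * total_fov)
  fovs <- list()
  s <- 0
  for (i in seq_len(nrow(layout))) {
    row <- layout[i, ]
    cfg <- condition_config(config, row)
    for (f in seq_len(row$n_fov)) {
      s <- s + 1
      if (row$role == "blank") {
        cfg0 <- cfg; cfg0$cells_per_fov <- 0
        field <- generate_cell_field(cfg0, fov_seeds[2 * s - 1])
        ren <- render_time_gated_stack(field, config = cfg0,
                                       seed = fov_seeds[2 * s])
      } else if (row$role == "reference_dye") {
        field <- list(labels = matrix(0L, cfg$image_size[1],
                                      cfg$image_size[2]),
                      truth = NULL)
        ren <- render_reference_fov(cfg, seed = fov_seeds[2 * s])
      } else {
        field <- generate_cell_field(cfg, fov_seeds[2 * s - 1])
        ren <- render_time_gated_stack(field, config = cfg,
                                       seed = fov_seeds[2 * s])
      }
      rec <- list(well = row$well, condition = row$condition,
                  role = row$role, fov = f, labels = field$labels,
                  truth = field$truth, donor = ren$donor,
                  acceptor = ren$acceptor)
      if (keep_expectation) {
        rec$expected_donor <- ren$expected_donor
        rec$expected_acceptor <- ren$expected_acceptor
      }
      fovs[[s]] <- rec
    }
  }
  structure(list(layout = layout, config = config, seed = seed,
                 fovs = fovs), class = "flim_plate")
}

# Uniform reference-dye FOV: monoexponential decay at the reference
# lifetime, used to calibrate t0.
render_reference_fov <- function(config, seed = NULL, ref_conc = 1000) {
  if (!is.null(seed)) set.seed(seed)
  H <- config$image_size[1]; W <- config$image_size[2]
  G <- n_gates(config$scheme)
  sig <- model_gate_signal(config$c_d * ref_conc, config$ref_lifetime, 1,
                           config$irf, config$scheme,
                           background = config$background_donor)
  expected_donor <- array(rep(sig, each = H * W), c(H, W, G))
  donor <- array(draw_counts(expected_donor, config), c(H, W, G))
  acceptor <- matrix(draw_counts(
    rep(config$background_acceptor, H * W), config), H, W)
  list(donor = donor, acceptor = acceptor,
       expected_donor = expected_donor,
       expected_acceptor = matrix(config$background_acceptor, H, W),
       scheme = config$scheme)
}

#' @export
print.flim_plate <- function(x, ...) {
  cat(sprintf("<flim_plate> %d wells, %d FOV, seed %d\n",
              nrow(x$layout), length(x$fovs), x$seed))
  print(x$config)
  invisible(x)
}

#' Simulate a fluorophore calibration series
#'
#' Forward-simulates calibration solutions of known concentration under
#' the plate's detection model and extracts the same intensity statistic
#' the cellular pipeline uses: for the donor, a monoexponential fit of the
#' gated solution decay yields the initial (t = 0) intensity per pixel;
#' for the acceptor, the background-subtracted mean intensity per pixel.
#'
#' @param config [plate_config()].
#' @param channel `"donor"` or `"acceptor"`.
#' @param concentrations Calibration concentrations (nM).
#' @param fov_size Pixels per calibration field (kept small; solutions are
#'   uniform).
#' @param seed Integer seed.
#' @param solution_lifetime Donor-solution lifetime (ps); purified
#'   fluorophore in buffer, default the unquenched donor lifetime.
#' @return data.frame `concentration`, `intensity` ready for
#'   [fit_intensity_calibration()].
#' @export
simulate_calibration_series <- function(config, channel = c("donor", "acceptor"),
                                        concentrations = c(100, 250, 500,
                                                           1000, 2500, 5000),
                                        fov_size = 32, seed = 1,
                                        solution_lifetime = NULL) {
  channel <- match.arg(channel)
  set.seed(seed)
  if (is.null(solution_lifetime)) solution_lifetime <- config$tau_d
  npx <- fov_size^2
  ints <- vapply(concentrations, function(conc) {
    if (channel == "donor") {
      sig <- model_gate_signal(config$c_d * conc, solution_lifetime, 1,
                               config$irf, config$scheme,
                               background = config$background_donor)
      counts <- matrix(draw_counts(rep(sig, each = npx), config), npx,
                       n_gates(config$scheme))
      decay <- colMeans(counts)
      fit <- fit_monoexponential(decay, config$scheme, config$irf,
                                 config$background_donor,
                                 tau_range = c(200, 4 * solution_lifetime))
      fit$i0
    } else {
      lam <- rep(config$c_a * conc + config$background_acceptor, npx)
      mean(draw_counts(lam, config)) - config$background_acceptor
    }
  }, numeric(1))
  data.frame(concentration = concentrations, intensity = ints)
}
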