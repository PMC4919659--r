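#' Repetition-rate wrap factor
#'
#' At high pulse repetition rates the decay does not fully complete between
#' excitation pulses, so every gate also collects residual fluorescence from
#' all preceding pulses. Summing the geometric series of pulse contributions
#' gives the wrap factor `1 / (1 - exp(-period / tau))` multiplying the
#' single-pulse signal. At 60 MHz with tau ~ 2.5 ns this is a ~0.1% effect,
#' but it keeps the forward model exact.
#'
#' @param tau Fluorescence lifetime (ps).
#' @param period Repetition period (ps).
#' @return The dimensionless wrap factor (>= 1).
#' @export
wrap_factor <- function(tau, period) {
  stopifnot(tau > 0, period > 0)
  1 / (1 - exp(-period / tau))
}

# Integral of the periodised unit-amplitude exponential exp(-t/tau)
# (period P, wrapped) over a gate [phase, phase + width]. `phase` is taken
# modulo P and may be any real number; width must be <= P. Vectorised over
# `phase`.
gate_integral_wrapped <- function(phase, width, tau, period) {
  W <- 1 / (1 - exp(-period / tau))
  phase <- phase %% period
  end <- phase + width
  inside <- tau * W * (exp(-phase / tau) - exp(-pmin(end, period) / tau))
  over <- pmax(end - period, 0)
  # portion of the gate that spills past the period boundary restarts at t=0
  spill <- tau * W * (1 - exp(-over / tau))
  inside + spill
}

#' Expected counts per time gate for a multi-exponential decay
#'
#' Forward model shared by the simulator and the fitters: a mixture of
#' exponential decays with given lifetimes and fractions, convolved with the
#' instrument response, integrated over each rectangular gate window, with
#' repetition-rate wrap-around and an additive per-gate background.
#'
#' For a delta IRF, zero background and a single lifetime `tau`, the count
#' in a gate opening at delay `t` after the time origin, of width `w`, is
#' `amplitude * tau * exp(-t/tau) * (1 - exp(-w/tau)) * W` with
#' `W = 1/(1 - exp(-P/tau))` the wrap factor for repetition period `P`.
#' Multi-component signals are the fraction-weighted sum; finite IRFs enter
#' by discrete convolution: each IRF sample shifts the decay origin, and the
#' gate integral of the shifted, periodised decay is evaluated in closed
#' form, so no additional time-discretisation error is incurred in the gate
#' integration itself.
#'
#' @param amplitude Decay amplitude: instantaneous intensity at t = 0
#'   (counts per ps of gate time).
#' @param lifetimes Numeric vector of component lifetimes (ps), all > 0.
#' @param fractions Amplitude fractions of the components; non-negative,
#'   summing to 1 (tolerance 1e-9).
#' @param irf A [irf_delta()], [irf_gaussian()] or [irf_measured()] object.
#' @param scheme A [gate_scheme()].
#' @param background Per-gate additive background counts (scalar or vector
#'   of length `length(scheme$delays)`).
#' @param oversample Sampling step (ps) for parametric IRFs.
#' @return Numeric vector of expected counts, one per gate.
#' @examples
#' sch <- gate_scheme()
#' model_gate_signal(1, 2500, 1, irf_delta(), sch)
#' @export
model_gate_signal <- function(amplitude, lifetimes, fractions = 1,
                              irf = irf_delta(), scheme,
                              background = 0, oversample = 25) {
  stopifnot(inherits(scheme, "gate_scheme"), inherits(irf, "flim_irf"))
  if (any(lifetimes <= 0)) stop("lifetimes must be > 0")
  if (length(fractions) != length(lifetimes))
    stop("fractions and lifetimes must have equal length")
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1 (tolerance 1e-9)")
  nb <- length(background)
  if (!nb %in% c(1L, n_gates(scheme)))
    stop("background must be scalar or one value per gate")

  basis <- gate_basis(lifetimes, irf, scheme, oversample)
  drop(basis %*% (amplitude * fractions)) + background
}

# Gate-count basis matrix: n_gates x n_lifetimes, unit amplitude per
# component. Shared by model_gate_signal and the fitters (the fitters solve
# linear amplitudes against these columns).
gate_basis <- function(lifetimes, irf, scheme, oversample = 25) {
  samp <- irf_samples(irf, oversample)
  # phase of each (gate, IRF-sample) pair relative to decay start
  ph <- outer(scheme$delays - scheme$t0, samp$t, "-")
  out <- matrix(0, length(scheme$delays), length(lifetimes))
  for (i in seq_along(lifetimes)) {
    g <- gate_integral_wrapped(ph, scheme$width, lifetimes[i],
                               scheme$rep_period)
    out[, i] <- drop(g %*% samp$w)
  }
  out
}

# Parabolic (Newton) polish of a smooth 1-D minimum found by Brent search;
# pushes the solution below Brent's ~sqrt(eps)*|x| precision floor, which
# matters for the noiseless exactness of the fitting chain.
polish_min <- function(f, x0, lower, upper, steps = c(1e-2, 1e-4)) {
  x <- x0
  for (h in steps) {
    xs <- c(x - h, x, x + h)
    if (xs[1] <= lower || xs[3] >= upper) next
    ys <- vapply(xs, f, numeric(1))
    d1 <- (ys[3] - ys[1]) / (2 * h)
    d2 <- (ys[3] - 2 * ys[2] + ys[1]) / h^2
    if (!is.finite(d2) || d2 <= 0) next
    cand <- x - d1 / d2
    if (cand > lower && cand < upper && abs(cand - x) < 10 * h &&
        f(cand) <= ys[2])
      x <- cand
  }
  x
}

#' Estimate the decay time origin from a reference-dye acquisition
#'
#' The start of the decay profile t0 drifts between plates; it is
#' calibrated by fitting gated data from a reference dye of known lifetime
#' (classically rhodamine 6G) with the lifetime fixed, leaving only t0 and
#' the amplitude free. The amplitude is profiled out linearly, and t0
#' minimises the weighted least-squares misfit over a bounded search.
#'
#' A poor fit (reduced chi-square above `flag_chisq`, e.g. because the
#' assumed reference lifetime is wrong) flags the result rather than
#' failing, so plate QC can inspect it.
#'
#' @param gate_counts Per-gate reference counts (vector), e.g. summed over a
#'   reference-well region of interest.
#' @param known_lifetime Reference-dye lifetime (ps); a required input, not
#'   a built-in constant.
#' @param scheme [gate_scheme()] of the acquisition (its `t0` is ignored).
#' @param irf Instrument response.
#' @param background Per-gate background counts.
#' @param t0_range Search interval for t0 (ps).
#' @param flag_chisq Reduced chi-square above which the result is flagged.
#' @return List with `t0` (ps), `chisq_red`, `amplitude`, and logical
#'   `flagged`.
#' @export
estimate_t0_from_reference <- function(gate_counts, known_lifetime, scheme,
                                       irf = irf_delta(), background = 0,
                                       t0_range = c(-2000, 2000),
                                       flag_chisq = 5) {
  stopifnot(known_lifetime > 0, length(t0_range) == 2, diff(t0_range) > 0)
  y <- gate_counts - background
  w <- 1 / pmax(gate_counts, 1)
  rss_at <- function(t0) {
    sch <- scheme
    sch$t0 <- t0
    m <- gate_basis(known_lifetime, irf, sch)[, 1]
    a <- max(sum(w * y * m) / sum(w * m^2), 0)
    sum(w * (y - a * m)^2)
  }
  # coarse grid to bracket the global minimum, then Brent refinement
  grid <- seq(t0_range[1], t0_range[2], length.out = 81)
  rg <- vapply(grid, rss_at, numeric(1))
  i <- which.min(rg)
  lo <- grid[max(i - 1, 1)]
  hi <- grid[min(i + 1, length(grid))]
  opt <- stats::optimize(rss_at, c(lo, hi), tol = 1e-6)
  sch <- scheme
  sch$t0 <- opt$minimum
  m <- gate_basis(known_lifetime, irf, sch)[, 1]
  a <- max(sum(w * y * m) / sum(w * m^2), 0)
  dof <- max(length(y) - 2, 1)
  chisq <- opt$objective / dof
  list(t0 = opt$minimum, chisq_red = chisq, amplitude = a,
       flagged = chisq > flag_chisq)
}

#' Per-gate background from a blank-well acquisition
#'
#' The detection background varies with gate delay (excitation leakage,
#' intensifier afterglow), so it is measured per gate from a well containing
#' only buffer. The estimate is the median over pixels of each gate image, a
#' robust central value that equals the mean for the noiseless case and is
#' insensitive to stray bright pixels.
#'
#' @param blank_stack Blank acquisition: an `H x W x G` array or an
#'   `n_pixels x G` matrix of counts, gates in acquisition order.
#' @return Numeric vector of per-gate background counts.
#' @export
estimate_background <- function(blank_stack) {
  if (is.array(blank_stack) && length(dim(blank_stack)) == 3) {
    d <- dim(blank_stack)
    blank_stack <- matrix(blank_stack, d[1] * d[2], d[3])
  }
  stopifnot(is.matrix(blank_stack))
  apply(blank_stack, 2, stats::median)
}
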