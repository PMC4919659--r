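#' Time-gate acquisition scheme
#'
#' Describes the temporal sampling of a gated-intensifier FLIM acquisition:
#' the gate opening delays relative to the excitation trigger, the (common)
#' gate width, the laser repetition period, the plate-level time origin of
#' the decay `t0`, and the per-gate integration time.
#'
#' All times are in picoseconds. The default scheme samples a decay with
#' five 1-ns gates at 1-ns spacing under 60 MHz pulsed excitation
#' (repetition period 1e6/60 ps), matching a typical wide-field time-gated
#' FRET acquisition.
#'
#' @param delays Numeric vector of gate opening delays (ps), strictly
#'   increasing, measured from the excitation trigger.
#' @param width Gate width (ps), shared by all gates.
#' @param rep_period Laser repetition period (ps). Gate windows may wrap
#'   around the period; incomplete decay from earlier pulses is modelled.
#' @param t0 Time origin of the decay (ps) on the trigger axis, normally
#'   calibrated per plate with a reference dye (see
#'   [estimate_t0_from_reference()]).
#' @param integration_time Per-gate integration time (s); recorded for
#'   bookkeeping, counts are always per integration.
#' @return An object of class `gate_scheme`.
#' @examples
#' gate_scheme()
#' gate_scheme(delays = c(0, 500, 1500, 3000, 6000), width = 1000)
#' @export
gate_scheme <- function(delays = seq(0, 4000, by = 1000), width = 1000,
                        rep_period = 1e6 / 60, t0 = 0,
                        integration_time = 1) {
  stopifnot(is.numeric(delays), length(delays) >= 1, !anyNA(delays))
  if (length(delays) > 1 && any(diff(delays) <= 0))
    stop("gate delays must be strictly increasing")
  if (width <= 0) stop("gate width must be > 0")
  if (rep_period <= 0) stop("repetition period must be > 0")
  if (width > rep_period)
    stop("gate width cannot exceed the repetition period")
  if (integration_time <= 0) stop("integration_time must be > 0")
  structure(
    list(delays = as.numeric(delays), width = as.numeric(width),
         rep_period = as.numeric(rep_period), t0 = as.numeric(t0),
         integration_time = as.numeric(integration_time)),
    class = "gate_scheme")
}

#' @export
print.gate_scheme <- function(x, ...) {
  cat(sprintf(
    "<gate_scheme> %d gates, width %.0f ps, delays %s ps\n  rep period %.1f ps, t0 %.1f ps\n",
    length(x$delays), x$width,
    paste(format(x$delays, trim = TRUE), collapse = ", "),
    x$rep_period, x$t0))
  invisible(x)
}

n_gates <- function(scheme) length(scheme$delays)

#' Instrument response functions
#'
#' The instrument response function (IRF) of a gated detector is convolved
#' with the exponential decay model before gate integration. Three forms are
#' supported: an ideal delta IRF (`irf_delta()`), a parametric Gaussian
#' (`irf_gaussian()`) specified by its centre and full width at half
#' maximum, and a measured IRF (`irf_measured()`) given on a uniform time
#' grid, e.g. from a scattering-sample acquisition. Measured amplitudes must
#' be non-negative; they are normalised to unit area on construction.
#'
#' @param center Gaussian centre (ps).
#' @param fwhm Gaussian full width at half maximum (ps), > 0.
#' @param times Uniform time grid (ps) of a measured IRF.
#' @param amplitudes Non-negative amplitudes on `times`.
#' @return An object of class `flim_irf`.
#' @examples
#' irf_delta()
#' irf_gaussian(fwhm = 150)
#' @export
irf_delta <- function() {
  structure(list(type = "delta"), class = "flim_irf")
}

#' @rdname irf_delta
#' @export
irf_gaussian <- function(center = 0, fwhm = 100) {
  if (fwhm <= 0) stop("IRF FWHM must be > 0")
  structure(list(type = "gaussian", center = center, fwhm = fwhm),
            class = "flim_irf")
}

#' @rdname irf_delta
#' @export
irf_measured <- function(times, amplitudes) {
  stopifnot(length(times) == length(amplitudes), length(times) >= 2)
  dt <- diff(times)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt))
    stop("measured IRF requires a uniform, increasing time grid")
  if (any(amplitudes < 0)) stop("measured IRF amplitudes must be >= 0")
  s <- sum(amplitudes)
  if (s <= 0) stop("measured IRF must have positive total amplitude")
  amplitudes <- amplitudes / (s * dt[1])  # unit area
  structure(list(type = "measured", times = as.numeric(times),
                 amplitudes = amplitudes),
            class = "flim_irf")
}

#' @export
print.flim_irf <- function(x, ...) {
  switch(x$type,
    delta = cat("<flim_irf> delta\n"),
    gaussian = cat(sprintf("<flim_irf> Gaussian, centre %.1f ps, FWHM %.1f ps\n",
                           x$center, x$fwhm)),
    measured = cat(sprintf("<flim_irf> measured, %d samples, span %.0f ps\n",
                           length(x$times), diff(range(x$times)))))
  invisible(x)
}

# Discretise an IRF into sample times and probability weights (sum 1).
# `step` is the oversampling step (ps) used for parametric IRFs.
irf_samples <- function(irf, step = 25) {
  switch(irf$type,
    delta = list(t = 0, w = 1),
    gaussian = {
      sigma <- irf$fwhm / (2 * sqrt(2 * log(2)))
      h <- min(step, irf$fwhm / 8)
      t <- seq(irf$center - 5 * sigma, irf$center + 5 * sigma, by = h)
      w <- stats::dnorm(t, irf$center, sigma)
      list(t = t, w = w / sum(w))
    },
    measured = {
      w <- irf$amplitudes
      list(t = irf$times, w = w / sum(w))
    },
    stop("unknown IRF type"))
}
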