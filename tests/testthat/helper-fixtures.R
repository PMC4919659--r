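# Shared fixtures for the test suite. Everything is generated in code.

default_scheme <- function() gate_scheme()

# Small, fast plate configuration for pipeline tests.
quick_config <- function(...) {
  args <- list(image_size = c(96, 96), cells_per_fov = 6,
               radius_range = c(5, 7))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(plate_config, args)
}

# Exact calibration curves matching the configured detection gains.
exact_calibrations <- function(config) {
  conc <- c(100, 500, 1000, 5000)
  list(
    donor = suppressWarnings(fit_intensity_calibration(
      conc, conc * config$c_d, "EGFP")),
    acceptor = suppressWarnings(fit_intensity_calibration(
      conc, conc * config$c_a, "mCherry")))
}

# Noiseless gated decay for a beta-mixture cell, scaled to a total photon
# count, as consumed by the fitters.
mixture_decay <- function(beta, total_photons = 1e4, tau_da = 1300,
                          tau_d = 2400, scheme = gate_scheme(),
                          irf = irf_delta(), background = 0) {
  y <- model_gate_signal(1, c(tau_da, tau_d), c(beta, 1 - beta), irf,
                         scheme, background = 0)
  y * total_photons / sum(y) + background
}
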