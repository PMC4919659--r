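#' Bimolecular binding equilibrium
#'
#' For the reaction D + A <-> DA with dissociation constant
#' `K_D = [D][A]/[DA]`, mass conservation gives the quadratic
#' `da^2 - (d_total + a_total + kd) * da + d_total * a_total = 0` for the
#' complex concentration. The physically admissible root is the smaller
#' one (the larger root exceeds both totals). It is evaluated in the
#' numerically stable form `2 d a / (S + sqrt(S^2 - 4 d a))` with
#' `S = d_total + a_total + kd`, which avoids cancellation when
#' `kd << totals`.
#'
#' All concentrations are in the same unit (nM by package convention).
#' Vectorised over all arguments. `kd = 0` gives the stoichiometric limit
#' `min(d_total, a_total)`; `kd = Inf` gives 0.
#'
#' @param d_total Total donor-labelled partner concentration (>= 0).
#' @param a_total Total acceptor-labelled partner concentration (>= 0).
#' @param kd Dissociation constant (>= 0, may be Inf).
#' @return Complex concentration `da`, same unit as the inputs.
#' @examples
#' solve_binding_equilibrium(1000, 1000, 500)  # 500
#' @export
solve_binding_equilibrium <- function(d_total, a_total, kd) {
  if (any(d_total < 0) || any(a_total < 0) || any(kd < 0))
    stop("concentrations and kd must be non-negative")
  n <- max(length(d_total), length(a_total), length(kd))
  d <- rep_len(d_total, n); a <- rep_len(a_total, n); k <- rep_len(kd, n)
  S <- d + a + k
  da <- ifelse(d * a == 0, 0,
               ifelse(is.infinite(k), 0,
                      2 * d * a / (S + sqrt(S^2 - 4 * d * a))))
  da
}

#' Bound acceptor fraction from the bound donor fraction
#'
#' The complex concentration can be written either as `beta * d_total`
#' (bound fraction of the donor) or `gamma * a_total` (bound fraction of
#' the acceptor), so `gamma = beta * d_total / a_total`. A `gamma` above 1
#' is physically impossible and indicates inconsistent measurements; it is
#' flagged rather than silently truncated.
#'
#' @param beta Bound donor fraction in \[0, 1\].
#' @param d_total,a_total Total concentrations (nM); `a_total` must be > 0.
#' @return List with `gamma` and logical `out_of_range` (gamma > 1).
#' @export
compute_gamma <- function(beta, d_total, a_total) {
  if (any(a_total <= 0)) stop("a_total must be > 0")
  if (any(beta < 0 | beta > 1)) stop("beta must lie in [0, 1]")
  g <- beta * d_total / a_total
  list(gamma = g, out_of_range = g > 1)
}

#' Fluorophore intensity-vs-concentration calibration
#'
#' Detected mean intensity per pixel is linearly proportional to
#' fluorophore concentration under fixed acquisition settings; the
#' proportionality constant converts cellular intensities into
#' concentrations for dissociation-constant estimation. Fits an ordinary
#' least-squares line through calibration solutions of known concentration.
#'
#' The calibration only transfers to data acquired with the same optical
#' configuration (objective, sectioning, gain); `settings_tag` records this
#' and [estimate_kd_per_cell()] refuses mismatched tags.
#'
#' @param concentrations Known concentrations (nM), >= 3 points.
#' @param intensities Measured mean intensities per pixel (counts).
#' @param fluorophore Label, e.g. `"EGFP"`.
#' @param settings_tag Acquisition-settings identifier.
#' @return A `calibration_curve`: `slope` (counts px^-1 per nM),
#'   `intercept`, `r_squared`, `fluorophore`, `settings_tag`.
#' @examples
#' fit_intensity_calibration(c(0, 100, 200), c(0, 10, 20))
#' @export
fit_intensity_calibration <- function(concentrations, intensities,
                                      fluorophore = "fluorophore",
                                      settings_tag = "default") {
  if (length(concentrations) < 3 || length(intensities) != length(concentrations))
    stop("need >= 3 matched calibration points")
  if (stats::var(concentrations) == 0)
    stop("calibration concentrations have zero variance")
  pos <- concentrations[concentrations > 0]
  if (length(pos) >= 2 && max(pos) / min(pos) < 10)
    warning("calibration concentrations span less than one decade")
  fit <- stats::lm(intensities ~ concentrations)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (slope <= 0) stop("calibration slope must be positive")
  r2 <- summary(fit)$r.squared
  mid <- (max(intensities) + min(intensities)) / 2
  if (mid > 0 && abs(intercept) > 0.1 * mid)
    warning("calibration intercept exceeds 10% of mid-range signal")
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 fluorophore = fluorophore, settings_tag = settings_tag),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> %s [%s]: slope %.4g counts/px/nM, intercept %.4g, R^2 %.5f\n",
    x$fluorophore, x$settings_tag, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

# intensity -> concentration through a calibration curve
calibrate_concentration <- function(intensity, cal) {
  (intensity - cal$intercept) / cal$slope
}

#' Per-cell dissociation constant from FRET fraction and intensities
#'
#' Combines the globally fitted interacting donor fraction `beta` with
#' calibrated donor and acceptor intensities to estimate the per-cell
#' dissociation constant. Total concentrations are
#' `d_total = I_D / c_D` and `a_total = I_A / c_A`; eliminating the free
#' concentrations via the bound fractions gives
#' `K_D = (1 - beta) * (a_total - beta * d_total) / beta`, which is
#' algebraically identical to free-D * free-A / complex.
#'
#' The donor intensity must be the fitted initial intensity of the decay
#' (t = 0 amplitude per pixel), not the total detected intensity: FRETing
#' and non-FRETing donors have different brightness because their lifetimes
#' (hence quantum yields) differ, and only the t = 0 amplitude is
#' proportional to donor concentration.
#'
#' Validity flags: `beta_degenerate` (beta at 0 or 1, K_D undefined),
#' `negative_free_acceptor` (`a_total <= beta * d_total`, inconsistent
#' measurement), `gamma_out_of_range` (bound acceptor fraction above
#' `1 + gamma_tol`). Flagged cells carry `NA` and are excluded from
#' aggregates.
#'
#' @param beta Interacting donor fraction(s) from the global fit.
#' @param i_d0 Fitted donor initial intensity per pixel (counts).
#' @param i_a Background-subtracted mean acceptor intensity per pixel.
#' @param cal_d,cal_a [fit_intensity_calibration()] curves for donor and
#'   acceptor; their `settings_tag`s must match.
#' @param gamma_tol Tolerance on the gamma <= 1 physical bound.
#' @return data.frame with `kd` (nM), `flag`, `d_total`, `a_total`,
#'   `gamma`.
#' @export
estimate_kd_per_cell <- function(beta, i_d0, i_a, cal_d, cal_a,
                                 gamma_tol = 0.05) {
  stopifnot(inherits(cal_d, "calibration_curve"),
            inherits(cal_a, "calibration_curve"))
  if (!identical(cal_d$settings_tag, cal_a$settings_tag))
    stop("donor and acceptor calibrations have different settings tags")
  n <- max(length(beta), length(i_d0), length(i_a))
  beta <- rep_len(beta, n); i_d0 <- rep_len(i_d0, n); i_a <- rep_len(i_a, n)
  d_total <- calibrate_concentration(i_d0, cal_d)
  a_total <- calibrate_concentration(i_a, cal_a)
  gamma <- ifelse(a_total > 0, beta * d_total / a_total, NA_real_)
  free_a <- a_total - beta * d_total
  flag <- rep("ok", n)
  flag[!is.na(gamma) & gamma > 1 + gamma_tol] <- "gamma_out_of_range"
  flag[free_a <= 0] <- "negative_free_acceptor"
  flag[is.na(beta) | beta <= 0 | beta >= 1] <- "beta_degenerate"
  kd <- ifelse(flag == "ok", (1 - beta) * free_a / beta, NA_real_)
  data.frame(kd = kd, flag = flag, d_total = d_total, a_total = a_total,
             gamma = gamma, beta = beta)
}

#' Aggregate per-cell dissociation constants by condition
#'
#' Per-cell K_D distributions are heavy-tailed (cells with small beta or
#' near-stoichiometric acceptor produce large, noisy estimates), so the
#' aggregate statistic is the median with the interquartile range; the mean
#' is also reported for comparison. Only cells flagged `ok` enter the
#' aggregate, and conditions with fewer than `min_cells` such cells are
#' withheld (NA) with a warning.
#'
#' @param kd_table data.frame from [estimate_kd_per_cell()], plus a
#'   grouping column.
#' @param condition Character/factor vector of condition labels (recycled).
#' @param min_cells Minimum number of `ok` cells per condition.
#' @return data.frame with one row per condition: `n_ok`, `n_excluded`,
#'   `kd_median`, `kd_iqr`, `kd_q1`, `kd_q3`, `kd_mean`, plus per-flag
#'   exclusion counts.
#' @export
aggregate_kd <- function(kd_table, condition, min_cells = 10) {
  stopifnot(is.data.frame(kd_table), "kd" %in% names(kd_table))
  condition <- rep_len(as.character(condition), nrow(kd_table))
  out <- lapply(split(seq_len(nrow(kd_table)), condition), function(ix) {
    sub <- kd_table[ix, ]
    ok <- sub$flag == "ok" & !is.na(sub$kd)
    kd <- sub$kd[ok]
    withheld <- sum(ok) < min_cells
    if (withheld)
      warning(sprintf("condition with %d ok cells (< %d): aggregate withheld",
                      sum(ok), min_cells), call. = FALSE)
    q <- if (withheld) rep(NA_real_, 3) else
      stats::quantile(kd, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(
      n_ok = sum(ok), n_excluded = sum(!ok),
      n_beta_degenerate = sum(sub$flag == "beta_degenerate"),
      n_negative_free_acceptor = sum(sub$flag == "negative_free_acceptor"),
      n_gamma_out_of_range = sum(sub$flag == "gamma_out_of_range"),
      kd_median = q[2], kd_iqr = q[3] - q[1], kd_q1 = q[1], kd_q3 = q[3],
      kd_mean = if (withheld) NA_real_ else mean(kd))
  })
  res <- do.call(rbind, out)
  res <- cbind(condition = names(out), res)
  rownames(res) <- NULL
  res
}
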