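#' Analyse a (synthetic or loaded) FLIM-FRET plate
#'
#' Runs the per-plate analysis chain: per-gate background estimation from
#' blank wells (falling back to the configured background if no blank is
#' present), optional t0 calibration from reference-dye wells, cell
#' segmentation on donor and acceptor intensity, per-cell decay/intensity
#' aggregation, a monoexponential fit per cell (the screening lifetime
#' readout), estimation of the unquenched donor lifetime per condition
#' from its donor-only wells, and a global double-exponential fit per
#' co-transfected condition/role group yielding the shared quenched
#' lifetime and per-cell interacting fractions.
#'
#' @param plate A `flim_plate` from [simulate_plate()] or [read_plate()].
#' @param k,min_area,smooth_radius,erode_radius,min_interior Segmentation
#'   and photometry parameters (see [segment_cells()],
#'   [aggregate_per_cell()]).
#' @param calibrate_t0 Re-estimate t0 from reference-dye wells when
#'   present.
#' @param global_roles Roles that receive a global biexponential fit.
#' @param tau_range Mono-fit search bounds (ps).
#' @return A `flim_screen`: list with `records` (per-cell table: well,
#'   condition, role, fov, cell, n_pixels, tau_mono, i_d0 — fitted t = 0
#'   donor amplitude per pixel —, i_a, ratio, beta, chisq, flags),
#'   `tau_d` (per-condition unquenched lifetimes), `global_fits`,
#'   `background`, `t0`.
#' @export
analyze_plate <- function(plate, k = 5, min_area = 100, smooth_radius = 2,
                          erode_radius = 2, min_interior = 20,
                          calibrate_t0 = FALSE,
                          global_roles = c("test", "negative_control"),
                          tau_range = c(200, 6000)) {
  stopifnot(inherits(plate, "flim_plate"))
  cfg <- plate$config
  scheme <- cfg$scheme
  irf <- cfg$irf

  # --- background from blank wells (median per gate over pixels)
  blanks <- Filter(function(f) f$role == "blank", plate$fovs)
  if (length(blanks)) {
    bg_donor <- rowMeans(vapply(blanks, function(b)
      estimate_background(b$donor), numeric(n_gates(scheme))))
    bg_acceptor <- mean(vapply(blanks, function(b)
      stats::median(b$acceptor), numeric(1)))
  } else {
    bg_donor <- cfg$background_donor
    bg_acceptor <- cfg$background_acceptor
  }

  # --- optional t0 calibration from reference-dye wells
  t0 <- scheme$t0
  refs <- Filter(function(f) f$role == "reference_dye", plate$fovs)
  if (calibrate_t0 && length(refs)) {
    decay <- Reduce(`+`, lapply(refs, function(r)
      apply(r$donor, 3, sum)))
    npx <- sum(vapply(refs, function(r) prod(dim(r$donor)[1:2]),
                      numeric(1)))
    est <- estimate_t0_from_reference(decay, cfg$ref_lifetime, scheme, irf,
                                      background = bg_donor * npx)
    if (!est$flagged) {
      t0 <- est$t0
      scheme$t0 <- t0
    }
  }

  # --- segmentation + aggregation + mono fit per FOV
  rec_list <- list()
  decay_store <- list()
  for (i in seq_along(plate$fovs)) {
    fv <- plate$fovs[[i]]
    if (!fv$role %in% c("donor_only", "negative_control", "test")) next
    need_acceptor <- fv$role != "donor_only"
    labels <- segment_cells(fv$donor[, , 1],
                            if (need_acceptor) fv$acceptor else NULL,
                            require_acceptor = need_acceptor,
                            k = k, min_area = min_area,
                            smooth_radius = smooth_radius)
    agg <- aggregate_per_cell(fv$donor, fv$acceptor, labels,
                              background_donor = bg_donor,
                              background_acceptor = bg_acceptor,
                              erode_radius = erode_radius,
                              min_interior = min_interior)
    nc <- nrow(agg$cells)
    if (nc == 0) next
    tau_mono <- chisq <- rep(NA_real_, nc)
    for (j in seq_len(nc)) {
      f <- fit_monoexponential(agg$decays[j, ], scheme, irf,
                               agg$background_per_cell[j, ],
                               tau_range = tau_range)
      tau_mono[j] <- if (f$fittable) f$tau else NA_real_
      chisq[j] <- f$chisq_red
    }
    rec <- data.frame(
      well = fv$well, condition = fv$condition, role = fv$role,
      fov = fv$fov, cell = agg$cells$cell,
      n_pixels = agg$cells$n_pixels, n_interior = agg$cells$n_interior,
      donor_gate1_mean = agg$cells$donor_gate1_mean,
      i_a = agg$cells$acceptor_mean,
      tau_mono = tau_mono, chisq_mono = chisq)
    rec_list[[length(rec_list) + 1]] <- rec
    decay_store[[length(decay_store) + 1]] <-
      list(key = paste(fv$condition, fv$role, sep = "|"),
           decays = agg$decays, background = agg$background_per_cell,
           n_interior = agg$cells$n_interior)
  }
  if (!length(rec_list))
    stop("no cells found on the plate")
  records <- do.call(rbind, rec_list)
  rownames(records) <- NULL

  # --- unquenched donor lifetime per condition from donor-only wells
  tau_d_tab <- stats::aggregate(
    tau_mono ~ condition, data = records[records$role == "donor_only", ],
    FUN = mean)
  names(tau_d_tab)[2] <- "tau_d"

  # --- global biexponential fit per condition/role group
  records$beta <- NA_real_
  records$i_d0 <- NA_real_
  records$flag <- ""
  global_fits <- list()
  keys <- unique(vapply(decay_store, `[[`, character(1), "key"))
  for (key in keys) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    cond <- parts[1]; role <- parts[2]
    if (!role %in% global_roles) next
    tau_d <- tau_d_tab$tau_d[tau_d_tab$condition == cond]
    if (!length(tau_d) || is.na(tau_d)) {
      warning(sprintf("condition '%s': no donor-only baseline; global fit skipped",
                      cond), call. = FALSE)
      next
    }
    grp <- Filter(function(d) d$key == key, decay_store)
    decays <- do.call(rbind, lapply(grp, `[[`, "decays"))
    bg <- do.call(rbind, lapply(grp, `[[`, "background"))
    n_int <- unlist(lapply(grp, `[[`, "n_interior"))
    gf <- fit_global_biexponential(decays, tau_d = tau_d, scheme = scheme,
                                   irf = irf, background = bg)
    global_fits[[key]] <- gf
    sel <- records$condition == cond & records$role == role
    records$beta[sel] <- gf$beta
    records$i_d0[sel] <- gf$i0 / n_int
    records$flag[sel] <- ifelse(gf$clipped, "beta_clipped", "")
  }
  # donor-only cells: i_d0 from the mono fit amplitude is not stored per
  # cell above; their concentration is not used downstream.
  records$ratio <- ifelse(!is.na(records$i_d0) & records$i_d0 > 0,
                          records$i_a / records$i_d0, NA_real_)

  structure(list(records = records, tau_d = tau_d_tab,
                 global_fits = global_fits,
                 background = list(donor = bg_donor,
                                   acceptor = bg_acceptor),
                 t0 = t0, scheme = scheme),
            class = "flim_screen")
}

#' @export
print.flim_screen <- function(x, ...) {
  cat(sprintf("<flim_screen> %d cells, %d conditions, %d global fits\n",
              nrow(x$records), length(unique(x$records$condition)),
              length(x$global_fits)))
  invisible(x)
}

#' Significance threshold for lifetime shifts
#'
#' Control lifetime differences (donor-only mean lifetime minus
#' negative-control mean lifetime, per condition) measure the biological
#' noise floor of the assay. To be conservative, a shift must exceed twice
#' the maximum absolute control difference to be called significant.
#'
#' @param control_deltas Numeric vector of control lifetime differences
#'   (ps), at least one.
#' @return Threshold in ps: `2 * max(abs(control_deltas))`.
#' @examples
#' significance_threshold(c(6, -9, 16))  # 32
#' @export
significance_threshold <- function(control_deltas) {
  if (!length(control_deltas) || all(is.na(control_deltas)))
    stop("need at least one control lifetime difference")
  2 * max(abs(control_deltas), na.rm = TRUE)
}

#' Per-condition mean lifetimes
#'
#' Unweighted mean of the per-cell monoexponential lifetimes for every
#' (condition, role) group, the per-condition screening statistic.
#'
#' @param records Per-cell record table from [analyze_plate()].
#' @return data.frame `condition`, `role`, `mean_tau`, `n_cells`.
#' @export
condition_lifetimes <- function(records) {
  stopifnot(all(c("condition", "role", "tau_mono") %in% names(records)))
  agg <- stats::aggregate(tau_mono ~ condition + role, data = records,
                          FUN = mean, na.rm = TRUE)
  names(agg)[3] <- "mean_tau"
  cnt <- stats::aggregate(tau_mono ~ condition + role, data = records,
                          FUN = function(v) sum(!is.na(v)))
  agg$n_cells <- cnt$tau_mono
  agg[order(agg$condition, agg$role), ]
}

#' Call protein-protein interactions from lifetime shifts
#'
#' A condition is called positive when its mean donor lifetime is reduced,
#' relative to the matching donor-only baseline, by at least the
#' significance threshold (shifts exactly at the threshold are positive).
#' Conditions without a donor-only baseline are left uncalled with a
#' warning.
#'
#' @param summaries Output of [condition_lifetimes()] (or any data.frame
#'   with `condition`, `role`, `mean_tau`).
#' @param threshold Significance threshold (ps), e.g. from
#'   [significance_threshold()].
#' @param test_role Role to call (default `"test"`).
#' @return data.frame `condition`, `baseline_tau`, `test_tau`, `delta_tau`,
#'   `call` (`"positive"`/`"negative"`/NA).
#' @export
call_interactions <- function(summaries, threshold, test_role = "test") {
  base <- summaries[summaries$role == "donor_only", ]
  test <- summaries[summaries$role == test_role, ]
  out <- lapply(seq_len(nrow(test)), function(i) {
    cond <- test$condition[i]
    b <- base$mean_tau[base$condition == cond]
    if (!length(b) || is.na(b)) {
      warning(sprintf("condition '%s' has no donor-only baseline; not scored",
                      cond), call. = FALSE)
      return(data.frame(condition = cond, baseline_tau = NA_real_,
                        test_tau = test$mean_tau[i], delta_tau = NA_real_,
                        call = NA_character_))
    }
    delta <- b - test$mean_tau[i]
    data.frame(condition = cond, baseline_tau = b,
               test_tau = test$mean_tau[i], delta_tau = delta,
               call = if (delta >= threshold) "positive" else "negative")
  })
  res <- do.call(rbind, out)
  res[order(res$condition), ]
}

#' Full screening call on an analysed plate
#'
#' Derives the plate-level significance threshold from the negative-control
#' conditions (donor-only minus negative-control mean lifetime per
#' condition, threshold = twice the maximum absolute difference) and calls
#' every test condition against its donor-only baseline.
#'
#' @param screen A `flim_screen` from [analyze_plate()].
#' @return List: `threshold` (ps), `control_deltas`, `calls` (data.frame),
#'   `summaries`.
#' @export
screen_calls <- function(screen) {
  summaries <- condition_lifetimes(screen$records)
  base <- summaries[summaries$role == "donor_only", ]
  neg <- summaries[summaries$role == "negative_control", ]
  deltas <- vapply(seq_len(nrow(neg)), function(i) {
    b <- base$mean_tau[base$condition == neg$condition[i]]
    if (!length(b)) NA_real_ else b - neg$mean_tau[i]
  }, numeric(1))
  deltas <- deltas[!is.na(deltas)]
  thr <- significance_threshold(deltas)
  calls <- call_interactions(summaries, thr)
  list(threshold = thr, control_deltas = deltas, calls = calls,
       summaries = summaries)
}

#' Write deterministic plate-level output tables
#'
#' Writes the standard reporting artefacts of a screen as CSV: a per-well
#' plate map of mean lifetimes, a per-condition box-plot summary (median,
#' quartiles, 1st/99th percentiles), and the per-cell lifetime-vs-ratio
#' scatter table underlying the 2D plots. Output is sorted and written
#' with fixed formatting so identical inputs give byte-identical files.
#'
#' @param records Per-cell record table from [analyze_plate()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of file paths written.
#' @export
render_outputs <- function(records, dir) {
  stopifnot(nrow(records) > 0)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  # plate map: mean tau per well
  pm <- stats::aggregate(tau_mono ~ well, data = records, FUN = mean,
                         na.rm = TRUE)
  names(pm)[2] <- "mean_tau_ps"
  cnt <- stats::aggregate(tau_mono ~ well, data = records,
                          FUN = function(v) sum(!is.na(v)))
  pm$n_cells <- cnt$tau_mono
  pm <- pm[order(pm$well), ]
  # box-plot summary per condition/role
  groups <- split(records, paste(records$condition, records$role, sep = "|"))
  bs <- do.call(rbind, lapply(sort(names(groups)), function(g) {
    v <- groups[[g]]$tau_mono
    v <- v[!is.na(v)]
    q <- stats::quantile(v, c(0.01, 0.25, 0.5, 0.75, 0.99), names = FALSE)
    parts <- strsplit(g, "|", fixed = TRUE)[[1]]
    data.frame(condition = parts[1], role = parts[2], n = length(v),
               p01 = q[1], q1 = q[2], median = q[3], q3 = q[4], p99 = q[5])
  }))
  # per-cell scatter: tau vs acceptor/donor ratio
  sc <- records[order(records$well, records$fov, records$cell),
                c("well", "condition", "role", "fov", "cell", "tau_mono",
                  "i_a", "i_d0", "ratio", "beta")]
  paths <- c(plate_map = file.path(dir, "plate_map.csv"),
             boxplot = file.path(dir, "boxplot_summary.csv"),
             scatter = file.path(dir, "cell_scatter.csv"))
  utils::write.csv(pm, paths["plate_map"], row.names = FALSE)
  utils::write.csv(bs, paths["boxplot"], row.names = FALSE)
  utils::write.csv(sc, paths["scatter"], row.names = FALSE)
  invisible(paths)
}

#' Per-cell dissociation constants for an analysed screen
#'
#' Applies [estimate_kd_per_cell()] to every globally fitted cell of the
#' given roles, using the fitted t = 0 donor amplitude per pixel and the
#' background-subtracted mean acceptor intensity with the supplied
#' calibration curves.
#'
#' @param screen A `flim_screen`.
#' @param cal_d,cal_a Donor / acceptor [fit_intensity_calibration()]
#'   curves.
#' @param roles Roles to include.
#' @return The screen's record table restricted to those roles, with the
#'   global-fit QC flag moved to `fit_flag` and columns `kd`, `flag` (the
#'   K_D validity flag), `d_total`, `a_total`, `gamma` appended; ready for
#'   [aggregate_kd()].
#' @export
estimate_kd_table <- function(screen, cal_d, cal_a, roles = "test") {
  rec <- screen$records
  rec <- rec[rec$role %in% roles & !is.na(rec$beta), , drop = FALSE]
  if (!nrow(rec)) stop("no globally fitted cells in the requested roles")
  kd <- estimate_kd_per_cell(rec$beta, rec$i_d0, rec$i_a, cal_d, cal_a)
  rec$fit_flag <- rec$flag
  rec$kd <- kd$kd
  rec$flag <- kd$flag
  rec$d_total <- kd$d_total
  rec$a_total <- kd$a_total
  rec$gamma <- kd$gamma
  rec
}
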