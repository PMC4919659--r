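# Counts are stored in 32-bit float TIFF pages scaled into [0, 1];
# the scale factor is recorded in the plate metadata and restored on read.
.tiff_scale <- 65536

write_stack_tiff <- function(stack, path) {
  d <- dim(stack)
  pages <- lapply(seq_len(d[3]), function(g) stack[, , g] / .tiff_scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (g in seq_along(pages)) arr[, , g] <- pages[[g]] * .tiff_scale
  arr
}

#' Write a simulated plate to disk
#'
#' Writes one multi-page TIFF per FOV and channel (donor pages in gate
#' order; acceptor a single page), the per-cell ground-truth table as CSV,
#' and a YAML metadata file recording the layout, gate scheme, seed,
#' detection gains and the TIFF count scale factor.
#'
#' @param plate A `flim_plate` from [simulate_plate()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @seealso [read_plate()]
#' @export
write_plate <- function(plate, dir) {
  stopifnot(inherits(plate, "flim_plate"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  truth_all <- list()
  fov_meta <- list()
  for (i in seq_along(plate$fovs)) {
    fv <- plate$fovs[[i]]
    base <- sprintf("%s_fov%02d", fv$well, fv$fov)
    write_stack_tiff(fv$donor, file.path(dir, paste0(base, "_donor.tif")))
    tiff::writeTIFF(fv$acceptor / .tiff_scale,
                    file.path(dir, paste0(base, "_acceptor.tif")),
                    bits.per.sample = 32L)
    if (!is.null(fv$truth) && nrow(fv$truth)) {
      tr <- cbind(well = fv$well, condition = fv$condition, fov = fv$fov,
                  fv$truth)
      truth_all[[length(truth_all) + 1]] <- tr
    }
    fov_meta[[i]] <- list(well = fv$well, condition = fv$condition,
                          role = fv$role, fov = fv$fov, file = base)
  }
  if (length(truth_all))
    utils::write.csv(do.call(rbind, truth_all),
                     file.path(dir, "ground_truth.csv"), row.names = FALSE)
  cfg <- plate$config
  meta <- list(
    seed = plate$seed,
    count_scale = .tiff_scale,
    gate_scheme = list(delays = cfg$scheme$delays, width = cfg$scheme$width,
                       rep_period = cfg$scheme$rep_period,
                       t0 = cfg$scheme$t0,
                       integration_time = cfg$scheme$integration_time),
    config = list(image_size = cfg$image_size,
                  cells_per_fov = cfg$cells_per_fov,
                  radius_range = cfg$radius_range, min_gap = cfg$min_gap,
                  expression_range = cfg$expression_range,
                  tau_d = cfg$tau_d, tau_da = cfg$tau_da,
                  c_d = cfg$c_d, c_a = cfg$c_a,
                  background_donor = cfg$background_donor,
                  background_acceptor = cfg$background_acceptor,
                  noise = cfg$noise, excess_variance = cfg$excess_variance,
                  kd_true = cfg$kd_true, ref_lifetime = cfg$ref_lifetime),
    fovs = fov_meta)
  yaml::write_yaml(meta, file.path(dir, "plate.yaml"))
  utils::write.csv(plate$layout, file.path(dir, "layout.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a plate written by [write_plate()]
#'
#' @param dir Directory containing `plate.yaml`, `layout.csv` and the
#'   per-FOV TIFFs.
#' @return A `flim_plate`.
#' @export
read_plate <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "plate.yaml"))
  layout <- utils::read.csv(file.path(dir, "layout.csv"))
  gs <- meta$gate_scheme
  scheme <- gate_scheme(delays = unlist(gs$delays), width = gs$width,
                        rep_period = gs$rep_period, t0 = gs$t0,
                        integration_time = gs$integration_time)
  mc <- meta$config
  config <- plate_config(
    image_size = unlist(mc$image_size), cells_per_fov = mc$cells_per_fov,
    radius_range = unlist(mc$radius_range), min_gap = mc$min_gap,
    expression_range = unlist(mc$expression_range),
    tau_d = mc$tau_d, tau_da = mc$tau_da, scheme = scheme,
    c_d = mc$c_d, c_a = mc$c_a,
    background_donor = unlist(mc$background_donor),
    background_acceptor = mc$background_acceptor,
    noise = mc$noise, excess_variance = mc$excess_variance,
    kd_true = mc$kd_true, ref_lifetime = mc$ref_lifetime)
  scale <- meta$count_scale
  truth_path <- file.path(dir, "ground_truth.csv")
  truth_all <- if (file.exists(truth_path)) utils::read.csv(truth_path)
               else NULL
  fovs <- lapply(meta$fovs, function(fm) {
    donor <- read_stack_tiff(file.path(dir, paste0(fm$file, "_donor.tif")))
    donor <- donor * (scale / .tiff_scale)
    acc <- tiff::readTIFF(file.path(dir, paste0(fm$file, "_acceptor.tif"))) *
      scale
    truth <- NULL
    if (!is.null(truth_all)) {
      sel <- truth_all$well == fm$well & truth_all$fov == fm$fov
      if (any(sel))
        truth <- truth_all[sel, setdiff(names(truth_all),
                                        c("well", "condition", "fov"))]
    }
    list(well = fm$well, condition = fm$condition, role = fm$role,
         fov = fm$fov, labels = NULL, truth = truth, donor = donor,
         acceptor = acc)
  })
  structure(list(layout = layout, config = config, seed = meta$seed,
                 fovs = fovs), class = "flim_plate")
}

#' Write / read a per-plate calibration file
#'
#' Stores the plate-level temporal calibration (t0 and per-gate
#' background) as structured text so fits on any FOV of the plate use one
#' consistent calibration.
#'
#' @param t0 Decay time origin (ps).
#' @param background Per-gate background counts.
#' @param path File path (YAML).
#' @return `write_plate_calibration` invisibly returns `path`;
#'   `read_plate_calibration` returns a list with `t0` and `background`.
#' @export
write_plate_calibration <- function(t0, background, path) {
  yaml::write_yaml(list(t0 = t0, background = background), path)
  invisible(path)
}

#' @rdname write_plate_calibration
#' @export
read_plate_calibration <- function(path) {
  cal <- yaml::read_yaml(path)
  list(t0 = cal$t0, background = unlist(cal$background))
}
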