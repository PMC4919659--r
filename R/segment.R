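#' Threshold-based cell segmentation
#'
#' Segments cells by intensity thresholding and connected components: each
#' channel image is smoothed with a small box filter, thresholded at
#' `median + k * mad` (a robust background + k-sigma rule), the channel
#' masks are combined (for co-transfection conditions a cell must exceed
#' both the donor and the acceptor threshold), connected components are
#' labelled, and components below `min_area` or touching the image border
#' are discarded. Labels are renumbered 1..n.
#'
#' @param donor_image Donor intensity image (e.g. the first gate or the
#'   gate sum).
#' @param acceptor_image Optional acceptor intensity image, same size.
#' @param require_acceptor Require cells to be above threshold in the
#'   acceptor channel too (default when an acceptor image is supplied).
#' @param k Threshold stringency in robust sigma units.
#' @param min_area Minimum component area (px).
#' @param smooth_radius Box-filter half-width (px) applied before
#'   thresholding; 0 disables smoothing.
#' @param exclude_border Drop components touching the image border.
#' @return Integer label matrix (0 = background) with attributes
#'   `threshold_donor` and `threshold_acceptor`.
#' @export
segment_cells <- function(donor_image, acceptor_image = NULL,
                          require_acceptor = !is.null(acceptor_image),
                          k = 5, min_area = 100, smooth_radius = 2,
                          exclude_border = TRUE) {
  stopifnot(is.matrix(donor_image))
  if (!is.null(acceptor_image))
    stopifnot(identical(dim(acceptor_image), dim(donor_image)))
  smooth <- function(img) {
    if (smooth_radius <= 0) return(img)
    side <- 2 * smooth_radius + 1
    kern <- matrix(1 / side^2, side, side)
    EBImage::filter2(img, kern, boundary = "replicate")
  }
  thr_of <- function(img) {
    stats::median(img) + k * max(stats::mad(img), .Machine$double.eps)
  }
  ds <- smooth(donor_image)
  thr_d <- thr_of(ds)
  mask <- ds > thr_d
  thr_a <- NA_real_
  if (require_acceptor) {
    if (is.null(acceptor_image))
      stop("require_acceptor = TRUE needs an acceptor image")
    as <- smooth(acceptor_image)
    thr_a <- thr_of(as)
    mask <- mask & (as > thr_a)
  }
  if (smooth_radius > 0) {
    # undo the dilation introduced by smoothing bright cells over the
    # threshold: brings the mask boundary back to the true cell edge
    brush <- EBImage::makeBrush(2 * smooth_radius + 1, shape = "disc")
    mask <- EBImage::erode(mask, brush) > 0
  }
  labels <- EBImage::bwlabel(mask)
  labels <- matrix(as.integer(labels), nrow(mask), ncol(mask))
  if (max(labels) > 0) {
    drop_ids <- integer(0)
    tab <- tabulate(labels, nbins = max(labels))
    drop_ids <- which(tab < min_area)
    if (exclude_border) {
      border <- unique(c(labels[1, ], labels[nrow(labels), ],
                         labels[, 1], labels[, ncol(labels)]))
      drop_ids <- union(drop_ids, border[border > 0])
    }
    if (length(drop_ids)) labels[labels %in% drop_ids] <- 0L
    # renumber surviving labels consecutively
    ids <- sort(unique(labels[labels > 0]))
    if (length(ids)) {
      map <- integer(max(ids)); map[ids] <- seq_along(ids)
      labels[labels > 0] <- map[labels[labels > 0]]
    }
  }
  attr(labels, "threshold_donor") <- thr_d
  attr(labels, "threshold_acceptor") <- thr_a
  labels
}

#' Per-cell intensity and decay aggregation
#'
#' For every segmented cell, sums the gated donor decay and averages the
#' channel intensities over an eroded "photometry" mask. The erosion (by
#' the segmentation smoothing radius plus one) removes the threshold halo
#' at cell edges, where smoothing mixes cell and background signal; means
#' taken strictly inside the cell are unbiased. Cells whose eroded mask
#' falls below `min_interior` pixels are dropped.
#'
#' The summed interior decay is what the fitters consume: summing gates
#' over each cell mask maximises photons per decay while preserving the
#' per-cell fractions, since every pixel of a cell shares its mixture.
#'
#' @param donor_stack `H x W x G` gated donor counts.
#' @param acceptor_image Acceptor intensity image.
#' @param labels Label matrix from [segment_cells()].
#' @param background_donor Per-gate donor background (per pixel).
#' @param background_acceptor Acceptor background (per pixel).
#' @param erode_radius Erosion radius for the photometry mask (px).
#' @param min_interior Minimum interior pixels to retain a cell.
#' @return List: `cells` data.frame (cell, n_pixels, n_interior,
#'   donor_gate1_mean, acceptor_mean — both background-subtracted per
#'   pixel), `decays` matrix (cells x gates, raw interior sums),
#'   `background_per_cell` matrix of per-gate background matching the
#'   decay sums.
#' @export
aggregate_per_cell <- function(donor_stack, acceptor_image, labels,
                               background_donor = 0,
                               background_acceptor = 0,
                               erode_radius = 2, min_interior = 20) {
  d <- dim(donor_stack)
  stopifnot(length(d) == 3, identical(dim(labels)[1:2], d[1:2]))
  G <- d[3]
  bg <- rep_len(background_donor, G)
  n <- max(labels, 0)
  empty <- list(
    cells = data.frame(cell = integer(0), n_pixels = integer(0),
                       n_interior = integer(0),
                       donor_gate1_mean = numeric(0),
                       acceptor_mean = numeric(0)),
    decays = matrix(numeric(0), 0, G),
    background_per_cell = matrix(numeric(0), 0, G))
  if (n == 0) return(empty)
  interior <- labels
  if (erode_radius > 0) {
    brush <- EBImage::makeBrush(2 * erode_radius + 1, shape = "disc")
    er <- EBImage::erode(labels > 0, brush)
    interior <- labels * matrix(as.integer(er > 0), d[1], d[2])
  }
  lab_vec <- as.vector(interior)
  keep_px <- lab_vec > 0
  lv <- lab_vec[keep_px]
  n_pixels <- tabulate(as.vector(labels)[as.vector(labels) > 0], nbins = n)
  n_interior <- tabulate(lv, nbins = n)
  px <- matrix(donor_stack, d[1] * d[2], G)[keep_px, , drop = FALSE]
  decays <- matrix(0, n, G)
  for (g in seq_len(G))
    decays[, g] <- unname(rowsum(px[, g], lv, reorder = TRUE))
  acc <- unname(rowsum(as.vector(acceptor_image)[keep_px], lv,
                       reorder = TRUE))[, 1]
  cells <- data.frame(
    cell = seq_len(n), n_pixels = n_pixels, n_interior = n_interior,
    donor_gate1_mean = decays[, 1] / pmax(n_interior, 1) - bg[1],
    acceptor_mean = acc / pmax(n_interior, 1) - background_acceptor)
  bg_per_cell <- outer(n_interior, bg)
  keep <- n_interior >= min_interior
  list(cells = cells[keep, , drop = FALSE],
       decays = decays[keep, , drop = FALSE],
       background_per_cell = bg_per_cell[keep, , drop = FALSE])
}

#' Match segmented labels to reference labels by overlap
#'
#' Greedy intersection-over-union matching between two label images,
#' used to validate segmentation against the generator's ground-truth
#' masks.
#'
#' @param labels,reference Integer label matrices of equal size.
#' @param min_iou Minimum IoU for a match.
#' @return data.frame `label`, `reference`, `iou`, one row per matched
#'   pair.
#' @export
match_labels <- function(labels, reference, min_iou = 0.5) {
  stopifnot(identical(dim(labels), dim(reference)))
  lv <- as.vector(labels); rv <- as.vector(reference)
  both <- lv > 0 & rv > 0
  if (!any(both))
    return(data.frame(label = integer(0), reference = integer(0),
                      iou = numeric(0)))
  ov <- table(lv[both], rv[both])
  area_l <- tabulate(lv[lv > 0], nbins = max(lv))
  area_r <- tabulate(rv[rv > 0], nbins = max(rv))
  pairs <- which(ov > 0, arr.ind = TRUE)
  li <- as.integer(rownames(ov))[pairs[, 1]]
  ri <- as.integer(colnames(ov))[pairs[, 2]]
  inter <- ov[pairs]
  iou <- inter / (area_l[li] + area_r[ri] - inter)
  ord <- order(iou, decreasing = TRUE)
  used_l <- used_r <- logical(0)
  out <- list()
  taken_l <- rep(FALSE, max(lv)); taken_r <- rep(FALSE, max(rv))
  for (j in ord) {
    if (iou[j] < min_iou) break
    if (taken_l[li[j]] || taken_r[ri[j]]) next
    taken_l[li[j]] <- TRUE; taken_r[ri[j]] <- TRUE
    out[[length(out) + 1]] <- data.frame(label = li[j], reference = ri[j],
                                         iou = iou[j])
  }
  if (!length(out))
    return(data.frame(label = integer(0), reference = integer(0),
                      iou = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$label), , drop = FALSE]
}
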