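#' Plate map of mean donor lifetimes
#'
#' Colour-coded per-well map of the mean monoexponential donor lifetime,
#' the standard at-a-glance rendering of a FLIM-FRET screening plate.
#'
#' @param records Per-cell record table from [analyze_plate()].
#' @return A ggplot object.
#' @export
plot_plate_map <- function(records) {
  pm <- stats::aggregate(tau_mono ~ well, data = records, FUN = mean,
                         na.rm = TRUE)
  pm$row <- substr(pm$well, 1, 1)
  pm$col <- as.integer(substr(pm$well, 2, 3))
  ggplot2::ggplot(pm, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$tau_mono)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_y_discrete(limits = rev(sort(unique(pm$row)))) +
    ggplot2::scale_fill_viridis_c(name = "mean τ (ps)") +
    ggplot2::labs(x = "column", y = "row",
                  title = "Mean donor lifetime per well") +
    ggplot2::theme_minimal()
}

#' Donor lifetime versus acceptor/donor intensity ratio
#'
#' Per-cell 2D scatter of the monoexponential donor lifetime against the
#' acceptor/donor intensity ratio. Interacting conditions show reduced
#' lifetimes already at low acceptor excess, separating from
#' non-interacting conditions across all ratio bins; this view is robust
#' to the uncorrelated donor/acceptor stoichiometry of co-transfection.
#'
#' @param records Per-cell record table with `ratio` and `tau_mono`
#'   columns (cells lacking a ratio are dropped).
#' @return A ggplot object.
#' @export
plot_lifetime_ratio <- function(records) {
  df <- records[!is.na(records$ratio) & !is.na(records$tau_mono), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio, y = .data$tau_mono,
                                   colour = .data$condition,
                                   shape = .data$role)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "acceptor / donor intensity ratio",
                  y = "donor lifetime (ps)") +
    ggplot2::theme_minimal()
}
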