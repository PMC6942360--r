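# Figures: equilibrium occupancy vs. landscape dynamism, one panel per
# species, one series per habitat-cover level. Plots are views of the
# results table, never recomputations: the saved figure carries a sidecar
# CSV with exactly the plotted values.

#' Plot equilibrium occupancy against landscape dynamism
#'
#' One panel per species; within a panel, dynamism on the x axis, mean
#' final occupancy with its 95% confidence interval on the y axis, and one
#' colour series per habitat-cover level. Rows with undefined CIs (single
#' iteration) are drawn as bare points with a warning.
#'
#' @param results results data frame from [run_experiment()].
#' @param species_ids optional subset of species ids to plot.
#' @return a ggplot object.
#' @export
plot_occupancy <- function(results, species_ids = NULL) {
  if (is.null(results) || nrow(results) == 0) {
    stop("results table is empty", call. = FALSE)
  }
  if (!is.null(species_ids)) {
    results <- results[results$species_id %in% species_ids, , drop = FALSE]
    if (nrow(results) == 0) stop("no rows for the requested species ids",
                                 call. = FALSE)
  }
  if (anyNA(results$ci_low)) {
    warning("some rows have undefined confidence intervals; ",
            "plotting points without error bars for those")
  }
  results$cover_lab <- factor(sprintf("%g%% cover", 100 * results$cover),
                              levels = sprintf("%g%% cover",
                                               sort(unique(100 * results$cover))))
  results$panel <- sprintf("species %d (%s)", results$species_id,
                           results$preference)
  gg <- ggplot2::ggplot(
    results,
    ggplot2::aes(x = 100 * .data$dynamism, y = .data$mean_occupancy,
                 colour = .data$cover_lab, group = .data$cover_lab)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "landscape dynamism (% patches turned over per step)",
                  y = "equilibrium metapopulation occupancy",
                  colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_bw()
  has_ci <- !is.na(results$ci_low)
  if (any(has_ci)) {
    gg <- gg + ggplot2::geom_errorbar(
      data = results[has_ci, , drop = FALSE],
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high), width = 0.8
    )
  }
  if (length(unique(results$panel)) > 1) {
    gg <- gg + ggplot2::facet_wrap(~panel)
  } else {
    gg <- gg + ggplot2::ggtitle(unique(results$panel))
  }
  gg
}

#' Save the occupancy figure with a sidecar data table
#'
#' Writes the figure and, next to it, `<stem>_data.csv` containing exactly
#' the columns plotted (`species_id, preference, cover, dynamism,
#' mean_occupancy, ci_low, ci_high`), so downstream checks can read the
#' plotted values without touching pixels.
#'
#' @inheritParams plot_occupancy
#' @param path figure file path; the extension selects the device
#'   (pdf/png/svg, per [ggplot2::ggsave()]).
#' @param width,height figure size in inches.
#' @return invisibly, a list with `figure` and `data` file paths.
#' @export
save_occupancy_figure <- function(results, path, species_ids = NULL,
                                  width = 9, height = 6) {
  gg <- plot_occupancy(results, species_ids)
  ggplot2::ggsave(path, gg, width = width, height = height)
  sidecar <- sub("\\.[A-Za-z]+$", "", path)
  sidecar <- paste0(sidecar, "_data.csv")
  keep <- c("species_id", "preference", "cover", "dynamism",
            "mean_occupancy", "ci_low", "ci_high")
  tab <- results
  if (!is.null(species_ids)) {
    tab <- tab[tab$species_id %in% species_ids, , drop = FALSE]
  }
  utils::write.csv(tab[, keep], sidecar, row.names = FALSE)
  invisible(list(figure = path, data = sidecar))
}
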