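#' Excitability time-course plot
#'
#' Mean baseline-normalized MEP amplitude (+/- SE across participants) per
#' time bin, one line per task, faceted by coil orientation — cue-locked or
#' response-locked depending on the input.
#'
#' @param binned A binned-excitability tibble.
#' @return A ggplot object.
#' @export
plot_excitability <- function(binned) {
  stopifnot_cols(binned, c("participant_id", "task", "coil", "bin",
                           "mean_norm_mep"), "`binned`")
  summ <- binned |>
    group_by(.data$task, .data$coil, .data$bin) |>
    summarise(
      se = sd(.data$mean_norm_mep) / sqrt(n()),
      mean = mean(.data$mean_norm_mep),
      .groups = "drop"
    )
  ggplot(summ, aes(x = .data$bin, y = .data$mean,
                   colour = .data$task, group = .data$task)) +
    geom_hline(yintercept = 1, linetype = "dotted", colour = "grey50") +
    geom_line() +
    geom_pointrange(aes(ymin = .data$mean - .data$se,
                        ymax = .data$mean + .data$se),
                    size = 0.3) +
    facet_wrap(~coil) +
    scale_colour_manual(values = c(SST = "#c0392b", GoOnly = "#2980b9")) +
    labs(x = "time bin", y = "MEP (normalized to baseline)",
         colour = NULL) +
    theme_minimal()
}

#' @export
autoplot.ss_binned <- function(object, ...) plot_excitability(object)

#' State-space trajectory plot
#'
#' Plots the (PA120, AP30) excitability trajectory through the bin sequence
#' for each task, with the dashed x = y reference line marking balanced
#' PA/AP excitability. Group-scope trajectories give the cleanest picture.
#'
#' @param trajectories A trajectory tibble from [build_trajectories()].
#' @return A ggplot object.
#' @export
plot_trajectory <- function(trajectories) {
  stopifnot_cols(trajectories, c("task", "bin", "pa", "ap"), "`trajectories`")
  start_bin <- bin_levels(unique(trajectories$alignment)[1])[1]
  ggplot(trajectories,
         aes(x = .data$pa, y = .data$ap, colour = .data$task,
             group = interaction(.data$task, .data$participant_id))) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey50") +
    geom_path() +
    geom_point(aes(shape = .data$bin == start_bin), size = 2,
               show.legend = FALSE) +
    scale_shape_manual(values = c(`TRUE` = 8, `FALSE` = 16)) +
    scale_colour_manual(values = c(SST = "#c0392b", GoOnly = "#2980b9")) +
    labs(x = "normalized PA120 MEP", y = "normalized AP30 MEP",
         colour = NULL) +
    coord_equal() +
    theme_minimal()
}

#' @export
autoplot.ss_trajectory <- function(object, ...) plot_trajectory(object)

#' Distance-series plot
#'
#' Per-bin Euclidean and cosine distances for the real (SST vs Go-only) and
#' simulated (bootstrap null) comparisons: mean +/- SE across participants,
#' faceted by metric.
#'
#' @param comparison Long table from [assemble_comparison_table()], or a
#'   distance tibble (which is then pivoted automatically).
#' @return A ggplot object.
#' @export
plot_distances <- function(comparison) {
  if (all(c("euclidean_d", "cosine_d") %in% names(comparison))) {
    comparison <- comparison |>
      pivot_longer(c("euclidean_d", "cosine_d"),
                   names_to = "metric", values_to = "distance") |>
      mutate(metric = sub("_d$", "", .data$metric))
  }
  stopifnot_cols(comparison, c("bin", "analysis_type", "metric", "distance"),
                 "`comparison`")
  summ <- comparison |>
    group_by(.data$metric, .data$analysis_type, .data$bin) |>
    summarise(se = sd(.data$distance) / sqrt(n()),
              mean = mean(.data$distance), .groups = "drop")
  ggplot(summ, aes(x = .data$bin, y = .data$mean,
                   colour = .data$analysis_type,
                   group = .data$analysis_type)) +
    geom_line() +
    geom_pointrange(aes(ymin = .data$mean - .data$se,
                        ymax = .data$mean + .data$se), size = 0.3) +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "time bin", y = "distance", colour = NULL) +
    theme_minimal()
}

#' @export
autoplot.ss_distances <- function(object, ...) plot_distances(object)
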