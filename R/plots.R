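#' Plot population trajectories
#'
#' Phage titres and host densities per replicate on a log10 scale with the
#' detection limit drawn as a dashed line.
#'
#' @param trajectory Trajectory tibble (`replicate`, `day`, `cfu_per_ml`,
#'   `pfu_per_ml`).
#' @param detection_limit Detection limit to draw (PFU/ml).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(trajectory, detection_limit = 200) {
  long <- tidyr::pivot_longer(trajectory, c("cfu_per_ml", "pfu_per_ml"),
                              names_to = "population", values_to = "density")
  long$population <- ifelse(long$population == "cfu_per_ml", "host (CFU/ml)",
                            "phage (PFU/ml)")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day,
                                     y = pmax(.data$density, 1),
                                     colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = detection_limit, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~replicate) +
    ggplot2::labs(x = "days post-infection", y = "density",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.range_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$dpi), y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "days post-infection",
                  y = paste("mean", object$statistic[1], "range")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.timeshift_table <- function(object, ...) {
  bg <- object$backgrounds
  bg$background <- factor(bg$background, c("past", "present", "future"))
  ggplot2::ggplot(bg, ggplot2::aes(x = .data$background, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "phage background relative to host",
                  y = "proportion of hosts infected") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gxe_series <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = factor(.data$host_dpi),
                               y = .data$mean_ratio)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::labs(x = "host days post-infection",
                  y = "G×E / E mean-square ratio") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.diversity_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, "replicate", "dpi", "pwd", "richness",
                  "mean_spacers"),
    c("pwd", "richness", "mean_spacers"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$dpi), y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "days post-infection", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the genome-location histogram of acquired spacers
#'
#' @param histogram Tibble from [location_histogram()].
#' @param bin_size Bin width used (for bar width).
#' @return A ggplot object.
#' @export
plot_spacer_locations <- function(histogram, bin_size = 1000L) {
  ggplot2::ggplot(histogram,
                  ggplot2::aes(x = .data$bin_start + bin_size / 2,
                               y = .data$count, fill = factor(.data$dpi))) +
    ggplot2::geom_col(width = bin_size * 0.9) +
    ggplot2::facet_wrap(~replicate) +
    ggplot2::labs(x = "genome position (nt)", y = "acquired spacers",
                  fill = "dpi") +
    ggplot2::theme_minimal()
}
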