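# ggplot2 helpers for the main result types. Thin layers: they return
# ggplot objects the user can restyle.

#' Plot alpha-diversity trajectories
#'
#' One panel per index, one line per experiment, with optional vertical
#' marks for injections (solid) and refills (dashed).
#'
#' @param alpha Output of [alpha_diversity()].
#' @param designs Optional [experiment_designs()] tibble for event marks.
#' @return A ggplot object.
#' @export
plot_alpha <- function(alpha, designs = NULL) {
  p <- ggplot2::ggplot(alpha, ggplot2::aes(x = .data$day, y = .data$value,
                                           colour = .data$experiment)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$index),
                        cols = ggplot2::vars(.data$experiment),
                        scales = "free_y") +
    ggplot2::labs(x = "day (0 = H2 injection)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
  if (!is.null(designs)) {
    ev <- designs |>
      tidyr::pivot_longer(c("injection_days", "refill_days"),
                          names_to = "event", values_to = "day") |>
      tidyr::unnest("day")
    p <- p + ggplot2::geom_vline(
      data = ev,
      ggplot2::aes(xintercept = .data$day,
                   linetype = .data$event),
      colour = "grey40", linewidth = 0.3) +
      ggplot2::scale_linetype_manual(
        values = c(injection_days = "solid", refill_days = "dashed"),
        guide = "none")
  }
  p
}

#' Plot z-score-normalized beta diversity per pair and time category
#'
#' Mirrors the conventional presentation: one point per (pair, category)
#' with the +-threshold band of the null model.
#'
#' @param beta Output of [pairwise_beta()].
#' @param threshold Band half-width (default 1.96).
#' @return A ggplot object.
#' @export
plot_beta_z <- function(beta, threshold = 1.96) {
  ggplot2::ggplot(beta, ggplot2::aes(x = .data$category, y = .data$z,
                                     group = .data$pair)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = c(-threshold, threshold),
                        colour = "grey30") +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$pair)) +
    ggplot2::labs(x = NULL, y = "z (observed vs mock-community null)") +
    ggplot2::theme_minimal()
}

#' Plot guild composition over time
#'
#' Stacked per-day guild fractions per experiment. With multi-guild
#' annotations the stack can exceed 1 (dual counting); see
#' [guild_trajectory()].
#'
#' @param guild_traj Output of [guild_trajectory()].
#' @return A ggplot object.
#' @export
plot_guilds <- function(guild_traj) {
  ggplot2::ggplot(guild_traj,
                  ggplot2::aes(x = .data$day, y = .data$fraction,
                               fill = .data$guild)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::facet_wrap(ggplot2::vars(.data$experiment)) +
    ggplot2::labs(x = "day (0 = H2 injection)", y = "fraction of reads") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.slime_report <- function(object, ...) {
  plot_beta_z(object$beta, threshold = object$config$threshold)
}

#' Autoplot method for null distributions
#'
#' Histogram of the null draws with the observed value, if given.
#'
#' @param object A `null_distribution`.
#' @param observed Optional observed Jaccard dissimilarity to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.null_distribution <- function(object, observed = NULL, ...) {
  p <- ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$jaccard)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$mean, linetype = "dotted") +
    ggplot2::labs(x = "Jaccard dissimilarity (mock pairs)", y = "count") +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_vline(xintercept = observed, colour = "red")
  }
  p
}
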