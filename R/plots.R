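#' Trial-cycle force timelines
#'
#' Mean anticipatory force per trial cycle for each object, with dashed
#' lines at the actual object weights -- the package's analogue of the
#' standard learning-curve figure.
#'
#' @param table Single-condition behavior tibble.
#' @return A ggplot object.
#' @export
plot_force_timelines <- function(table) {
  assert_single_condition(table)
  d <- table |>
    dplyr::group_by(.data$cycle, .data$object_id) |>
    dplyr::summarise(force = mean(.data$anticipatory_force_N),
                     weight = weight_to_force(mean(.data$mass_g)),
                     .groups = "drop") |>
    dplyr::mutate(object = factor(.data$object_id))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cycle, y = .data$force,
                                  color = .data$object)) +
    ggplot2::geom_line(linewidth = ifelse(d$object_id == 3L, 0.9, 0.4)) +
    ggplot2::geom_hline(
      data = dplyr::distinct(d, .data$object, .data$weight),
      ggplot2::aes(yintercept = .data$weight, color = .data$object),
      linetype = "dashed", alpha = 0.6) +
    ggplot2::labs(x = "Trial cycle", y = "Anticipatory force (N)",
                  color = "Object",
                  title = unique(table$condition)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.gmm_fit
#' @export
autoplot.bimodality_result <- function(object, ...) {
  p <- autoplot.gmm_fit(object$fit2, ...)
  x <- object$fit1$data
  grid <- seq(min(x) - 2 * sd(x), max(x) + 2 * sd(x), length.out = 400)
  d1 <- tibble::tibble(
    x = grid,
    density = dnorm(grid, object$fit1$means, object$fit1$sds))
  p + ggplot2::geom_line(data = d1,
                         ggplot2::aes(x = .data$x, y = .data$density),
                         color = "steelblue", linewidth = 0.8)
}

#' Histogram with fitted mixture densities
#'
#' @param object A `gmm_fit` (or `bimodality_result`, which overlays the
#'   single-component fit in blue and the two-component fit in green).
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gmm_fit <- function(object, bins = 15, ...) {
  x <- object$data
  grid <- seq(min(x) - 2 * sd(x), max(x) + 2 * sd(x), length.out = 400)
  dens <- purrr::map_dfr(seq_len(object$n_components), function(k) {
    tibble::tibble(component = factor(k), x = grid,
                   density = object$weights[k] *
                     dnorm(grid, object$means[k], object$sds[k]))
  })
  total <- dens |>
    dplyr::group_by(.data$x) |>
    dplyr::summarise(density = sum(.data$density), .groups = "drop")
  ggplot2::ggplot(tibble::tibble(value = x),
                  ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80",
                            color = "grey50") +
    ggplot2::geom_line(data = total,
                       ggplot2::aes(x = .data$x, y = .data$density),
                       color = "seagreen", linewidth = 0.9,
                       inherit.aes = FALSE) +
    ggplot2::labs(x = "Outlier learning (N)", y = "Density") +
    ggplot2::theme_minimal()
}

#' Release-phase trace plot
#'
#' @param object A `release_trace` from [simulate_release()].
#' @param ... Unused.
#' @return A ggplot object with position and load-force panels.
#' @export
autoplot.release_trace <- function(object, ...) {
  d <- tidyr::pivot_longer(object, c("position_m", "force_N"),
                           names_to = "series", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_s, y = .data$value)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Power-curve plot
#'
#' @param curve Output of [power_curve()].
#' @return A ggplot object.
#' @export
plot_power_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$n, y = .data$power)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo,
                                      ymax = .data$ci_hi),
                         fill = "steelblue", alpha = 0.2) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(color = "steelblue") +
    ggplot2::labs(x = "Sample size", y = "P(two-component favored)") +
    ggplot2::theme_minimal()
}
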