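#' Alpha-beta-gamma plot
#'
#' Renders an `abg_bundle` in the conventional dual-axis layout: alpha
#' diversity in red on the left axis, the multiple-site Simpson dissimilarity
#' in blue rescaled onto a right-hand axis, both against subsampled gamma
#' diversity, with their 95% confidence bands; one panel per group with a
#' uniform gamma scale.
#'
#' @param object An `abg_bundle` from [abg_plot_data()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.abg_bundle <- function(object, ...) {
  tabs <- bundle_tables(object)
  pts <- tabs$points
  bands <- tabs$bands
  amax <- max(pts$alpha, 1)
  scale_beta <- function(b) b * amax  # beta in [0,1] onto the alpha axis
  bands <- bands |>
    dplyr::mutate(dplyr::across(
      c("fit", "lower", "upper"),
      ~ ifelse(.data$component == "beta", scale_beta(.x), .x)))
  pts_long <- dplyr::bind_rows(
    dplyr::transmute(pts, .data$group, component = "alpha", gamma = .data$gamma,
                     value = .data$alpha),
    dplyr::transmute(pts, .data$group, component = "beta", gamma = .data$gamma,
                     value = scale_beta(.data$beta_sim)))
  ggplot2::ggplot(bands, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_point(data = pts_long,
                        ggplot2::aes(x = .data$gamma, y = .data$value,
                                     colour = .data$component),
                        alpha = 0.5, size = 1) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper,
                                      group = .data$component),
                         fill = "grey70", alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit, colour = .data$component),
                       linewidth = 1) +
    ggplot2::scale_colour_manual(values = c(alpha = "#c0392b", beta = "#2f6db3")) +
    ggplot2::scale_y_continuous(
      name = "alpha diversity (mean species per collection)",
      sec.axis = ggplot2::sec_axis(~ . / amax, name = "Simpson's metric (beta)")) +
    ggplot2::facet_wrap(~ group) +
    ggplot2::labs(x = "gamma diversity (subsampled species richness)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Null-distribution diagnostic plot
#'
#' Histogram of the null beta-gamma slopes with the observed per-period
#' slopes overlaid.
#'
#' @param null A `null_distribution` from [null_slopes()].
#' @param periods Optional per-period coupling table (from [coupling_test()]).
#' @return A ggplot object.
#' @export
plot_null <- function(null, periods = NULL) {
  df <- tidy(null)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$slope)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey60", colour = "white") +
    ggplot2::geom_vline(xintercept = null$mean_slope, linetype = 2) +
    ggplot2::labs(x = "null beta-gamma slope", y = "trials") +
    ggplot2::theme_minimal()
  if (!is.null(periods)) {
    p <- p + ggplot2::geom_vline(data = periods,
                                 ggplot2::aes(xintercept = .data$slope),
                                 colour = "#c0392b") +
      ggplot2::geom_text(data = periods,
                         ggplot2::aes(x = .data$slope, y = Inf,
                                      label = .data$Period),
                         angle = 90, vjust = -0.4, hjust = 1.1, size = 3)
  }
  p
}
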