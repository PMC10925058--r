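# ggplot2 display helpers for the main result types. These are diagnostic
# displays, not publication figures.

#' Scatter of the F_bn-Q_n clouds with fitted models
#'
#' @param data Regional table (or cloud) with `q_n`, `f_bn` and optionally
#'   `condition`.
#' @param models Optional named list of [coupling_model()] objects (one per
#'   condition) drawn as curves.
#' @return A ggplot.
#' @export
plot_coupling <- function(data, models = NULL) {
  assert_cols(data, c("q_n", "f_bn"), "plot_coupling")
  has_cond <- "condition" %in% names(data)
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$q_n, y = .data$f_bn)) +
    (if (has_cond) ggplot2::geom_point(ggplot2::aes(colour = .data$condition), alpha = 0.6)
     else ggplot2::geom_point(alpha = 0.6)) +
    ggplot2::labs(x = "Normalized perfusion Q_n",
                  y = "Normalized blood volume F_bn") +
    ggplot2::theme_minimal()
  if (!is.null(models)) {
    grid <- seq(max(0, min(data$q_n)), max(data$q_n), length.out = 200)
    curves <- purrr::imap_dfr(models, function(m, nm) {
      tibble::tibble(q_n = grid, f_bn = predict(m, grid), condition = nm)
    })
    p <- p + ggplot2::geom_line(
      data = curves,
      mapping = if (has_cond) ggplot2::aes(colour = .data$condition) else NULL,
      linewidth = 0.8
    )
  }
  p
}

#' Vertical profiles of the normalized quantities
#'
#' @param profiles Output of [vertical_profiles()].
#' @return A ggplot with one panel per quantity.
#' @export
plot_vertical_profiles <- function(profiles) {
  assert_cols(profiles, c("height_mid", "q_n_mean", "f_bn_mean"),
              "plot_vertical_profiles")
  long <- profiles |>
    tidyr::pivot_longer(cols = c("q_n_mean", "f_bn_mean"),
                        names_to = "quantity", values_to = "mean") |>
    dplyr::mutate(quantity = ifelse(.data$quantity == "q_n_mean", "Q_n", "F_bn"))
  has_cond <- "condition" %in% names(long)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mean, y = .data$height_mid)) +
    (if (has_cond) ggplot2::geom_path(ggplot2::aes(colour = .data$condition))
     else ggplot2::geom_path()) +
    (if (has_cond) ggplot2::geom_point(ggplot2::aes(colour = .data$condition))
     else ggplot2::geom_point()) +
    ggplot2::facet_wrap(~quantity) +
    ggplot2::labs(x = "Level mean", y = "Relative height (0 = dependent)") +
    ggplot2::theme_minimal()
}

#' Longitudinal comet display
#'
#' Draws, for each ROI, the segment from its baseline `(q_a, f_ba)` to its
#' injury value, grouped by height level.
#'
#' @param longitudinal Output of [longitudinal_changes()].
#' @param n_levels Number of height bands used for colouring (default 5).
#' @return A ggplot.
#' @export
plot_longitudinal <- function(longitudinal, n_levels = 5) {
  assert_cols(longitudinal,
              c("q_a_baseline", "q_a_injury", "f_ba_baseline", "f_ba_injury",
                "height_fraction"),
              "plot_longitudinal")
  d <- longitudinal |>
    dplyr::mutate(level = factor(pmin(
      findInterval(.data$height_fraction, seq(0, 1, length.out = n_levels + 1),
                   rightmost.closed = TRUE), n_levels)))
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$q_a_baseline, y = .data$f_ba_baseline,
                   xend = .data$q_a_injury, yend = .data$f_ba_injury,
                   colour = .data$level),
      alpha = 0.6,
      arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm"))
    ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "Adjusted perfusion Q_a", y = "Adjusted blood volume F_ba",
                  colour = "Height level") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sokoloff_fit <- function(object, ...) {
  d <- object$fitted |>
    dplyr::mutate(mid_s = (.data$frame_start_s + .data$frame_end_s) / 2)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mid_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "Time (s)", y = "Activity (kBq/ml)",
                  title = "Sokoloff fit") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
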