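#' Plot a cumulative DVH
#'
#' Step plot of the cumulative dose-volume histogram: fraction of structure
#' volume receiving at least each dose.
#'
#' @param object A `dvh_curve` from [cumulative_dvh()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dvh_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose, y = 100 * .data$frac_ge)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(
      x = "Dose (Gy)", y = "Volume (%)",
      title = sprintf("Cumulative DVH: %s (%s)",
                      attr(object, "structure"), attr(object, "modality"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a criterion decision matrix as interval ranges
#'
#' Conservative mean +/- 2 SD intervals per diagnostic group, faceted by DVH
#' point and coloured by modality, with the tolerance band shown as dashed
#' lines — the standard commissioning interval plot on which the pass/fail
#' pattern is read off.
#'
#' @param object A `decision_matrix` from [decision_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.decision_matrix <- function(object, ...) {
  tol <- attr(object, "tolerance")
  df <- tibble::as_tibble(object)
  df$diagnosis <- factor(df$diagnosis, levels = unique(df$diagnosis))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$diagnosis, y = .data$mean_pct,
                                   colour = .data$modality)) +
    ggplot2::geom_hline(yintercept = c(-tol, tol), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$interval_low, ymax = .data$interval_high,
                   shape = .data$passed),
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$dvh_point)) +
    ggplot2::labs(
      x = NULL, y = "Difference vs CT (%), mean ± 2 SD",
      shape = sprintf("within ±%g%%", tol)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.decision_matrix
#' @param x A `decision_matrix`.
#' @param y Unused.
#' @export
plot.decision_matrix <- function(x, y, ...) print(autoplot.decision_matrix(x, ...))
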