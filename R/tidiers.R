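#' Tidy a periodogram into its grid
#'
#' @param x An `"ls_periodogram"`.
#' @param ... Unused.
#' @return Tibble `(period_h, power, significant)`.
#' @export
tidy.ls_periodogram <- function(x, ...) {
  dplyr::mutate(x$grid, significant = .data$power >= x$z_alpha)
}

#' One-row summary of a periodogram
#'
#' @param x An `"ls_periodogram"`.
#' @param ... Unused.
#' @return Tibble with sample size, span, grid extent, `M`, `alpha`,
#'   `z_alpha`, `pn_floor` and the primary peak's period/power/p.
#' @export
glance.ls_periodogram <- function(x, ...) {
  i <- which.max(x$grid$power)
  tibble::tibble(
    n = x$n, span_h = x$span_h, M = x$M, alpha = x$alpha,
    z_alpha = x$z_alpha, pn_floor = x$pn_floor,
    peak_period_h = x$grid$period_h[i],
    peak_power = x$grid$power[i],
    peak_p = ls_p_value(x$grid$power[i], x$M)
  )
}

#' Plot a periodogram
#'
#' @param object An `"ls_periodogram"`.
#' @param ... Unused.
#' @return A ggplot of power against period with the significance threshold
#'   and the PN floor as horizontal lines.
#' @export
autoplot.ls_periodogram <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(.data$period_h, .data$power)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(
      yintercept = object$z_alpha, linetype = "dashed",
      colour = "firebrick"
    ) +
    ggplot2::geom_hline(
      yintercept = object$pn_floor, linetype = "dotted",
      colour = "steelblue"
    ) +
    ggplot2::labs(
      x = "period (h)", y = "normalized power (PN)",
      subtitle = sprintf(
        "dashed: alpha = %g threshold (M = %d); dotted: PN floor %g",
        object$alpha, object$M, object$pn_floor
      )
    ) +
    ggplot2::theme_minimal()
}

#' Dot plot of per-animal free-running periods by group
#'
#' Individual tau values as dots with the group mean +/- SEM overlaid, the
#' standard presentation for cohort free-running periods.
#'
#' @param tau_table Tibble with `treatment_group` and `tau_hours` columns.
#' @return A ggplot.
#' @export
plot_tau_points <- function(tau_table) {
  sm <- summarize_groups(tau_table)
  ggplot2::ggplot(
    tau_table,
    ggplot2::aes(.data$treatment_group, .data$tau_hours)
  ) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::geom_pointrange(
      data = sm,
      ggplot2::aes(
        y = .data$mean_tau,
        ymin = .data$mean_tau - dplyr::coalesce(.data$sem, 0),
        ymax = .data$mean_tau + dplyr::coalesce(.data$sem, 0)
      ),
      colour = "magenta3", linewidth = 1
    ) +
    ggplot2::labs(x = NULL, y = "free-running period τ (h)") +
    ggplot2::theme_minimal()
}
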