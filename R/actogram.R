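#' Build a double-plotted actogram
#'
#' Bins the record's counts modulo the fold period into rows of consecutive
#' periods; each row concatenates period i and period i+1, so a drifting
#' rhythm reads as a continuous diagonal. A parallel light matrix marks which
#' cells fall in a lights-on segment of the schedule.
#'
#' @param record An [activity_record()].
#' @param fold_period_hours Fold (row) period, hours; default 24.
#' @return An object of class `"actogram"`: list with `matrix` (days x
#'   2*bins-per-period counts, `NA` for missing bins), `light` (same shape,
#'   logical), `fold_period_hours`, `bin_seconds`.
#' @export
build_actogram <- function(record, fold_period_hours = 24) {
  bs <- record_bin_seconds(record)
  bins_per_period <- as.integer(round(fold_period_hours * 3600 / bs))
  n_periods <- ceiling(nrow(record) / bins_per_period)
  padded <- rep(NA_real_, n_periods * bins_per_period)
  padded[seq_len(nrow(record))] <- record$count
  base <- matrix(padded, nrow = n_periods, ncol = bins_per_period, byrow = TRUE)

  sch <- attr(record, "schedule")
  light_vec <- rep(FALSE, n_periods * bins_per_period)
  if (!is.null(sch)) {
    tt <- (seq_along(light_vec) - 0.5) * bs / 3600
    on_segs <- sch[sch$lights == "on", , drop = FALSE]
    for (s in seq_len(nrow(on_segs))) {
      light_vec <- light_vec |
        (tt >= on_segs$start_h[s] & tt < on_segs$end_h[s])
    }
  }
  light_base <- matrix(light_vec,
    nrow = n_periods, ncol = bins_per_period,
    byrow = TRUE
  )

  double_plot <- function(m) {
    right <- rbind(m[-1, , drop = FALSE], matrix(NA, 1, ncol(m)))
    cbind(m, right)
  }
  mat <- double_plot(base)
  light <- double_plot(light_base)
  light[is.na(light)] <- FALSE

  structure(
    list(
      matrix = mat, light = light,
      fold_period_hours = fold_period_hours, bin_seconds = bs,
      animal_id = attr(record, "animal_id")
    ),
    class = "actogram"
  )
}

#' @export
print.actogram <- function(x, ...) {
  cat(sprintf(
    "<actogram> %s: %d rows x %d cells (fold %g h, double-plotted)\n",
    x$animal_id, nrow(x$matrix), ncol(x$matrix), x$fold_period_hours
  ))
  invisible(x)
}

#' Plot an actogram
#'
#' @param object An `"actogram"` from [build_actogram()].
#' @param ... Unused.
#' @return A ggplot: activity raster with the light schedule shaded.
#' @export
autoplot.actogram <- function(object, ...) {
  m <- object$matrix
  df <- tidyr::expand_grid(
    day = seq_len(nrow(m)),
    cell = seq_len(ncol(m))
  )
  df$count <- as.vector(t(m))
  df$light <- as.vector(t(object$light))
  df$hour <- (df$cell - 0.5) * object$bin_seconds / 3600
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hour, y = .data$day)) +
    ggplot2::geom_tile(
      data = df[df$light, ],
      fill = "lightyellow", height = 1
    ) +
    ggplot2::geom_tile(ggplot2::aes(alpha = .data$count), fill = "black", height = 0.8) +
    ggplot2::scale_alpha_continuous(range = c(0, 1), na.value = 0, guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(
      x = sprintf("time (h, two %g-h periods per row)", object$fold_period_hours),
      y = "day", title = object$animal_id
    ) +
    ggplot2::theme_minimal()
}
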