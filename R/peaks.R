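#' Detect significant periodogram peaks and distinct components
#'
#' Local maxima of the periodogram are tested against the significance
#' threshold. The highest point of the scan is the primary peak (reported with
#' its p-value whether or not it is significant). A significant secondary
#' maximum is reported as a *distinct* rhythmic component only if it is
#' non-harmonic -- its period differs from the primary's period, half-period
#' and double period by more than `harmonic_tol_h` -- and its power is at
#' least `min_rel_power` of the primary's. The relative-power condition
#' rejects spectral-leakage sidelobes of a strong primary peak (a rectangular
#' observation window puts the first sidelobe at about 5% of the peak power,
#' which crosses any fixed significance threshold once the primary is strong
#' enough), so that a single consolidated rhythm is not mistaken for multiple
#' components.
#'
#' @param pg An `"ls_periodogram"` from [lomb_scargle()].
#' @param harmonic_tol_h Harmonic tolerance, hours (default 0.5).
#' @param min_rel_power Secondary-to-primary power ratio floor (default 0.1).
#' @return A tibble of peaks: `period_h`, `power`, `p_value`, `is_primary`,
#'   `significant`, `distinct_component`, ordered by decreasing power.
#' @export
detect_peaks <- function(pg, harmonic_tol_h = 0.5, min_rel_power = 0.1) {
  p <- pg$grid$power
  per <- pg$grid$period_h
  n <- length(p)
  i_max <- which.max(p)
  ## interior local maxima (plateau-safe), always including the global max
  is_lmax <- rep(FALSE, n)
  if (n >= 3L) {
    is_lmax[2:(n - 1)] <- p[2:(n - 1)] > p[1:(n - 2)] & p[2:(n - 1)] >= p[3:n]
  }
  is_lmax[i_max] <- TRUE
  idx <- which(is_lmax)

  out <- tibble::tibble(
    period_h = per[idx],
    power = p[idx],
    p_value = ls_p_value(p[idx], pg$M),
    is_primary = idx == i_max,
    significant = p[idx] >= pg$z_alpha
  )
  prim_per <- per[i_max]
  prim_pow <- p[i_max]
  harmonic <- purrr::map_lgl(out$period_h, function(pp) {
    !isTRUE(all.equal(pp, prim_per)) && (
      abs(pp - prim_per) <= harmonic_tol_h ||
        abs(pp - prim_per / 2) <= harmonic_tol_h ||
        abs(pp - prim_per * 2) <= harmonic_tol_h
    )
  })
  out$distinct_component <- out$is_primary |
    (out$significant & !harmonic & out$power >= min_rel_power * prim_pow)
  ## primary itself only counts as a component when significant
  out$distinct_component[out$is_primary] <- out$significant[out$is_primary]
  out <- dplyr::filter(out, .data$significant | .data$is_primary)
  dplyr::arrange(out, dplyr::desc(.data$power))
}

#' Refine the period of a peak by parabolic interpolation
#'
#' Fits a parabola to the log-power at the peak's grid point and its two
#' neighbours and returns the interpolated period. At a grid boundary no
#' interpolation is possible: the boundary value is returned with a warning.
#'
#' @param pg An `"ls_periodogram"`.
#' @param period_h Grid period of the peak to refine (default: the primary).
#' @return Interpolated period, hours.
#' @export
estimate_tau <- function(pg, period_h = NULL) {
  per <- pg$grid$period_h
  p <- pg$grid$power
  i <- if (is.null(period_h)) which.max(p) else which.min(abs(per - period_h))
  if (i == 1L || i == length(per)) {
    warn("peak at grid boundary; returning the boundary period uninterpolated")
    return(per[i])
  }
  y <- log(pmax(p[(i - 1):(i + 1)], 1e-300))
  x <- per[(i - 1):(i + 1)]
  ## parabola through three (possibly unevenly spaced) points, Newton form
  d1 <- (y[2] - y[1]) / (x[2] - x[1])
  c2 <- ((y[3] - y[2]) / (x[3] - x[2]) - d1) / (x[3] - x[1])
  if (c2 >= 0) {
    return(per[i]) # not a concave peak at this resolution
  }
  vertex <- (x[1] + x[2]) / 2 - d1 / (2 * c2)
  ## clamp to the bracketing interval
  min(max(vertex, x[1]), x[3])
}
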