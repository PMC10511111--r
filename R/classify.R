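#' Sliding-window period stability
#'
#' Estimates the free-running period in sliding windows over the DD series and
#' reports the range (max - min) of the window estimates. Only windows whose
#' periodogram has a significant peak contribute; a period that changes during
#' the measurement produces a large range. With fewer than two valid windows
#' the range is 0 and the result is flagged as low-coverage.
#'
#' The window scans use a finer grid (`oversample` 8 by default) than the main
#' periodogram: a 5-day window's natural grid step near circadian periods
#' exceeds 1 h, so sub-grid resolution is needed for a meaningful range.
#'
#' @param data A tibble `(time_h, count)` of DD samples (see [segment_dd()]).
#' @param window_days,step_days Window length and step, days.
#' @param period_range,alpha Passed to [lomb_scargle()].
#' @param oversample Oversampling of the window scans (default 8).
#' @return A list: `range_h`, `window_taus` (tibble of `window_start_day`,
#'   `tau_h`, `power`), `low_coverage`.
#' @export
period_stability <- function(data, window_days = 5, step_days = 1,
                             period_range = c(16, 35), alpha = 0.01,
                             oversample = 8) {
  t0 <- min(data$time_h)
  span_days <- (max(data$time_h) - t0) / 24
  if (span_days < window_days + step_days) {
    ## record too short for two windows
    return(list(
      range_h = 0,
      window_taus = tibble::tibble(
        window_start_day = numeric(), tau_h = numeric(), power = numeric()
      ),
      low_coverage = TRUE
    ))
  }
  starts <- seq(0, span_days - window_days, by = step_days)
  taus <- purrr::map_dfr(starts, function(s) {
    win <- data[data$time_h >= t0 + s * 24 &
      data$time_h < t0 + (s + window_days) * 24, ]
    if (nrow(win) < 8L || length(unique(win$count)) < 2L) {
      return(NULL)
    }
    pg <- lomb_scargle(win,
      period_range = period_range,
      oversample = oversample, alpha = alpha
    )
    pk <- pg$grid$power[which.max(pg$grid$power)]
    if (pk < pg$z_alpha) {
      return(NULL)
    }
    tibble::tibble(
      window_start_day = s,
      tau_h = estimate_tau(pg),
      power = pk
    )
  })
  if (nrow(taus) < 2L) {
    return(list(range_h = 0, window_taus = taus, low_coverage = TRUE))
  }
  list(
    range_h = max(taus$tau_h) - min(taus$tau_h),
    window_taus = taus,
    low_coverage = FALSE
  )
}

#' Classify a record as strong, complex or arrhythmic
#'
#' Applies the three-way rhythmicity rule: *arrhythmic* if the primary
#' periodogram power is below the PN floor (20 by default) or not significant
#' at `alpha`; otherwise *strong* if there is exactly one distinct significant
#' non-harmonic component and the sliding-window period range does not exceed
#' `stability_tol_h`; otherwise *complex* (more than one component, or an
#' unstable period).
#'
#' @param peaks Peak table from [detect_peaks()].
#' @param stability_range_h Range from [period_stability()].
#' @param pg The `"ls_periodogram"` the peaks came from.
#' @param stability_tol_h Stability tolerance, hours (default 1).
#' @return A one-row tibble: `classification`, `tau_hours` (`NA` for
#'   arrhythmic), `primary_power`, `primary_p`, `n_components`,
#'   `stability_range_h`.
#' @export
classify_rhythmicity <- function(peaks, stability_range_h, pg,
                                 stability_tol_h = 1.0) {
  prim <- peaks[peaks$is_primary, ]
  stopifnot(nrow(prim) == 1L)
  n_comp <- sum(peaks$distinct_component)
  arrhythmic <- prim$power < pg$pn_floor || prim$p_value >= pg$alpha
  classification <- if (arrhythmic) {
    "arrhythmic"
  } else if (n_comp == 1L && stability_range_h <= stability_tol_h) {
    "strong"
  } else {
    "complex"
  }
  tibble::tibble(
    classification = classification,
    tau_hours = if (arrhythmic) NA_real_ else estimate_tau(pg, prim$period_h),
    primary_power = prim$power,
    primary_p = prim$p_value,
    n_components = n_comp,
    stability_range_h = stability_range_h
  )
}

#' Analyze one activity record end to end
#'
#' DD segmentation, Lomb-Scargle scan, peak detection, period-stability
#' analysis and strong/complex/arrhythmic classification in one call.
#'
#' @param record An [activity_record()].
#' @param window_days,convention Passed to [segment_dd()].
#' @param period_range,oversample,alpha,pn_floor Passed to [lomb_scargle()].
#' @param harmonic_tol_h,min_rel_power Passed to [detect_peaks()].
#' @param stability_tol_h Passed to [classify_rhythmicity()].
#' @param stability_window_days,stability_step_days Passed to
#'   [period_stability()].
#' @return A one-row tibble with `animal_id`, the classification columns of
#'   [classify_rhythmicity()], `low_coverage`, and a list-column `peaks`.
#' @export
analyze_record <- function(record, window_days = NULL,
                           convention = c("label", "offset"),
                           period_range = c(16, 35), oversample = 4,
                           alpha = 0.01, pn_floor = 20,
                           harmonic_tol_h = 0.5, min_rel_power = 0.1,
                           stability_tol_h = 1.0,
                           stability_window_days = 5, stability_step_days = 1) {
  dd <- segment_dd(record, window_days = window_days, convention = convention)
  if (length(unique(dd$count)) < 2L) {
    ## a constant series carries no rhythm information
    return(tibble::tibble(
      animal_id = attr(record, "animal_id"),
      classification = "arrhythmic", tau_hours = NA_real_,
      primary_power = 0, primary_p = 1, n_components = 0L,
      stability_range_h = 0, low_coverage = TRUE, peaks = list(tibble::tibble())
    ))
  }
  pg <- lomb_scargle(dd,
    period_range = period_range, oversample = oversample,
    alpha = alpha, pn_floor = pn_floor
  )
  peaks <- detect_peaks(pg,
    harmonic_tol_h = harmonic_tol_h,
    min_rel_power = min_rel_power
  )
  stab <- period_stability(dd,
    window_days = stability_window_days,
    step_days = stability_step_days,
    period_range = period_range, alpha = alpha
  )
  call <- classify_rhythmicity(peaks, stab$range_h, pg,
    stability_tol_h = stability_tol_h
  )
  dplyr::bind_cols(
    tibble::tibble(animal_id = attr(record, "animal_id")),
    call,
    tibble::tibble(low_coverage = stab$low_coverage, peaks = list(peaks))
  )
}

#' Analyze a cohort of records
#'
#' @param cohort A tibble with list-column `record` (e.g. from
#'   [simulate_cohort()]) or a list of [activity_record()]s.
#' @param ... Passed to [analyze_record()].
#' @return A tibble of per-animal rhythm calls; cohort grouping columns
#'   (`group`, `true_tau_hours`, `phenotype`) are carried through when present.
#' @export
analyze_cohort <- function(cohort, ...) {
  if (is.data.frame(cohort)) {
    calls <- purrr::map_dfr(cohort$record, analyze_record, ...)
    keep <- intersect(c("group", "phenotype", "true_tau_hours"), names(cohort))
    dplyr::bind_cols(cohort[, keep, drop = FALSE], calls)
  } else {
    purrr::map_dfr(cohort, analyze_record, ...)
  }
}
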