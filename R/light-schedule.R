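#' Build a light schedule for an entrainment / free-run protocol
#'
#' A light schedule is a tibble of contiguous, non-overlapping segments
#' `(start_h, end_h, lights)` covering the whole recording span, in hours since
#' the start of the recording. The recording is assumed to start at lights-on
#' of the first entrainment day, so Zeitgeber Time 0 (ZT0) falls at `zt0_h`
#' hours (0 by default) into the recording.
#'
#' The standard protocol is `entrain_days` light-dark (LD) cycles of
#' `light_hours` light followed by `dark_hours` darkness, then `dd_days` of
#' constant darkness (DD).
#'
#' @param entrain_days Number of LD entrainment days (may be 0).
#' @param light_hours,dark_hours Photoperiod of one entrainment day, in hours.
#'   Must sum to 24.
#' @param dd_days Number of days of constant darkness appended after
#'   entrainment. Must be at least 1.
#' @param zt0_h Clock offset of lights-on within the recording, hours.
#' @return A tibble with columns `start_h`, `end_h`, `lights` (`"on"`/`"off"`)
#'   and attributes `zt0_h` and `dd_onset_h` (hours at which permanent darkness
#'   begins), of class `"light_schedule"`.
#' @examples
#' light_schedule(entrain_days = 5, light_hours = 18, dark_hours = 6, dd_days = 10)
#' @export
light_schedule <- function(entrain_days, light_hours, dark_hours, dd_days,
                           zt0_h = 0) {
  assert_scalar_num(entrain_days, "entrain_days", lower = 0)
  assert_scalar_num(dd_days, "dd_days", lower = 1)
  assert_scalar_num(light_hours, "light_hours", lower = 0, upper = 24)
  assert_scalar_num(dark_hours, "dark_hours", lower = 0, upper = 24)
  if (abs(light_hours + dark_hours - 24) > 1e-9) {
    abort("`light_hours` + `dark_hours` must equal 24")
  }
  segs <- list()
  t <- 0
  if (entrain_days > 0) {
    for (d in seq_len(entrain_days)) {
      segs[[length(segs) + 1L]] <-
        tibble::tibble(start_h = t, end_h = t + light_hours, lights = "on")
      segs[[length(segs) + 1L]] <-
        tibble::tibble(start_h = t + light_hours, end_h = t + 24, lights = "off")
      t <- t + 24
    }
  }
  dd_onset <- t
  segs[[length(segs) + 1L]] <-
    tibble::tibble(start_h = t, end_h = t + 24 * dd_days, lights = "off")
  out <- dplyr::bind_rows(segs)
  ## merge the final entrainment night into the DD block boundary is not
  ## needed: segments stay contiguous and non-overlapping by construction
  structure(out,
    zt0_h = zt0_h,
    dd_onset_h = dd_onset,
    class = c("light_schedule", class(out))
  )
}

#' Hour at which constant darkness begins
#'
#' @param schedule A [light_schedule()].
#' @return Hours since recording start at which the final, permanent dark
#'   segment begins.
#' @export
dd_onset <- function(schedule) {
  on_h <- attr(schedule, "dd_onset_h")
  if (is.null(on_h)) {
    ## infer: start of the last "off" segment that runs to the end
    off <- schedule[schedule$lights == "off", , drop = FALSE]
    if (nrow(off) == 0L) abort("schedule contains no dark segment")
    on_h <- max(off$start_h[off$end_h >= max(schedule$end_h) - 1e-9])
  }
  on_h
}

schedule_span_h <- function(schedule) max(schedule$end_h)

## TRUE for times that fall in the permanent-dark (DD) block
in_dd <- function(schedule, time_h) time_h >= dd_onset(schedule) - 1e-9
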