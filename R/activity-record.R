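#' Construct an activity record
#'
#' The package's central currency: one animal's locomotor activity as counts
#' per time bin. The record is a tibble with columns `time_h` (hours since the
#' start of the recording, at the bin start, strictly increasing) and `count`
#' (non-negative integer events/beam-breaks per bin; `NA` marks a missing bin
#' -- a zero is meaningful activity data and is never used for missingness).
#'
#' @param counts Integer vector of per-bin counts; `NA` = missing bin.
#' @param bin_seconds Bin width in seconds (default 300 s = 5-minute frames).
#' @param schedule A [light_schedule()] covering the recording span.
#' @param animal_id Identifier string.
#' @param species Free-text species tag.
#' @param t0 Optional absolute start timestamp (`POSIXct`), kept as metadata.
#' @return A tibble of class `"activity_record"` with attributes `animal_id`,
#'   `bin_seconds`, `schedule`, `species`, `t0`.
#' @export
activity_record <- function(counts, bin_seconds = 300, schedule = NULL,
                            animal_id = "animal", species = "", t0 = NULL) {
  if (length(counts) < 1L) abort("`counts` must have length >= 1")
  if (any(counts < 0, na.rm = TRUE)) abort("counts must be non-negative")
  assert_scalar_num(bin_seconds, "bin_seconds", lower = 0, strict_lower = TRUE)
  time_h <- (seq_along(counts) - 1L) * bin_seconds / 3600
  out <- tibble::tibble(time_h = time_h, count = as.numeric(counts))
  structure(out,
    animal_id = as.character(animal_id),
    bin_seconds = bin_seconds,
    schedule = schedule,
    species = as.character(species),
    t0 = t0,
    class = c("activity_record", class(out))
  )
}

record_schedule <- function(record) {
  sch <- attr(record, "schedule")
  if (is.null(sch)) abort("activity record carries no light schedule")
  sch
}

record_bin_seconds <- function(record) {
  bs <- attr(record, "bin_seconds")
  if (is.null(bs)) abort("activity record carries no bin width")
  bs
}

#' Number of missing bins in an activity record
#' @param record An [activity_record()].
#' @return Integer count of `NA` bins.
#' @export
n_missing_bins <- function(record) sum(is.na(record$count))

#' @export
print.activity_record <- function(x, ...) {
  cat(sprintf(
    "<activity_record> %s%s: %d bins of %gs, %d missing\n",
    attr(x, "animal_id"),
    if (nzchar(attr(x, "species") %||% "")) paste0(" (", attr(x, "species"), ")") else "",
    nrow(x), attr(x, "bin_seconds"), n_missing_bins(x)
  ))
  NextMethod()
}

#' Write / read an activity table
#'
#' Lossless CSV round-trip for activity records: columns `animal_id`, `time_h`,
#' `count` (empty cell = missing bin), one row per bin, plus a header comment
#' line carrying the bin width. Several records may share one file.
#'
#' @param records An [activity_record()] or list of them.
#' @param path Output CSV path.
#' @return `write_activity_table()` returns `path` invisibly;
#'   `read_activity_table()` returns a list of activity records.
#' @export
write_activity_table <- function(records, path) {
  if (inherits(records, "activity_record")) records <- list(records)
  rows <- purrr::map_dfr(records, function(r) {
    tibble::tibble(
      animal_id = attr(r, "animal_id"),
      species = attr(r, "species") %||% "",
      bin_seconds = attr(r, "bin_seconds"),
      time_h = r$time_h,
      count = r$count
    )
  })
  readr::write_csv(rows, path, na = "")
  invisible(path)
}

#' @param schedule Optional [light_schedule()] attached to every record read.
#' @rdname write_activity_table
#' @export
read_activity_table <- function(path, schedule = NULL) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, na = "")
  needed <- c("animal_id", "bin_seconds", "time_h", "count")
  if (!all(needed %in% names(tbl))) {
    abort("activity table must have columns animal_id, bin_seconds, time_h, count")
  }
  split(tbl, tbl$animal_id) |>
    purrr::map(function(d) {
      d <- dplyr::arrange(d, .data$time_h)
      activity_record(
        counts = d$count,
        bin_seconds = d$bin_seconds[[1]],
        schedule = schedule,
        animal_id = d$animal_id[[1]],
        species = if ("species" %in% names(d) && !is.na(d$species[[1]])) {
          as.character(d$species[[1]])
        } else {
          ""
        }
      )
    }) |>
    unname()
}
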