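#' Read a beam-break locomotor monitor file
#'
#' Parses the de facto standard tab-delimited monitor dialect used by DAM/LAM
#' family beam-break instruments: one row per reading with columns
#' `index, date (DD Mon YY), time (HH:MM:SS), status, 6 auxiliary columns,`
#' then 32 per-channel count columns. Status `1` means a valid reading; rows
#' with any other status are kept in the time base but their counts are marked
#' missing (never zero -- zeros are real data). The bin width is inferred from
#' consecutive timestamps. The exact column layout is an assumption of this
#' reader (the instrument vendor does not publish a formal schema) and is
#' documented here.
#'
#' @param path Monitor text file.
#' @param channel_ids Integer channels to extract, each in 1..32.
#' @param schedule Optional [light_schedule()] attached to each record.
#' @param species Species tag attached to each record.
#' @return A list of [activity_record()]s, one per requested channel, named
#'   `ch<k>`.
#' @export
read_monitor_file <- function(path, channel_ids, schedule = NULL, species = "") {
  if (!file.exists(path)) abort(sprintf("monitor file not found: %s", path))
  channel_ids <- as.integer(channel_ids)
  if (any(channel_ids < 1L | channel_ids > 32L)) {
    abort("`channel_ids` must lie in 1..32")
  }
  lines <- readr::read_lines(path)
  lines <- sub("\r$", "", lines)        # tolerate CRLF dialects
  lines <- lines[nzchar(trimws(lines))] # tolerate trailing blank lines
  if (length(lines) == 0L) abort("monitor file is empty")

  parts <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- 10L + 32L
  ts <- numeric(length(parts))
  status <- integer(length(parts))
  counts <- matrix(NA_real_, nrow = length(parts), ncol = 32L)
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    if (length(p) != n_col) {
      abort(sprintf(
        "line %d: expected %d tab-separated fields, found %d", i, n_col, length(p)
      ))
    }
    tm <- as.POSIXct(paste(p[2], p[3]), format = "%d %b %y %H:%M:%S", tz = "UTC")
    st <- suppressWarnings(as.integer(p[4]))
    cn <- suppressWarnings(as.numeric(p[11:42]))
    if (is.na(tm) || is.na(st) || anyNA(cn)) {
      abort(sprintf("line %d: unparseable row", i))
    }
    if (any(cn < 0)) abort(sprintf("line %d: negative count", i))
    ts[i] <- as.numeric(tm)
    status[i] <- st
    counts[i, ] <- cn
  }
  if (any(diff(ts) <= 0)) abort("non-monotone timestamps in monitor file")

  bin_seconds <- if (length(ts) > 1L) median(diff(ts)) else 300
  bad <- status != 1L
  t0 <- as.POSIXct(ts[1], origin = "1970-01-01", tz = "UTC")

  lapply(channel_ids, function(ch) {
    cnt <- counts[, ch]
    cnt[bad] <- NA_real_
    rec <- activity_record(
      counts = cnt, bin_seconds = bin_seconds, schedule = schedule,
      animal_id = sprintf("ch%d", ch), species = species, t0 = t0
    )
    rec
  }) |> stats::setNames(sprintf("ch%d", channel_ids))
}
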