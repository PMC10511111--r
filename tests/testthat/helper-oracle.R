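# Independent reference implementation of the classical normalized
# Lomb-Scargle periodogram: a direct scalar-sum transliteration of the
# defining formula, deliberately kept separate from the package's vectorised
# code path so the two can be compared.
oracle_pn <- function(times_h, x, periods_h) {
  n <- length(x)
  xbar <- mean(x)
  s2 <- sum((x - xbar)^2) / (n - 1)
  vapply(periods_h, function(p) {
    w <- 2 * pi / p
    theta <- atan2(
      sum(sin(2 * w * times_h)),
      sum(cos(2 * w * times_h))
    ) / (2 * w)
    ct <- st <- cc <- ss <- 0
    for (i in seq_len(n)) {
      a <- w * (times_h[i] - theta)
      ct <- ct + (x[i] - xbar) * cos(a)
      st <- st + (x[i] - xbar) * sin(a)
      cc <- cc + cos(a)^2
      ss <- ss + sin(a)^2
    }
    (ct^2 / cc + st^2 / ss) / (2 * s2)
  }, numeric(1))
}

# Tab-delimited monitor fixture in the standard 42-column dialect:
# index, date, time, status, 6 auxiliary columns, 32 channel counts.
write_monitor_fixture <- function(path, times, counts_ch1, status = NULL,
                                  counts_other = 0, eol = "\n") {
  n <- length(times)
  status <- status %||% rep(1L, n)
  rows <- vapply(seq_len(n), function(i) {
    counts <- rep(counts_other, 32)
    counts[1] <- counts_ch1[i]
    paste(c(
      i,
      format(times[i], "%d %b %y"),
      format(times[i], "%H:%M:%S"),
      status[i],
      rep(0, 6),
      counts
    ), collapse = "\t")
  }, character(1))
  writeLines(rows, path, sep = eol)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Noise-free sinusoidal series sampled every 5 minutes.
sine_series <- function(period_h, days = 10, bin_h = 1 / 12, amp = 1,
                        mean_level = 5) {
  time_h <- seq(0, days * 24 - bin_h, by = bin_h)
  tibble::tibble(
    time_h = time_h,
    count = mean_level + amp * sin(2 * pi * time_h / period_h)
  )
}

# A group vector with exact mean m and exact sample SD s.
exact_group <- function(n, m, s) {
  base <- seq_len(n)
  base <- base - mean(base)
  base <- base / sd(base)
  m + s * base
}
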