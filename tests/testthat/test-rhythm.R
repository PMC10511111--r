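test_that("segment_dd returns exactly the DD bins under both window conventions", {
  sch <- light_schedule(5, 18, 6, dd_days = 10)
  rec <- activity_record(rep(1:3, length.out = 15 * 288),
    bin_seconds = 300,
    schedule = sch
  )
  dd <- segment_dd(rec)
  expect_equal(nrow(dd), 10 * 288)
  expect_true(all(dd$time_h >= 0))

  ## day labels "1-7" mean the first seven DD days
  expect_equal(nrow(segment_dd(rec, c(1, 7), convention = "label")), 7 * 288)
  ## offset convention: [1, 7) days after DD onset
  expect_equal(nrow(segment_dd(rec, c(1, 7), convention = "offset")), 6 * 288)

  ## missing bins are excluded from the sample set
  counts <- rep(1:3, length.out = 15 * 288)
  counts[5 * 288 + 1:10] <- NA
  rec_na <- activity_record(counts, bin_seconds = 300, schedule = sch)
  expect_equal(nrow(segment_dd(rec_na)), 10 * 288 - 10)

  ## a single labelled day is one day of samples; a reversed window is empty
  expect_equal(nrow(segment_dd(rec, c(4, 4), convention = "label")), 288)
  expect_error(segment_dd(rec, c(5, 3)), "empty")
})

test_that("the periodogram matches an independent direct-sum reference to 1e-8", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(30:60, 1)
    t <- sort(stats::runif(n, 0, 120))
    x <- stats::rnorm(n) + sin(2 * pi * t / stats::runif(1, 18, 30))
    periods <- seq(16, 35, by = 0.9)
    pg <- lomb_scargle(tibble::tibble(time_h = t, count = x), periods = periods)
    ref <- oracle_pn(t, x, periods)
    expect_lt(max(abs(pg$grid$power - ref) / pmax(ref, 1e-12)), 1e-8)
  }
})

test_that("a noiseless sinusoid is recovered at its period", {
  d <- sine_series(24, days = 10)
  pg <- lomb_scargle(d)
  step <- max(diff(pg$grid$period_h[abs(pg$grid$period_h - 24) < 1]))
  expect_lt(abs(pg$grid$period_h[which.max(pg$grid$power)] - 24), step + 1e-9)
})

test_that("powers are invariant to rescaling the values", {
  d <- sine_series(25, days = 8)
  d$count <- d$count + stats::rnorm(nrow(d), sd = 0.3)
  pg1 <- lomb_scargle(d)
  d2 <- d
  d2$count <- d2$count * 37.5
  pg2 <- lomb_scargle(d2)
  expect_equal(pg1$grid$power, pg2$grid$power, tolerance = 1e-12)
})

test_that("a single fixed frequency's null power is Exponential(1)", {
  nrep <- 2000
  t <- (0:575) / 12
  x <- withr::with_seed(99, matrix(stats::rnorm(576 * nrep), nrow = 576))
  pn <- freerun:::ls_power_matrix(t, x, 1 / 24.7)[1, ]
  ks <- stats::ks.test(pn, stats::pexp)
  expect_gt(ks$p.value, 0.01)
})

test_that("the significance threshold inverts the extreme-value formula", {
  ## with M = 1 the threshold inverts a single exponential tail
  expect_equal(ls_significance_threshold(1, alpha = 1 - (1 - exp(-5))), 5)
  expect_equal(ls_significance_threshold(500, 0.01), 10.8157, tolerance = 1e-4)
  expect_lt(ls_significance_threshold(1, 1 - 1e-12), 1e-10)
})

test_that("white-noise records rarely show a significant peak at alpha 0.01", {
  nrep <- 400
  t <- (0:2879) / 12
  hits <- purrr::map_lgl(seq_len(nrep), function(i) {
    cnt <- withr::with_seed(5000 + i, stats::rpois(2880, 3))
    pg <- lomb_scargle(tibble::tibble(time_h = t, count = cnt))
    max(pg$grid$power) >= pg$z_alpha
  })
  expect_lte(mean(hits), 0.015 + 3 * sqrt(0.015 * 0.985 / nrep))
})

test_that("peak detection separates true components and suppresses harmonics", {
  ## one clean sinusoid: exactly one component
  pg1 <- lomb_scargle(sine_series(24, days = 10))
  pk1 <- detect_peaks(pg1)
  expect_equal(sum(pk1$distinct_component), 1L)

  ## two well-separated strong components over 20 days: two components
  t <- seq(0, 20 * 24 - 1 / 12, by = 1 / 12)
  d2 <- tibble::tibble(
    time_h = t,
    count = 5 + sin(2 * pi * t / 24) + sin(2 * pi * t / 27)
  )
  pk2 <- detect_peaks(lomb_scargle(d2))
  expect_equal(sum(pk2$distinct_component), 2L)
  expect_equal(sort(pk2$period_h[pk2$distinct_component]), c(24, 27),
    tolerance = 0.02
  )

  ## a sharp waveform has a strong 12-h harmonic: still one component
  spec <- sim_spec(
    tau_hours = 24, entrain_days = 0, dd_days = 10,
    concentration_kappa = 6
  )
  d3 <- tibble::tibble(time_h = t[t < 240], count = sim_rate(spec, t[t < 240]))
  pg3 <- lomb_scargle(d3, period_range = c(8, 30))
  pk3 <- detect_peaks(pg3)
  expect_gt(max(pk3$power[abs(pk3$period_h - 12) < 1], 0), pg3$z_alpha)
  expect_equal(sum(pk3$distinct_component), 1L)
})

test_that("parabolic interpolation refines the period below the grid step", {
  d <- sine_series(24.05, days = 10)
  pg <- lomb_scargle(d, periods = seq(20, 28, by = 0.1))
  expect_lt(abs(estimate_tau(pg) - 24.05), 0.02)

  ## peak exactly on a symmetric grid point returns the grid value
  dsym <- sine_series(24, days = 10)
  pgsym <- lomb_scargle(dsym, periods = seq(23, 25, by = 0.05))
  expect_equal(estimate_tau(pgsym), 24, tolerance = 1e-3)

  ## peak at the grid boundary: no interpolation, warning
  pgb <- lomb_scargle(d, periods = seq(24.1, 30, by = 0.1))
  expect_warning(tau_b <- estimate_tau(pgb), "boundary")
  expect_equal(tau_b, 24.1)
})

test_that("period stability flags drifting rhythms but not stationary ones", {
  d <- sine_series(24, days = 10)
  d$count <- d$count + withr::with_seed(3, stats::rnorm(nrow(d), sd = 0.1))
  st <- period_stability(d)
  expect_false(st$low_coverage)
  expect_lt(st$range_h, 0.3)

  spec <- sim_spec(
    phenotype = "complex_drifting", tau_hours = 24,
    drift_hours_per_day = 0.3, entrain_days = 0, dd_days = 10
  )
  t <- seq(0, 240 - 1 / 12, by = 1 / 12)
  dd <- tibble::tibble(time_h = t, count = sim_rate(spec, t))
  st_drift <- period_stability(dd)
  expect_gte(st_drift$range_h, 1.0)

  short <- period_stability(sine_series(24, days = 4))
  expect_true(short$low_coverage)
  expect_equal(short$range_h, 0)
})

test_that("classification honours the PN floor and the component count", {
  d <- sine_series(24, days = 10)
  pg <- lomb_scargle(d)
  peaks <- detect_peaks(pg)

  ## synthetic peak tables at the documented boundary
  fake_pg <- pg
  mk_peaks <- function(powers, periods) {
    tibble::tibble(
      period_h = periods, power = powers,
      p_value = freerun:::ls_p_value(powers, pg$M),
      is_primary = powers == max(powers),
      significant = powers >= pg$z_alpha,
      distinct_component = powers >= pg$z_alpha
    )
  }
  below <- classify_rhythmicity(mk_peaks(19.9, 24), 0.2, fake_pg)
  expect_equal(below$classification, "arrhythmic")
  expect_true(is.na(below$tau_hours))

  at_floor <- classify_rhythmicity(mk_peaks(20.0, 24), 0.2, fake_pg)
  expect_equal(at_floor$classification, "strong")

  two <- classify_rhythmicity(mk_peaks(c(35, 30), c(24, 27.5)), 0.2, fake_pg)
  expect_equal(two$classification, "complex")

  unstable <- classify_rhythmicity(mk_peaks(35, 24), 1.7, fake_pg)
  expect_equal(unstable$classification, "complex")
})

test_that("strong synthetic rhythms are recovered across the circadian range", {
  taus <- c(20, 23.33, 24, 26, 28.63, 30)
  calls <- purrr::map_dfr(taus, function(tt) {
    purrr::map_dfr(1:5, function(i) {
      spec <- sim_spec(
        tau_hours = tt, baseline_rate = 1, amplitude = 5,
        seed = freerun:::derive_seed(7, "recovery", round(tt * 100) + i)
      )
      cbind(true_tau = tt, analyze_record(simulate_activity_record(spec)))
    })
  })
  expect_gte(mean(calls$classification == "strong"), 0.90)
  err <- abs(calls$tau_hours - calls$true_tau)
  expect_lte(median(err, na.rm = TRUE), 0.15)
})

test_that("relaxing alpha never turns a rhythmic call arrhythmic", {
  rec <- simulate_activity_record(sim_spec(tau_hours = 25, seed = 55))
  cls <- purrr::map_chr(
    c(0.001, 0.01, 0.05),
    ~ analyze_record(rec, alpha = .x)$classification
  )
  expect_false(any(cls == "arrhythmic"))
  ## under the three-class rule a stable single-peak rhythm stays strong
  expect_true(all(cls == "strong"))
})

test_that("actograms double-plot every row", {
  sch <- light_schedule(5, 18, 6, dd_days = 5)
  rec <- simulate_activity_record(sim_spec(tau_hours = 27, dd_days = 5, seed = 2))
  act <- build_actogram(rec)
  expect_equal(dim(act$matrix), c(10, 2 * 288))
  for (r in seq_len(nrow(act$matrix) - 1)) {
    expect_identical(
      act$matrix[r, 289:576],
      act$matrix[r + 1, 1:288]
    )
  }
  ## light overlay marks the entrained days only
  expect_true(any(act$light[1, 1:288]))
  expect_false(any(act$light[6:10, 1:288]))

  zero <- build_actogram(activity_record(rep(0, 10 * 288), schedule = sch))
  expect_true(all(zero$matrix == 0, na.rm = TRUE))

  ## appending a bin never breaks the double-plot property
  rec2 <- activity_record(c(rec$count, 4), schedule = attr(rec, "schedule"))
  act2 <- build_actogram(rec2)
  expect_identical(act2$matrix[1, 289:576], act2$matrix[2, 1:288])
})

test_that("tidy, glance and autoplot expose the periodogram", {
  pg <- lomb_scargle(sine_series(24, days = 10))
  td <- tidy(pg)
  expect_named(td, c("period_h", "power", "significant"))
  gl <- glance(pg)
  expect_equal(gl$peak_period_h, 24, tolerance = 0.3)
  expect_s3_class(autoplot(pg), "ggplot")
  expect_s3_class(autoplot(build_actogram(
    simulate_activity_record(sim_spec(dd_days = 2, seed = 1))
  )), "ggplot")
})
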