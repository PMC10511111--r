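test_that("simulation is deterministic given a seed", {
  spec <- sim_spec(tau_hours = 25, seed = 11)
  r1 <- simulate_activity_record(spec)
  r2 <- simulate_activity_record(spec)
  expect_identical(r1$count, r2$count)

  specs <- list(a = sim_spec(tau_hours = 24), b = sim_spec(tau_hours = 28))
  c1 <- simulate_cohort(specs, n_per_group = 3, seed = 5)
  c2 <- simulate_cohort(specs, n_per_group = 3, seed = 5)
  expect_identical(
    purrr::map(c1$record, "count"),
    purrr::map(c2$record, "count")
  )
})

test_that("cohort structure: sizes, labels, insertion stability", {
  specs <- list(ctrl = sim_spec(tau_hours = 24), trt = sim_spec(tau_hours = 28))
  expect_equal(nrow(simulate_cohort(specs, 0, seed = 1)), 0L)
  co <- simulate_cohort(specs, 20, seed = 1)
  expect_equal(nrow(co), 40L)
  expect_equal(unname(table(co$group)[c("ctrl", "trt")]), c(20L, 20L),
    ignore_attr = TRUE
  )
  ## animal 1's record must not change when the cohort grows
  small <- simulate_cohort(specs, 2, seed = 1)
  expect_identical(small$record[[1]]$count, co$record[[1]]$count)
})

test_that("empirical DD mean rate matches the analytic mean of the rate model", {
  spec <- sim_spec(tau_hours = 24, entrain_days = 5, dd_days = 10,
    light_hours = 18, dark_hours = 6, seed = 21
  )
  rec <- simulate_activity_record(spec)
  dd_idx <- rec$time_h >= 5 * 24
  mid <- rec$time_h[dd_idx] + spec$bin_seconds / 7200
  lam <- sim_rate(spec, mid)
  n <- sum(dd_idx)
  se <- sqrt(mean(lam) / n)
  expect_lt(abs(mean(rec$count[dd_idx]) - mean(lam)), 3 * se)
})

test_that("the rate model is continuous at the LD-to-DD transition", {
  for (ph in c("strong", "complex_two_component", "complex_drifting", "arrhythmic")) {
    spec <- sim_spec(
      phenotype = ph, tau_hours = 27, tau2_hours = 23,
      entrain_days = 5, dd_days = 5
    )
    t_dd <- 5 * 24
    eps <- 1e-7
    expect_equal(
      sim_rate(spec, t_dd - eps), sim_rate(spec, t_dd + eps),
      tolerance = 1e-4
    )
  }
})

test_that("in the sharp-peak noiseless limit activity peaks are spaced tau apart", {
  spec <- sim_spec(
    tau_hours = 26, entrain_days = 0, dd_days = 10,
    concentration_kappa = 60
  )
  tt <- seq(0, 10 * 24, by = 1 / 60)
  lam <- sim_rate(spec, tt)
  ## one argmax per cycle
  peaks <- tt[which(diff(sign(diff(lam))) == -2) + 1L]
  spacing <- diff(peaks)
  expect_true(all(abs(spacing - 26) < 0.05))
})

test_that("a flat rate yields arrhythmic downstream classifications", {
  specs <- purrr::map(1:40, ~ sim_spec(
    phenotype = "arrhythmic",
    baseline_rate = 1, amplitude = 5, seed = 1000 + .x
  ))
  calls <- purrr::map_chr(specs, function(sp) {
    analyze_record(simulate_activity_record(sp))$classification
  })
  expect_gte(mean(calls == "arrhythmic"), 0.95)
})

test_that("trajectories stay inside the dish and follow the step-length law", {
  arena <- arena_spec(dish_diameter_cm = 9)
  spec <- sim_spec(
    tau_hours = 24, entrain_days = 0, dd_days = 14,
    baseline_rate = 1e-9, amplitude = 0, seed = 31
  )
  tr <- simulate_trajectory(spec, arena)
  expect_true(all(sqrt(tr$x_cm^2 + tr$y_cm^2) <= 9 / 2 + 1e-9))
  ## pure jitter: P(step > 1 cm) = exp(-1 / 0.2)
  disp <- sqrt(diff(tr$x_cm)^2 + diff(tr$y_cm)^2)
  expect_lt(abs(mean(disp > 1) - exp(-1 / 0.2)), 0.006)

  ## always active, huge dish: P(step > 1 cm) = exp(-1 / 2.5)
  big <- arena_spec(dish_diameter_cm = 500)
  spec2 <- sim_spec(
    tau_hours = 24, entrain_days = 0, dd_days = 2,
    baseline_rate = 2, amplitude = 0, seed = 32
  )
  tr2 <- simulate_trajectory(spec2, big)
  disp2 <- sqrt(diff(tr2$x_cm)^2 + diff(tr2$y_cm)^2)
  expect_lt(abs(mean(disp2 > 1) - exp(-1 / 2.5)), 0.07)
})

test_that("rendered frames carry the animal at its true position", {
  arena <- arena_spec(noise_sd = 0)
  spec <- sim_spec(
    tau_hours = 24, entrain_days = 0, dd_days = 1,
    baseline_rate = 1e-9, amplitude = 0, seed = 41
  )
  tr <- simulate_trajectory(spec, arena)
  tr_static <- tr[1:5, ]
  tr_static$x_cm <- tr_static$x_cm * 0 + 1.23
  tr_static$y_cm <- tr_static$y_cm * 0 - 0.77
  attr(tr_static, "frame_interval_seconds") <- 300
  class(tr_static) <- class(tr)
  rf <- render_frames(tr_static, arena, seed = 1)
  ## noise-free static animal: all frames identical
  expect_identical(rf$frames$frames[[1]], rf$frames$frames[[5]])
  ## centroid of the rendered disc lands within 0.5 px of the true position
  img <- rf$frames$frames[[1]]
  fg <- img < 150
  ctr_row <- mean(row(img)[rf$mask$labels == 1])
  ctr_col <- mean(col(img)[rf$mask$labels == 1])
  cx <- (mean(col(img)[fg]) - ctr_col) * arena$pixel_scale_cm
  cy <- (mean(row(img)[fg]) - ctr_row) * arena$pixel_scale_cm
  expect_lt(abs(cx - 1.23), 0.5 * arena$pixel_scale_cm)
  expect_lt(abs(cy - (-0.77)), 0.5 * arena$pixel_scale_cm)
})

test_that("a parallel arena renders one mask label per dish", {
  arena <- arena_spec(n_dishes = 47, pixel_scale_cm = 0.15, noise_sd = 0)
  spec <- sim_spec(
    tau_hours = 24, entrain_days = 0, dd_days = 1,
    baseline_rate = 1e-9, amplitude = 0
  )
  tracks <- purrr::map(1:47, function(k) {
    sp <- spec
    sp$seed <- k
    tr <- simulate_trajectory(sp, arena, dish_id = k)
    tr2 <- tr[1:2, ]
    attr(tr2, "frame_interval_seconds") <- 300
    class(tr2) <- class(tr)
    tr2
  })
  rf <- render_frames(tracks, arena, seed = 2)
  expect_equal(rf$mask$n_dishes, 47L)
  expect_equal(sort(unique(as.vector(rf$mask$labels[rf$mask$labels > 0]))), 1:47)
})
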