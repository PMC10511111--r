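tau_tbl <- function(...) {
  groups <- list(...)
  purrr::imap_dfr(groups, function(v, g) {
    tibble::tibble(
      animal_id = sprintf("%s_%d", g, seq_along(v)),
      treatment_group = g, tau_hours = v
    )
  })
}

test_that("group summaries compute mean and SEM with the n-1 denominator", {
  sm <- summarize_groups(tau_tbl(a = c(24, 24, 24), b = c(23, 25), c = 26))
  expect_equal(sm$mean_tau[sm$treatment_group == "a"], 24)
  expect_equal(sm$sem[sm$treatment_group == "a"], 0)
  expect_equal(sm$mean_tau[sm$treatment_group == "b"], 24)
  expect_equal(sm$sem[sm$treatment_group == "b"], 1) # SD = sqrt(2), n = 2
  expect_false(sm$sem_defined[sm$treatment_group == "c"])
})

test_that("the unpaired t-test is Student's pooled form with df = n1 + n2 - 2", {
  tt <- t_test_unpaired(tau_tbl(g1 = c(1, 2, 3), g2 = c(2, 3, 4)), "g1", "g2")
  expect_equal(abs(tt$statistic), 1.2247, tolerance = 1e-4)
  expect_equal(tt$df, 4)

  same <- t_test_unpaired(tau_tbl(a = c(24, 25, 26), b = c(24, 25, 26)), "a", "b")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  const_eq <- t_test_unpaired(tau_tbl(a = c(24, 24), b = c(24, 24)), "a", "b")
  expect_equal(const_eq$p_value, 1)
  expect_error(
    t_test_unpaired(tau_tbl(a = c(24, 24), b = c(25, 25)), "a", "b"),
    "zero pooled variance"
  )
  expect_error(t_test_unpaired(tau_tbl(a = 24, b = c(25, 26)), "a", "b"), "n >= 2")
})

test_that("one-way ANOVA matches a brute-force sum-of-squares oracle", {
  tbl <- tau_tbl(
    a = c(23.1, 24.2, 23.7, 24.9),
    b = c(25.0, 25.8, 24.6),
    c = c(27.3, 26.1, 26.9, 28.0, 27.5)
  )
  an <- one_way_anova(tbl)
  ## oracle: explicit between/within sums of squares
  y <- tbl$tau_hours
  g <- tbl$treatment_group
  gm <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  ss_b <- sum(ns * (gm - mean(y))^2)
  ss_w <- sum((y - gm[g])^2)
  f_oracle <- (ss_b / (length(gm) - 1)) / (ss_w / (length(y) - length(gm)))
  expect_equal(an$statistic, f_oracle, tolerance = 1e-10)
  expect_equal(an$df1, 2)
  expect_equal(an$df2, 9)
  expect_equal(an$p_value, stats::pf(f_oracle, 2, 9, lower.tail = FALSE),
    tolerance = 1e-12
  )
})

test_that("ANOVA F is shift invariant, scale invariant and flags degeneracy", {
  tbl <- tau_tbl(a = c(23, 24, 25), b = c(26, 27, 29))
  f0 <- one_way_anova(tbl)$statistic
  shifted <- tbl
  shifted$tau_hours <- shifted$tau_hours + 100
  scaled <- tbl
  scaled$tau_hours <- scaled$tau_hours * 3.5
  expect_equal(one_way_anova(shifted)$statistic, f0, tolerance = 1e-10)
  expect_equal(one_way_anova(scaled)$statistic, f0, tolerance = 1e-10)

  degen <- one_way_anova(tau_tbl(a = c(24, 24), b = c(26, 26)))
  expect_true(degen$degenerate)
  expect_equal(degen$statistic, Inf)
})

test_that("with two groups the ANOVA p equals the t-test p and F = t^2", {
  tbl <- tau_tbl(a = c(23.3, 24.1, 23.9, 24.6), b = c(25.2, 24.8, 26.0))
  an <- one_way_anova(tbl)
  tt <- t_test_unpaired(tbl, "a", "b")
  expect_equal(an$statistic, tt$statistic^2, tolerance = 1e-10)
  expect_equal(an$p_value, tt$p_value, tolerance = 1e-10)
})

test_that("Dunnett reduces to the plain comparison for a family of one", {
  tbl <- tau_tbl(ctrl = c(23.5, 24.2, 24.8, 23.9), trt = c(25.1, 26.2, 25.6, 24.9))
  dn <- dunnett_test(tbl, "ctrl", seed = 4)
  raw_p <- 2 * stats::pt(-abs(dn$statistic), df = dn$df)
  expect_equal(dn$p_adjusted, raw_p, tolerance = 5e-4)
  expect_lt(dn$mc_se, 1e-3)
})

test_that("Dunnett adjusted p never falls below the unadjusted p and grows with the family", {
  set.seed(12)
  for (i in 1:10) {
    tbl <- tau_tbl(
      ctrl = rnorm(6, 24), t1 = rnorm(5, 24.5),
      t2 = rnorm(7, 25), t3 = rnorm(4, 24)
    )
    dn <- dunnett_test(tbl, "ctrl", seed = i)
    raw_p <- 2 * stats::pt(-abs(dn$statistic), df = dn$df)
    expect_true(all(dn$p_adjusted >= raw_p - 2e-3))
  }
  ## identical treatment vs control: p grows as more groups join the family
  base <- list(ctrl = c(23.8, 24.1, 24.4, 23.9), t1 = c(23.9, 24.2, 24.3, 24.0))
  p1 <- dunnett_test(do.call(tau_tbl, base), "ctrl", seed = 3)$p_adjusted[1]
  base$t2 <- c(25, 26, 25.5, 24.7)
  base$t3 <- c(22.9, 23.5, 23.1, 23.8)
  d3 <- dunnett_test(do.call(tau_tbl, base), "ctrl", seed = 3)
  p3 <- d3$p_adjusted[d3$comparison == "t1 vs ctrl"]
  expect_gt(p3, p1)
})

test_that("Dunnett agrees with an independent implementation", {
  skip_if_not_installed("multcomp")
  tbl <- tau_tbl(
    ctrl = c(23.2, 24.0, 24.5, 23.8, 24.3),
    t1 = c(25.1, 25.9, 24.8, 25.5),
    t2 = c(24.1, 24.4, 23.9, 24.6, 24.0, 24.8)
  )
  dn <- dunnett_test(tbl, "ctrl", seed = 2, maxpts = 5e5)
  fit <- stats::aov(tau_hours ~ treatment_group,
    data = transform(tbl, treatment_group = stats::relevel(factor(treatment_group), "ctrl"))
  )
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(treatment_group = "Dunnett"))
  ref <- summary(gl, test = multcomp::adjusted("free")) # same max-|T| family
  ref_p <- summary(gl)$test$pvalues
  expect_equal(sort(dn$p_adjusted), sort(as.numeric(ref_p)), tolerance = 5e-3)
})

test_that("the family-wise error of Dunnett under the null is near nominal", {
  nrep <- 1500
  hits <- withr::with_seed(31, {
    purrr::map_lgl(seq_len(nrep), function(i) {
      tbl <- tau_tbl(
        ctrl = rnorm(8, 24, 0.8), t1 = rnorm(8, 24, 0.8),
        t2 = rnorm(8, 24, 0.8)
      )
      dn <- dunnett_test(tbl, "ctrl", seed = i, maxpts = 4000)
      any(dn$p_adjusted < 0.05)
    })
  })
  expect_lt(abs(mean(hits) - 0.05), 0.02)
})
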