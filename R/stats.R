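#' Summarize free-running periods by treatment group
#'
#' Per-group n, mean and standard error of the mean (sample SD with the n-1
#' denominator over the square root of n). Statistics over tau are meant to be
#' computed on strongly rhythmic animals only, as the rhythm calls define them.
#'
#' @param tau_table Tibble with columns `treatment_group` and `tau_hours`
#'   (see [read_tau_table()]).
#' @return Tibble `(treatment_group, n, mean_tau, sem)`; `sem` is `NA` (and
#'   `sem_defined` is `FALSE`) for singleton groups.
#' @export
summarize_groups <- function(tau_table) {
  tau_table |>
    dplyr::group_by(.data$treatment_group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_tau = mean(.data$tau_hours),
      sem = if (dplyr::n() > 1L) sd(.data$tau_hours) / sqrt(dplyr::n()) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(sem_defined = !is.na(.data$sem))
}

#' Unpaired two-tailed Student's t-test between two groups
#'
#' Pooled-variance Student's t with df = n1 + n2 - 2 and a two-tailed p-value.
#' Zero pooled variance with equal means yields t = 0, p = 1; zero pooled
#' variance with unequal means is an error.
#'
#' @param tau_table Tibble with `treatment_group` and `tau_hours` columns.
#' @param group1,group2 The two group labels to compare.
#' @return A one-row tibble of class `"freerun_test"`: `comparison`,
#'   `statistic`, `df`, `p_value`, `method`, `adjusted`.
#' @export
t_test_unpaired <- function(tau_table, group1, group2) {
  g1 <- tau_table$tau_hours[tau_table$treatment_group == group1]
  g2 <- tau_table$tau_hours[tau_table$treatment_group == group2]
  if (length(g1) < 2L || length(g2) < 2L) abort("both groups need n >= 2")
  pooled_var <- ((length(g1) - 1) * var(g1) + (length(g2) - 1) * var(g2)) /
    (length(g1) + length(g2) - 2)
  if (pooled_var == 0) {
    if (isTRUE(all.equal(mean(g1), mean(g2)))) {
      res <- list(statistic = 0, parameter = length(g1) + length(g2) - 2, p.value = 1)
    } else {
      abort("zero pooled variance with unequal means")
    }
  } else {
    res <- stats::t.test(g1, g2, var.equal = TRUE, alternative = "two.sided")
  }
  out <- tibble::tibble(
    comparison = sprintf("%s vs %s", group1, group2),
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = res$p.value,
    method = "Student t (pooled, two-tailed)",
    adjusted = FALSE
  )
  class(out) <- c("freerun_test", class(out))
  out
}

#' One-way analysis of variance across treatment groups
#'
#' F = MS_between / MS_within on (k-1, N-k) degrees of freedom. If every group
#' is internally constant (MS_within = 0) the result is flagged degenerate,
#' with F infinite when the group means differ.
#'
#' @param tau_table Tibble with `treatment_group` and `tau_hours` columns.
#' @return A one-row tibble of class `"freerun_test"`: `comparison`,
#'   `statistic` (F), `df1`, `df2`, `p_value`, `degenerate`.
#' @export
one_way_anova <- function(tau_table) {
  grp <- factor(tau_table$treatment_group)
  if (nlevels(grp) < 2L) abort("need at least 2 groups")
  y <- tau_table$tau_hours
  k <- nlevels(grp)
  N <- length(y)
  ms_within <- sum(tapply(y, grp, function(v) sum((v - mean(v))^2))) / (N - k)
  degenerate <- ms_within == 0
  if (degenerate) {
    means_equal <- length(unique(round(tapply(y, grp, mean), 12))) == 1L
    stat <- if (means_equal) NaN else Inf
    p <- if (means_equal) NA_real_ else 0
  } else {
    an <- stats::anova(stats::lm(y ~ grp))
    stat <- an[["F value"]][1]
    p <- an[["Pr(>F)"]][1]
  }
  out <- tibble::tibble(
    comparison = paste(levels(grp), collapse = " | "),
    statistic = stat, df1 = k - 1, df2 = N - k, p_value = p,
    method = "one-way ANOVA", adjusted = FALSE, degenerate = degenerate
  )
  class(out) <- c("freerun_test", class(out))
  out
}

#' Dunnett's many-to-one comparisons against a control
#'
#' For each treatment i, \eqn{t_i = (\bar x_i - \bar x_c) /
#' \sqrt{MS_W (1/n_i + 1/n_c)}} with the ANOVA within-group mean square on
#' N - k degrees of freedom. The two-sided family-wise adjusted p-value is
#' \eqn{P(\max_j |T_j| \ge |t_i|)} under the equicorrelated multivariate-t
#' null with correlations \eqn{\rho_{ij} = \sqrt{n_i n_j} /
#' \sqrt{(n_i+n_c)(n_j+n_c)}}, evaluated by seeded quasi-Monte-Carlo
#' integration; the integration error is reported as `mc_se`.
#'
#' @param tau_table Tibble with `treatment_group` and `tau_hours` columns.
#' @param control Label of the control group (must have n >= 2).
#' @param seed Seed of the quasi-Monte-Carlo integration.
#' @param maxpts Maximum integrand evaluations (default 1e5).
#' @return A tibble of class `"freerun_test"`, one row per treatment:
#'   `comparison`, `n_i`, `n_ctrl`, `mean_diff`, `statistic`, `df`,
#'   `p_adjusted`, `mc_se`.
#' @export
dunnett_test <- function(tau_table, control, seed = 1L, maxpts = 1e5) {
  grp <- factor(tau_table$treatment_group)
  if (!control %in% levels(grp)) abort(sprintf("control group '%s' not found", control))
  y <- tau_table$tau_hours
  ns <- tapply(y, grp, length)
  if (ns[[control]] < 2L) abort("control group must have n >= 2")
  means <- tapply(y, grp, mean)
  k <- nlevels(grp)
  N <- length(y)
  df <- N - k
  ms_w <- sum(tapply(y, grp, function(v) sum((v - mean(v))^2))) / df
  if (ms_w <= 0) abort("zero within-group variance; Dunnett statistics undefined")
  treatments <- setdiff(levels(grp), control)
  n_c <- ns[[control]]
  n_t <- ns[treatments]
  t_stat <- (means[treatments] - means[[control]]) /
    sqrt(ms_w * (1 / n_t + 1 / n_c))
  ## equicorrelated multivariate-t correlation structure
  lam <- sqrt(n_t / (n_t + n_c))
  corr <- outer(lam, lam)
  diag(corr) <- 1
  p_adj <- numeric(length(treatments))
  mc_se <- numeric(length(treatments))
  for (i in seq_along(treatments)) {
    pr <- with_seed(seed, mvtnorm::pmvt(
      lower = rep(-abs(t_stat[i]), length(treatments)),
      upper = rep(abs(t_stat[i]), length(treatments)),
      df = df, corr = corr,
      algorithm = mvtnorm::GenzBretz(maxpts = maxpts, abseps = 1e-5)
    ))
    p_adj[i] <- min(1, max(0, 1 - as.numeric(pr)))
    mc_se[i] <- attr(pr, "error")
  }
  out <- tibble::tibble(
    comparison = sprintf("%s vs %s", treatments, control),
    n_i = as.integer(n_t), n_ctrl = as.integer(n_c),
    mean_diff = unname(means[treatments] - means[[control]]),
    statistic = unname(t_stat), df = df,
    p_adjusted = p_adj, mc_se = mc_se,
    method = "Dunnett (multivariate t, quasi-Monte-Carlo)",
    adjusted = TRUE
  )
  class(out) <- c("freerun_test", class(out))
  out
}

#' @export
tidy.freerun_test <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
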