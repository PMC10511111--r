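#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (usually read from a YAML file) with
#' top-level keys `mode` (`"synthetic"`, `"monitor"` or `"activity_table"`),
#' `seed`, `schedule`, `cohort` (synthetic mode), `input` (file modes),
#' `analysis` and `stats`. Unknown keys, at the top level or inside a section,
#' are rejected; parameter values are checked against the ranges their owning
#' stage enforces before any computation runs.
#'
#' @param config Named list or path to a YAML file.
#' @return The validated config, invisibly, with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is_scalar_string(config)) config <- yaml::read_yaml(config)
  known_top <- c("mode", "seed", "schedule", "cohort", "input", "analysis", "stats")
  extra <- setdiff(names(config), known_top)
  if (length(extra)) abort(sprintf("unknown config keys: %s", paste(extra, collapse = ", ")))
  config$mode <- config$mode %||% "synthetic"
  if (!config$mode %in% c("synthetic", "monitor", "activity_table")) {
    abort("mode must be synthetic, monitor or activity_table")
  }
  config$seed <- as.integer(config$seed %||% 1L)

  sch_def <- list(entrain_days = 5, light_hours = 18, dark_hours = 6, dd_days = 10)
  extra <- setdiff(names(config$schedule), names(sch_def))
  if (length(extra)) abort(sprintf("unknown schedule keys: %s", paste(extra, collapse = ", ")))
  config$schedule <- utils::modifyList(sch_def, config$schedule %||% list())

  an_def <- list(
    alpha = 0.01, pn_floor = 20, period_min = 16, period_max = 35,
    oversample = 4, dd_window = NULL, convention = "label",
    stability_tol_h = 1.0, harmonic_tol_h = 0.5, min_rel_power = 0.1
  )
  extra <- setdiff(names(config$analysis), names(an_def))
  if (length(extra)) abort(sprintf("unknown analysis keys: %s", paste(extra, collapse = ", ")))
  config$analysis <- utils::modifyList(an_def, config$analysis %||% list())
  a <- config$analysis
  assert_scalar_num(a$alpha, "alpha", lower = 0, upper = 1,
    strict_lower = TRUE, strict_upper = TRUE)
  assert_scalar_num(a$pn_floor, "pn_floor", lower = 0)
  if (a$period_min >= a$period_max) abort("period_min must be below period_max")

  st_def <- list(control = NULL, method = "dunnett")
  extra <- setdiff(names(config$stats), names(st_def))
  if (length(extra)) abort(sprintf("unknown stats keys: %s", paste(extra, collapse = ", ")))
  config$stats <- utils::modifyList(st_def, config$stats %||% list())
  if (!config$stats$method %in% c("dunnett", "ttest", "none")) {
    abort("stats method must be dunnett, ttest or none")
  }

  if (config$mode == "synthetic") {
    if (is.null(config$cohort$groups)) abort("synthetic mode needs cohort$groups")
    config$cohort$n_per_group <- config$cohort$n_per_group %||% 10L
  }
  invisible(config)
}

config_to_specs <- function(config) {
  sch <- config$schedule
  purrr::map(config$cohort$groups, function(g) {
    args <- utils::modifyList(
      list(
        entrain_days = sch$entrain_days, dd_days = sch$dd_days,
        light_hours = sch$light_hours, dark_hours = sch$dark_hours
      ),
      g
    )
    do.call(sim_spec, args)
  })
}

#' Run the full pipeline into a run directory
#'
#' Orchestrates simulate (or load) -> analyze -> stats, persisting every
#' intermediate as CSV in `out_dir` together with a manifest (config hash,
#' seed, package and R versions). Rerunning with the same config and seed
#' reproduces all numeric outputs bit for bit: every stochastic stage consumes
#' only seeds derived from the master seed keyed by stage name.
#'
#' @param config Named list or YAML path; see [validate_config()].
#' @param out_dir Output directory (created; must be empty or absent).
#' @return `out_dir`, invisibly. Files written: `cohort_truth.csv`,
#'   `rhythm_calls.csv`, `tau_table.csv`, `group_summary.csv`, `stats.csv`
#'   (unless method `"none"`), `manifest.yaml`.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  records <- switch(config$mode,
    synthetic = {
      specs <- config_to_specs(config)
      simulate_cohort(specs, config$cohort$n_per_group,
        seed = derive_seed(config$seed, "simulate")
      )
    },
    abort(sprintf("mode '%s' requires input files; use the reader functions and analyze_cohort() directly", config$mode))
  )

  truth <- dplyr::select(records, -"record")
  write_results(truth, file.path(out_dir, "cohort_truth.csv"))

  a <- config$analysis
  calls <- analyze_cohort(records,
    window_days = a$dd_window, convention = a$convention,
    period_range = c(a$period_min, a$period_max), oversample = a$oversample,
    alpha = a$alpha, pn_floor = a$pn_floor,
    harmonic_tol_h = a$harmonic_tol_h, min_rel_power = a$min_rel_power,
    stability_tol_h = a$stability_tol_h
  )
  write_results(
    dplyr::select(calls, -"peaks"),
    file.path(out_dir, "rhythm_calls.csv")
  )

  ## tau statistics on strongly rhythmic animals only
  tau_tbl <- calls |>
    dplyr::filter(.data$classification == "strong") |>
    dplyr::transmute(
      animal_id = .data$animal_id,
      treatment_group = .data$group,
      tau_hours = .data$tau_hours
    )
  write_results(tau_tbl, file.path(out_dir, "tau_table.csv"))
  write_results(summarize_groups(tau_tbl), file.path(out_dir, "group_summary.csv"))

  if (config$stats$method != "none" && nrow(tau_tbl) > 0) {
    ctrl <- config$stats$control %||% unique(records$group)[[1]]
    present <- unique(tau_tbl$treatment_group)
    st <- NULL
    if (ctrl %in% present && length(present) >= 2L &&
      sum(tau_tbl$treatment_group == ctrl) >= 2L) {
      st <- switch(config$stats$method,
        dunnett = dunnett_test(tau_tbl, ctrl,
          seed = derive_seed(config$seed, "dunnett")
        ),
        ttest = {
          other <- setdiff(present, ctrl)
          purrr::map_dfr(other, ~ t_test_unpaired(tau_tbl, ctrl, .x))
        }
      )
    }
    if (!is.null(st)) write_results(tidy(st), file.path(out_dir, "stats.csv"))
  }

  manifest <- list(
    config = config,
    config_hash = rlang::hash(config),
    seed = config$seed,
    freerun_version = as.character(utils::packageVersion("freerun")),
    r_version = R.version.string
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' Summarize a pipeline run
#'
#' Per-group percentages of the three rhythmicity classes plus the mean and
#' SEM of tau over strongly rhythmic animals; groups with no strong animals
#' get `"n/a"` in the tau columns.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return A tibble (also written to `report.csv` in the run directory) with
#'   columns `group`, `n`, `pct_strong`, `pct_complex`, `pct_arrhythmic`,
#'   `mean_tau`, `sem_tau` (the latter two as strings so `"n/a"` can appear).
#' @export
report_run <- function(run_dir) {
  calls <- read_results(file.path(run_dir, "rhythm_calls.csv"))
  summary <- calls |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      pct_strong = 100 * mean(.data$classification == "strong"),
      pct_complex = 100 * mean(.data$classification == "complex"),
      pct_arrhythmic = 100 * mean(.data$classification == "arrhythmic"),
      mean_tau_num = ifelse(any(.data$classification == "strong"),
        mean(.data$tau_hours[.data$classification == "strong"]), NA_real_
      ),
      sem_tau_num = ifelse(sum(.data$classification == "strong") > 1L,
        sd(.data$tau_hours[.data$classification == "strong"]) /
          sqrt(sum(.data$classification == "strong")), NA_real_
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mean_tau = ifelse(is.na(.data$mean_tau_num), "n/a",
        sprintf("%.4f", .data$mean_tau_num)
      ),
      sem_tau = ifelse(is.na(.data$sem_tau_num), "n/a",
        sprintf("%.4f", .data$sem_tau_num)
      )
    ) |>
    dplyr::select(-"mean_tau_num", -"sem_tau_num")
  readr::write_csv(summary, file.path(run_dir, "report.csv"))
  summary
}
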