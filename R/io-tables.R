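#' Read a table of per-animal free-running periods
#'
#' Reads a CSV with header `animal_id, treatment_group, tau_hours`, as used to
#' hold per-animal free-running periods of strongly rhythmic animals for the
#' cohort statistics stage.
#'
#' @param path CSV path.
#' @return A tibble with columns `animal_id` (character), `treatment_group`
#'   (character, non-empty) and `tau_hours` (positive numeric).
#' @export
read_tau_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("animal_id", "treatment_group", "tau_hours")
  if (!all(needed %in% names(tbl))) {
    abort("tau table must have columns animal_id, treatment_group, tau_hours")
  }
  tbl <- dplyr::mutate(tbl,
    animal_id = as.character(.data$animal_id),
    treatment_group = as.character(.data$treatment_group),
    tau_hours = as.numeric(.data$tau_hours)
  )
  if (any(is.na(tbl$tau_hours)) || any(tbl$tau_hours <= 0)) {
    abort("tau_hours must be positive")
  }
  if (any(!nzchar(tbl$treatment_group) | is.na(tbl$treatment_group))) {
    abort("treatment_group must be non-empty")
  }
  dup <- tbl |>
    dplyr::count(.data$treatment_group, .data$animal_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    warn(sprintf(
      "duplicate animal_id within a group (%s); rows kept",
      paste(unique(dup$animal_id), collapse = ", ")
    ))
  }
  tbl[, needed]
}

#' Write a results table to CSV
#'
#' All tabular outputs are UTF-8 CSV with the tibble's column names as the
#' header; floating-point columns are printed with 4 decimals so that the
#' write/read cycle is value-stable at the documented precision.
#'
#' @param results A data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  out <- dplyr::mutate(
    results,
    dplyr::across(dplyr::where(is.double), ~ round(.x, 4))
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, na = "")
}
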