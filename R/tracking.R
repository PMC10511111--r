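#' Estimate a static background image
#'
#' Per-pixel median over a uniform subsample of at most `max_frames` frames.
#' With the animal moving, the median suppresses it and recovers the empty
#' arena.
#'
#' @param frames A [frame_set()] with at least 3 frames.
#' @param max_frames Subsample cap (default 200).
#' @return A numeric background matrix on the 0--255 scale.
#' @export
estimate_background <- function(frames, max_frames = 200) {
  n <- length(frames$frames)
  if (n < 3L) abort("need at least 3 frames to estimate a background")
  idx <- unique(round(seq(1, n, length.out = min(n, max_frames))))
  stack <- vapply(frames$frames[idx], identity,
    FUN.VALUE = frames$frames[[1]]
  )
  apply(stack, c(1, 2), median)
}

## robust noise scale of background-subtracted differences
robust_sd <- function(x) mad(x, center = 0)

#' Locate the animal in one frame
#'
#' Within the dish's mask region, the absolute background difference is
#' thresholded at `max(k_sd * robust noise SD, abs_floor)` (the noise SD is a
#' median-absolute-deviation estimate over the dish region); if the foreground
#' area reaches `min_area_px`, the intensity-weighted centroid of the largest
#' connected component (ties broken by lower label order) is returned in cm.
#' Otherwise the animal is reported as not located for this frame.
#'
#' @param frame Numeric matrix (0--255 grayscale).
#' @param background Matrix from [estimate_background()].
#' @param mask An [roi_mask()].
#' @param dish_id Dish label to search.
#' @param k_sd Threshold in robust noise SDs (default 4).
#' @param abs_floor Absolute threshold floor, gray levels.
#' @param min_area_px Minimum foreground blob area, pixels.
#' @return A one-row tibble `(dish_id, x_cm, y_cm, located)`; coordinates are
#'   relative to the dish-region centroid, `NA` when not located.
#' @export
locate_animal <- function(frame, background, mask, dish_id,
                          k_sd = 4, abs_floor = 10, min_area_px = 9) {
  if (!dish_id %in% seq_len(mask$n_dishes)) {
    abort(sprintf("dish_id %s not present in mask", dish_id))
  }
  region <- mask$labels == dish_id
  d <- abs(frame - background)
  dr <- d[region]
  thr <- max(k_sd * robust_sd(dr), abs_floor)
  fg <- d >= thr & region
  not_found <- tibble::tibble(
    dish_id = as.integer(dish_id),
    x_cm = NA_real_, y_cm = NA_real_, located = FALSE
  )
  if (sum(fg) < min_area_px) {
    return(not_found)
  }
  lab <- EBImage::bwlabel(fg * 1)
  sizes <- tabulate(lab[lab > 0])
  best <- which(sizes == max(sizes))[1] # tie -> lower label
  if (sizes[best] < min_area_px) {
    return(not_found)
  }
  sel <- lab == best
  wts <- d[sel]
  rows <- row(frame)[sel]
  cols <- col(frame)[sel]
  cy <- sum(rows * wts) / sum(wts)
  cx <- sum(cols * wts) / sum(wts)
  ## cm coordinates relative to the dish-region centroid, +x along columns
  ctr_y <- mean(row(frame)[region])
  ctr_x <- mean(col(frame)[region])
  tibble::tibble(
    dish_id = as.integer(dish_id),
    x_cm = (cx - ctr_x) * mask$pixel_scale_cm,
    y_cm = (cy - ctr_y) * mask$pixel_scale_cm,
    located = TRUE
  )
}

#' Track positions across a frame stack
#'
#' Runs [estimate_background()] once, then [locate_animal()] on every frame
#' for each requested dish.
#'
#' @param frames A [frame_set()].
#' @param mask An [roi_mask()].
#' @param dish_ids Dishes to track (default: all in the mask).
#' @inheritParams locate_animal
#' @return A `position_track` tibble `(dish_id, time_h, x_cm, y_cm, located)`.
#' @export
track_positions <- function(frames, mask, dish_ids = seq_len(mask$n_dishes),
                            k_sd = 4, abs_floor = 10, min_area_px = 9) {
  bg <- estimate_background(frames)
  out <- purrr::map_dfr(dish_ids, function(k) {
    purrr::map_dfr(seq_along(frames$frames), function(f) {
      loc <- locate_animal(frames$frames[[f]], bg, mask, k,
        k_sd = k_sd, abs_floor = abs_floor, min_area_px = min_area_px
      )
      loc$time_h <- frames$time_h[[f]]
      loc
    })
  })
  out <- dplyr::select(
    out, "dish_id", "time_h", "x_cm", "y_cm", "located"
  )
  structure(out,
    frame_interval_seconds = frames$frame_interval_seconds,
    class = c("position_track", class(out))
  )
}

#' Score activity events from a position track
#'
#' Implements the displacement scoring rule: each consecutive pair of located
#' positions yields one binary event -- 1 if the Euclidean body shift is
#' strictly greater than `threshold_cm` (1 cm by default), else 0. Pairs with
#' either endpoint not located become missing bins, never zeros.
#'
#' @param track A `position_track` (from [simulate_trajectory()] or
#'   [track_positions()]) for a single dish.
#' @param threshold_cm Displacement threshold, cm (strict inequality).
#' @param schedule Optional [light_schedule()] attached to the record.
#' @param missing_flag_frac Fraction of missing bins above which the record is
#'   flagged (`qc_flag` attribute).
#' @return An [activity_record()] of 0/1 events with
#'   `bin_seconds` equal to the frame interval; attribute `qc` holds the
#'   fraction located and the dropout flag.
#' @export
events_from_track <- function(track, threshold_cm = 1.0, schedule = NULL,
                              missing_flag_frac = 0.2) {
  if (length(unique(track$dish_id)) != 1L) {
    abort("`track` must cover a single dish; split first")
  }
  if (nrow(track) < 2L) abort("need at least 2 samples to score events")
  assert_scalar_num(threshold_cm, "threshold_cm", lower = 0)
  dx <- diff(track$x_cm)
  dy <- diff(track$y_cm)
  disp <- sqrt(dx^2 + dy^2)
  ok <- track$located[-1] & track$located[-nrow(track)]
  ev <- ifelse(ok, as.numeric(disp > threshold_cm), NA_real_)
  interval <- attr(track, "frame_interval_seconds") %||%
    (diff(track$time_h[1:2]) * 3600)
  rec <- activity_record(ev,
    bin_seconds = interval, schedule = schedule,
    animal_id = sprintf("dish%d", track$dish_id[[1]]),
    species = ""
  )
  frac_missing <- mean(!ok)
  attr(rec, "qc") <- list(
    fraction_located = mean(track$located),
    fraction_missing_bins = frac_missing,
    dropout_flag = frac_missing > missing_flag_frac
  )
  rec
}
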