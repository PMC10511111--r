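#' Specify a Petri-dish arena
#'
#' Geometry and imaging parameters of the synthetic arena used to generate
#' trajectories and render frame stacks.
#'
#' @param dish_diameter_cm Dish diameter (default 9 cm).
#' @param pixel_scale_cm Centimetres per pixel.
#' @param n_dishes Number of dishes run in parallel.
#' @param blob_radius_px Rendered animal radius, pixels.
#' @param noise_sd Gaussian pixel noise SD, grayscale units (0--255 scale).
#' @return A list of class `"arena_spec"`.
#' @export
arena_spec <- function(dish_diameter_cm = 9, pixel_scale_cm = 0.05,
                       n_dishes = 1, blob_radius_px = 6, noise_sd = 2) {
  assert_scalar_num(dish_diameter_cm, "dish_diameter_cm", lower = 0, strict_lower = TRUE)
  assert_scalar_num(pixel_scale_cm, "pixel_scale_cm", lower = 0, strict_lower = TRUE)
  assert_scalar_num(n_dishes, "n_dishes", lower = 1)
  assert_scalar_num(blob_radius_px, "blob_radius_px", lower = 1)
  assert_scalar_num(noise_sd, "noise_sd", lower = 0)
  if (2 * blob_radius_px * pixel_scale_cm >= dish_diameter_cm) {
    abort("rendered animal does not fit inside the dish")
  }
  structure(
    list(
      dish_diameter_cm = dish_diameter_cm, pixel_scale_cm = pixel_scale_cm,
      n_dishes = as.integer(n_dishes), blob_radius_px = blob_radius_px,
      noise_sd = noise_sd
    ),
    class = "arena_spec"
  )
}

#' Simulate a 2-D locomotor trajectory in a dish
#'
#' One position per `bin_seconds`. At each step the animal is "active" with
#' probability \eqn{p(t) = \min(1, \lambda(t))}, where \eqn{\lambda(t)} is the
#' circadian rate model of [sim_spec()] interpreted on a per-frame probability
#' scale; an active step has exponentially distributed length (mean
#' `active_step_cm`), a resting step is small positional jitter (mean
#' `rest_step_cm`), both in a uniformly random direction. Steps are truncated
#' to the dish span and reflected at the dish wall, so the track never leaves
#' the dish.
#'
#' @param spec A [sim_spec()]; `baseline_rate` and `amplitude` are read as
#'   per-frame activity propensities (dimensionless, capped at 1).
#' @param arena An [arena_spec()].
#' @param dish_id Label for the output track.
#' @param active_step_cm,rest_step_cm Mean exponential step lengths, cm.
#' @return A tibble of class `"position_track"` with columns `dish_id`,
#'   `time_h`, `x_cm`, `y_cm`, `located` (all `TRUE` for simulated tracks) and
#'   attributes `frame_interval_seconds` and `ground_truth`.
#' @export
simulate_trajectory <- function(spec, arena = arena_spec(), dish_id = 1L,
                                active_step_cm = 2.5, rest_step_cm = 0.2) {
  r_max <- arena$dish_diameter_cm / 2
  n_days <- spec$entrain_days + spec$dd_days
  n_steps <- as.integer(round(n_days * 24 * 3600 / spec$bin_seconds))
  time_h <- (seq_len(n_steps) - 1L) * spec$bin_seconds / 3600
  p_active <- pmin(1, sim_rate(spec, time_h))

  pos <- with_seed(spec$seed, {
    x <- numeric(n_steps)
    y <- numeric(n_steps)
    active <- runif(n_steps) < p_active
    len <- ifelse(active,
      rexp(n_steps, rate = 1 / active_step_cm),
      rexp(n_steps, rate = 1 / rest_step_cm)
    )
    len <- pmin(len, arena$dish_diameter_cm) # truncate to the dish span
    ang <- runif(n_steps, 0, 2 * pi)
    for (i in seq_len(n_steps)[-1]) {
      xn <- x[i - 1] + len[i] * cos(ang[i])
      yn <- y[i - 1] + len[i] * sin(ang[i])
      rr <- sqrt(xn^2 + yn^2)
      if (rr > r_max) { # reflect radially at the wall
        scl <- (2 * r_max - rr) / rr
        if (scl < 0) scl <- 0 # extreme step: land at the centre side
        xn <- xn * scl
        yn <- yn * scl
        rr <- abs(2 * r_max - rr)
        if (rr > r_max) { # still outside after one reflection: clamp
          xn <- xn * 0.999 * r_max / max(rr, 1e-12)
          yn <- yn * 0.999 * r_max / max(rr, 1e-12)
        }
      }
      x[i] <- xn
      y[i] <- yn
    }
    list(x = x, y = y, active = active)
  })

  out <- tibble::tibble(
    dish_id = as.integer(dish_id), time_h = time_h,
    x_cm = pos$x, y_cm = pos$y, located = TRUE
  )
  structure(out,
    frame_interval_seconds = spec$bin_seconds,
    ground_truth = list(
      phenotype = spec$phenotype, tau_hours = spec$tau_hours,
      active = pos$active, seed = spec$seed
    ),
    class = c("position_track", class(out))
  )
}

## Dish centre layout for rendering: square grid, row-major
dish_centres_px <- function(arena) {
  d_px <- arena$dish_diameter_cm / arena$pixel_scale_cm
  margin <- 4
  n <- arena$n_dishes
  ncol_g <- ceiling(sqrt(n))
  nrow_g <- ceiling(n / ncol_g)
  pitch <- d_px + 2 * margin
  centres <- purrr::map_dfr(seq_len(n), function(k) {
    gi <- (k - 1L) %/% ncol_g
    gj <- (k - 1L) %% ncol_g
    tibble::tibble(
      dish_id = k,
      cy = margin + d_px / 2 + gi * pitch,
      cx = margin + d_px / 2 + gj * pitch
    )
  })
  list(
    centres = centres,
    height = ceiling(nrow_g * pitch + 2 * margin),
    width = ceiling(ncol_g * pitch + 2 * margin)
  )
}

#' Render synthetic frames and the matching ROI mask
#'
#' Each frame is a uniform bright background with one dark disc per dish at
#' the true animal position plus Gaussian pixel noise; the mask labels each
#' dish's circular region. Ground-truth positions are retained on the result.
#'
#' @param tracks A `position_track` or list of them (one per dish; dish ids
#'   must be 1..n_dishes of `arena`).
#' @param arena An [arena_spec()].
#' @param background,animal_value Background and animal gray levels (0--255).
#' @param seed Seed for the pixel noise.
#' @return A list with elements `frames` (a [frame_set()]), `mask` (an
#'   [roi_mask()]) and `truth` (tibble of true positions per frame and dish).
#' @export
render_frames <- function(tracks, arena = arena_spec(), background = 200,
                          animal_value = 60, seed = 1L) {
  if (inherits(tracks, "position_track")) tracks <- list(tracks)
  layout <- dish_centres_px(arena)
  h <- layout$height
  w <- layout$width
  r_dish_px <- arena$dish_diameter_cm / arena$pixel_scale_cm / 2

  ## label mask: circular dish regions
  rowc <- matrix(seq_len(h), nrow = h, ncol = w)
  colc <- matrix(seq_len(w), nrow = h, ncol = w, byrow = TRUE)
  labels <- matrix(0L, nrow = h, ncol = w)
  for (k in seq_len(arena$n_dishes)) {
    ck <- layout$centres[k, ]
    inside <- (rowc - ck$cy)^2 + (colc - ck$cx)^2 <= r_dish_px^2
    labels[inside] <- k
  }
  mask <- roi_mask(labels, pixel_scale_cm = arena$pixel_scale_cm)

  n_frames <- nrow(tracks[[1]])
  interval <- attr(tracks[[1]], "frame_interval_seconds") %||% 300
  truth <- purrr::map_dfr(tracks, function(tr) {
    tibble::tibble(
      frame = seq_len(nrow(tr)), dish_id = tr$dish_id,
      x_cm = tr$x_cm, y_cm = tr$y_cm
    )
  })

  frames <- with_seed(seed, {
    lapply(seq_len(n_frames), function(f) {
      img <- matrix(background, nrow = h, ncol = w)
      for (tr in tracks) {
        k <- tr$dish_id[[1]]
        ck <- layout$centres[layout$centres$dish_id == k, ]
        ## cm coordinates are dish-centred; +x -> +column, +y -> +row
        px_col <- ck$cx + tr$x_cm[f] / arena$pixel_scale_cm
        px_row <- ck$cy + tr$y_cm[f] / arena$pixel_scale_cm
        rr <- arena$blob_radius_px
        r_lo <- max(1L, floor(px_row - rr - 1))
        r_hi <- min(h, ceiling(px_row + rr + 1))
        c_lo <- max(1L, floor(px_col - rr - 1))
        c_hi <- min(w, ceiling(px_col + rr + 1))
        for (i in r_lo:r_hi) {
          dj <- sqrt(pmax(0, rr^2 - (i - px_row)^2))
          if ((i - px_row)^2 <= rr^2) {
            j_lo <- max(1L, ceiling(px_col - dj))
            j_hi <- min(w, floor(px_col + dj))
            if (j_lo <= j_hi) img[i, j_lo:j_hi] <- animal_value
          }
        }
      }
      if (arena$noise_sd > 0) {
        img <- img + matrix(rnorm(h * w, sd = arena$noise_sd), nrow = h)
      }
      pmin(pmax(img, 0), 255)
    })
  })

  list(
    frames = frame_set(frames, frame_interval_seconds = interval),
    mask = mask,
    truth = truth
  )
}
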