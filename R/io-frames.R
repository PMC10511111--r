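#' Frame stacks and ROI masks
#'
#' A frame set holds an ordered sequence of timed grayscale images (numeric
#' matrices on a 0--255 scale) sampled at a nominal fixed interval (300 s
#' frames in the standard assay). An ROI mask is an integer label image
#' (0 = background, k = dish k, labels forming a contiguous positive range)
#' plus the pixel scale in cm per pixel that calibrates displacements.
#'
#' @param frames List of numeric matrices, all with identical dimensions.
#' @param frame_interval_seconds Seconds between consecutive frames.
#' @param time_h Optional explicit frame times (hours); default is a regular
#'   grid starting at 0.
#' @return `frame_set()` returns a list of class `"frame_set"` with elements
#'   `frames`, `time_h`, `frame_interval_seconds`.
#' @export
frame_set <- function(frames, frame_interval_seconds = 300, time_h = NULL) {
  if (length(frames) < 1L) abort("need at least one frame")
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1L) abort("mixed image dimensions in frame set")
  if (is.null(time_h)) {
    time_h <- (seq_along(frames) - 1L) * frame_interval_seconds / 3600
  }
  if (length(time_h) != length(frames) || any(diff(time_h) <= 0)) {
    abort("frame timestamps must be strictly increasing, one per frame")
  }
  structure(
    list(
      frames = frames, time_h = time_h,
      frame_interval_seconds = frame_interval_seconds
    ),
    class = "frame_set"
  )
}

#' @export
print.frame_set <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<frame_set> %d frames of %dx%d px every %gs\n",
    length(x$frames), d[1], d[2], x$frame_interval_seconds
  ))
  invisible(x)
}

read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(sprintf("unsupported image format: .%s", ext))
  )
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
  img * 255
}

#' Read timed grayscale frames from image files
#'
#' @param paths Character vector of PNG/TIFF paths, in temporal order.
#' @param frame_interval_seconds Seconds between consecutive frames.
#' @return A [frame_set()].
#' @export
read_frames <- function(paths, frame_interval_seconds = 300) {
  if (length(paths) < 1L) abort("no frame files given")
  frame_set(lapply(paths, read_gray_image),
    frame_interval_seconds = frame_interval_seconds
  )
}

#' @param labels Integer matrix of ROI labels (0 background, k = dish k).
#' @param pixel_scale_cm Centimetres per pixel; required and positive.
#' @rdname frame_set
#' @export
roi_mask <- function(labels, pixel_scale_cm) {
  if (missing(pixel_scale_cm) || is.null(pixel_scale_cm)) {
    abort("`pixel_scale_cm` is required")
  }
  assert_scalar_num(pixel_scale_cm, "pixel_scale_cm", lower = 0, strict_lower = TRUE)
  labels <- matrix(as.integer(round(labels)), nrow = nrow(labels))
  present <- sort(unique(labels[labels > 0L]))
  if (length(present) == 0L) abort("mask contains no dish labels")
  if (!identical(present, seq_len(max(present)))) {
    abort("mask labels must form a contiguous range 1..n_dishes")
  }
  structure(
    list(labels = labels, pixel_scale_cm = pixel_scale_cm, n_dishes = max(present)),
    class = "roi_mask"
  )
}

#' Read an ROI label-mask image
#'
#' Grayscale pixel values are rounded to integer labels (0 = background).
#'
#' @param path PNG/TIFF path of the label image. Pixel value k (on the 0-255
#'   scale) labels dish k.
#' @param pixel_scale_cm Centimetres per pixel.
#' @return A [roi_mask()].
#' @export
read_roi_mask <- function(path, pixel_scale_cm) {
  roi_mask(round(read_gray_image(path)), pixel_scale_cm = pixel_scale_cm)
}

#' Write a frame set / ROI mask as PNG files
#'
#' @param fs A [frame_set()]; `mask` an [roi_mask()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix for frames.
#' @return Character vector of the written paths, invisibly.
#' @export
write_frames <- function(fs, dir, prefix = "frame") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_%05d.png", prefix, seq_along(fs$frames)))
  for (i in seq_along(fs$frames)) {
    png::writePNG(pmin(pmax(fs$frames[[i]] / 255, 0), 1), paths[i])
  }
  invisible(paths)
}

#' @param mask An [roi_mask()].
#' @param path Output PNG path for the mask.
#' @rdname write_frames
#' @export
write_roi_mask <- function(mask, path) {
  png::writePNG(mask$labels / 255, path)
  invisible(path)
}
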