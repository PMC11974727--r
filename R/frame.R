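#' Image frame with physical calibration
#'
#' An `image_frame` is the universal carrier of a single-channel microscopy
#' image: a numeric intensity matrix plus the pixel size (micrometres per
#' pixel) and an acquisition timestamp (seconds). Matrix rows run along the
#' image y axis and columns along x. Pixel coordinates are 0-based with pixel
#' centres at integers, `(x = column, y = row)`; angles are measured from the
#' +x axis, counter-clockwise in image coordinates. This convention is used
#' throughout the package.
#'
#' @param intensity numeric matrix of non-negative intensities (rows x cols).
#' @param pixel_size pixel size in micrometres per pixel (> 0).
#' @param timestamp acquisition time in seconds (default 0).
#' @return An object of class `image_frame`: a list with elements
#'   `intensity`, `pixel_size`, `timestamp`.
#' @examples
#' fr <- image_frame(matrix(0, 32, 32), pixel_size = 0.11)
#' dim(fr$intensity)
#' @export
image_frame <- function(intensity, pixel_size, timestamp = 0) {
  if (!is.matrix(intensity) || !is.numeric(intensity) ||
      nrow(intensity) < 1L || ncol(intensity) < 1L) {
    stop("`intensity` must be a non-empty numeric matrix")
  }
  if (anyNA(intensity)) stop("`intensity` must not contain NA")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number (um/px)")
  }
  structure(
    list(intensity = intensity, pixel_size = as.numeric(pixel_size),
         timestamp = as.numeric(timestamp)),
    class = "image_frame"
  )
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("<image_frame> %d x %d px, %.4g um/px, t = %.3g s\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_size,
              x$timestamp))
  invisible(x)
}

#' Time-lapse stack of image frames
#'
#' A `time_lapse` bundles a list of equally sized intensity matrices with a
#' shared pixel size and per-frame timestamps in seconds. Timestamps must be
#' strictly increasing but need not be regular.
#'
#' @param frames list of numeric matrices, all the same dimension.
#' @param pixel_size micrometres per pixel (> 0).
#' @param times numeric vector of per-frame timestamps in seconds; defaults
#'   to `0, 1, 2, ...`.
#' @return An object of class `time_lapse` with elements `frames`,
#'   `pixel_size`, `times`.
#' @export
time_lapse <- function(frames, pixel_size, times = NULL) {
  if (!is.list(frames) || length(frames) < 1L) {
    stop("`frames` must be a non-empty list of matrices")
  }
  d <- dim(frames[[1L]])
  ok <- vapply(frames, function(f) is.matrix(f) && identical(dim(f), d),
               logical(1))
  if (!all(ok)) stop("all frames must be matrices of identical dimension")
  if (is.null(times)) times <- seq_along(frames) - 1
  if (length(times) != length(frames)) {
    stop("`times` must have one entry per frame")
  }
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number (um/px)")
  }
  structure(
    list(frames = frames, pixel_size = as.numeric(pixel_size),
         times = as.numeric(times)),
    class = "time_lapse"
  )
}

#' @export
print.time_lapse <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf(
    "<time_lapse> %d frames of %d x %d px, %.4g um/px, t in [%.3g, %.3g] s\n",
    length(x$frames), d[1L], d[2L], x$pixel_size, min(x$times), max(x$times)))
  invisible(x)
}

#' @export
length.time_lapse <- function(x) length(x$frames)

#' Extract one frame of a time-lapse as an image_frame
#'
#' @param stack a `time_lapse`.
#' @param i frame index (1-based).
#' @return An `image_frame` carrying the stack's pixel size and the frame's
#'   timestamp.
#' @export
get_frame <- function(stack, i) {
  stopifnot(inherits(stack, "time_lapse"))
  i <- as.integer(i)
  if (i < 1L || i > length(stack$frames)) stop("frame index out of range")
  image_frame(stack$frames[[i]], stack$pixel_size, stack$times[[i]])
}

as_intensity <- function(x) {
  if (inherits(x, "image_frame")) x$intensity else x
}
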