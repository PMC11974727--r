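# Nuclear segmentation and the cortical nuclear ratio time series. The
# cortical nuclear ratio is the count of nuclei in the outer donut of the
# fitted sporangium ellipse divided by the count in the inner disk; it sits
# near 1 under uniform placement and peaks during cortical migration.

#' Segment nuclei in a single frame
#'
#' Foreground by multi-level Otsu thresholding (brightest class of
#' `n_threshold_classes`), touching nuclei split by marker-controlled
#' watershed on the Euclidean distance transform (markers = local maxima of
#' the distance map with a minimum separation), objects smaller than
#' `min_area_px` discarded. Centroids are intensity-weighted.
#'
#' @param frame an `image_frame` or matrix.
#' @param min_area_px minimum object area in px^2 (default 9).
#' @param n_threshold_classes Otsu class count (default 3: background /
#'   cytoplasm / nuclei).
#' @param marker_sep_px minimum separation of watershed markers (default 5).
#' @return a `nucleus_set`: list with `centroids` (matrix of 0-based x, y),
#'   `areas` (px^2), `labels` (label matrix) and `frame_index` (NA here;
#'   filled by stack-level callers).
#' @export
segment_nuclei <- function(frame, min_area_px = 9, n_threshold_classes = 3L,
                           marker_sep_px = 5) {
  img <- as_intensity(frame)
  if (all(img == img[1L])) {
    return(nucleus_set(matrix(numeric(0), 0L, 2L), numeric(0),
                       labels = matrix(0L, nrow(img), ncol(img))))
  }
  thr <- otsu_thresholds(img, n_classes = n_threshold_classes)
  fg <- img > thr[length(thr)]
  if (!any(fg)) {
    return(nucleus_set(matrix(numeric(0), 0L, 2L), numeric(0),
                       labels = matrix(0L, nrow(img), ncol(img))))
  }
  dt <- distance_transform(fg)
  mx <- local_maxima(dt, min_distance_px = marker_sep_px, threshold = 1)
  markers <- matrix(0L, nrow(img), ncol(img))
  if (nrow(mx)) {
    markers[cbind(mx$y + 1L, mx$x + 1L)] <- seq_len(nrow(mx))
    lab <- watershed_labels(dt, markers, fg)
  } else {
    lab <- label_components(fg)
  }
  # any foreground not reached by the flood keeps its own component label
  orphan <- fg & lab == 0L
  if (any(orphan)) {
    extra <- label_components(orphan)
    lab[orphan] <- extra[orphan] + max(lab)
  }
  ids <- sort(unique(lab[lab > 0L]))
  cx <- numeric(0); cy <- numeric(0); area <- numeric(0)
  for (id in ids) {
    idx <- which(lab == id, arr.ind = TRUE)
    if (nrow(idx) < min_area_px) { lab[lab == id] <- 0L; next }
    w <- img[idx]
    if (sum(w) <= 0) w <- rep(1, nrow(idx))
    cx <- c(cx, sum((idx[, 2L] - 1) * w) / sum(w))
    cy <- c(cy, sum((idx[, 1L] - 1) * w) / sum(w))
    area <- c(area, nrow(idx))
  }
  nucleus_set(cbind(x = cx, y = cy), area, labels = lab)
}

#' Nucleus set container
#'
#' @param centroids matrix of 0-based `x`, `y` centroids (px).
#' @param areas object areas (px^2), positive.
#' @param labels optional label matrix.
#' @param frame_index optional frame index.
#' @return object of class `nucleus_set`.
#' @export
nucleus_set <- function(centroids, areas, labels = NULL,
                        frame_index = NA_integer_) {
  centroids <- matrix(as.numeric(centroids), ncol = 2L,
                      dimnames = list(NULL, c("x", "y")))
  if (nrow(centroids) != length(areas)) {
    stop("one area per centroid required")
  }
  if (length(areas) && any(areas <= 0)) stop("areas must be positive")
  structure(list(centroids = centroids, areas = as.numeric(areas),
                 labels = labels, frame_index = frame_index),
            class = "nucleus_set")
}

#' @export
print.nucleus_set <- function(x, ...) {
  cat(sprintf("<nucleus_set> %d nuclei\n", nrow(x$centroids)))
  invisible(x)
}

#' Cortical nuclear ratio of one frame
#'
#' Outer-donut count divided by inner-disk count of nucleus centroids under
#' the `f`-scaled concentric ellipse; centroids outside the perimeter
#' ellipse are excluded. A zero inner count yields an undefined ratio,
#' which is flagged (`defined = FALSE`) and propagated rather than dropped.
#'
#' @param nuclei a `nucleus_set` (or bare centroid matrix).
#' @param E the perimeter `ellipse_model`.
#' @param f donut boundary factor in (0, 1); default 0.70.
#' @return list with `ratio`, `defined`, `n_inner`, `n_outer`, `n_outside`.
#' @export
cortical_ratio <- function(nuclei, E, f = 0.70) {
  pts <- if (inherits(nuclei, "nucleus_set")) nuclei$centroids else
    as.matrix(nuclei)
  cl <- classify_points(pts, E, f)
  defined <- cl$inner > 0L
  list(ratio = if (defined) cl$outer / cl$inner else NA_real_,
       defined = defined,
       n_inner = cl$inner, n_outer = cl$outer, n_outside = cl$outside)
}

#' Cortical ratio series container
#'
#' @param times times in minutes (strictly increasing).
#' @param ratios ratios (NA where undefined).
#' @param sporangium_id identifier string.
#' @param peak_index optional index of the aligned peak.
#' @return object of class `cortical_ratio_series`.
#' @export
cortical_ratio_series <- function(times, ratios, sporangium_id = "sp1",
                                  peak_index = NA_integer_) {
  stopifnot(length(times) == length(ratios))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(ratios < 0, na.rm = TRUE)) stop("ratios must be >= 0")
  structure(list(times = as.numeric(times), ratios = as.numeric(ratios),
                 sporangium_id = sporangium_id,
                 peak_index = as.integer(peak_index)),
            class = "cortical_ratio_series")
}

#' Align a ratio series to its peak
#'
#' Shifts times so the global maximum defined ratio sits at t = 0 (ties
#' broken by the earliest time). An optional 3-point median prefilter can
#' resist single-frame segmentation glitches (off by default). Inter-sample
#' intervals are preserved exactly.
#'
#' @param series a `cortical_ratio_series`.
#' @param median_prefilter apply a 3-point running median before peak
#'   finding (default FALSE).
#' @return the series with shifted `times` and `peak_index` set.
#' @export
align_to_peak <- function(series, median_prefilter = FALSE) {
  stopifnot(inherits(series, "cortical_ratio_series"))
  r <- series$ratios
  if (all(is.na(r))) stop("all ratios undefined: cannot align")
  rr <- r
  if (median_prefilter && sum(!is.na(r)) >= 3L) {
    ok <- !is.na(r)
    rr[ok] <- stats::runmed(r[ok], 3L)
  }
  rr[is.na(rr)] <- -Inf
  peak <- which.max(rr)  # which.max takes the first (earliest) maximum
  series$times <- series$times - series$times[peak]
  series$peak_index <- as.integer(peak)
  series
}

#' Cortical ratio time series for a whole stack
#'
#' Runs [segment_nuclei()] on every frame and [cortical_ratio()] against a
#' fixed perimeter ellipse.
#'
#' @param stack a `time_lapse` of the nuclear channel.
#' @param E perimeter `ellipse_model`.
#' @param f donut boundary factor (default 0.70).
#' @param interval_min frame interval in minutes; defaults to the stack's
#'   timestamps converted from seconds.
#' @param sporangium_id identifier for the output.
#' @param ... passed to [segment_nuclei()].
#' @return a `cortical_ratio_series` plus per-frame counts in
#'   `attr(, "counts")`.
#' @export
stack_cortical_ratio <- function(stack, E, f = 0.70, interval_min = NULL,
                                 sporangium_id = "sp1", ...) {
  stopifnot(inherits(stack, "time_lapse"))
  n <- length(stack$frames)
  times <- if (is.null(interval_min)) stack$times / 60 else
    interval_min * (seq_len(n) - 1)
  rows <- lapply(seq_len(n), function(i) {
    ns <- segment_nuclei(stack$frames[[i]], ...)
    cr <- cortical_ratio(ns, E, f)
    data.frame(frame = i, t_min = times[i], n_inner = cr$n_inner,
               n_outer = cr$n_outer, n_outside = cr$n_outside,
               ratio = cr$ratio)
  })
  tab <- do.call(rbind, rows)
  out <- cortical_ratio_series(tab$t_min, tab$ratio, sporangium_id)
  attr(out, "counts") <- tab
  out
}

#' Loess smoothing with pointwise confidence band
#'
#' Locally weighted degree-1 (linear) regression with tricube weights over
#' the nearest `ceiling(span * n)` neighbours — `stats::loess` with
#' `degree = 1` — plus a pointwise confidence band from the local fit's
#' standard errors. Undefined (NA) ratios are skipped, not interpolated
#' away silently.
#'
#' @param series a `cortical_ratio_series`, or a list/data.frame with
#'   `times` and `ratios`.
#' @param span loess span in (0, 1]; default 0.2 (the published setting).
#' @param ci_level confidence level; default 0.99 (the published setting).
#' @return data.frame with `t`, `fit`, `lo`, `hi`.
#' @export
loess_smooth <- function(series, span = 0.2, ci_level = 0.99) {
  t <- series$times; y <- series$ratios
  ok <- !is.na(y)
  t <- t[ok]; y <- y[ok]
  n <- length(y)
  if (n < 10L) stop("need at least 10 defined points to smooth")
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  if (ceiling(span * n) < 3L) {
    stop("span too small: local fits need at least 3 points")
  }
  fit <- stats::loess(y ~ t, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  pr <- stats::predict(fit, newdata = data.frame(t = t), se = TRUE)
  z <- stats::qt(1 - (1 - ci_level) / 2, df = pr$df)
  data.frame(t = t, fit = pr$fit,
             lo = pr$fit - z * pr$se.fit,
             hi = pr$fit + z * pr$se.fit)
}
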