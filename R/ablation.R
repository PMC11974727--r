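# Laser-ablation recoil mechanics: FFT cross-correlation PIV, SNR
# filtering, decomposition of velocities into the radial component relative
# to the ablation site, distance/time binned summaries with bootstrap CIs,
# kymographs and receding-tip distance curves.

#' Ablation event description
#'
#' @param point length-2 `(x, y)` ablation site in px (0-based).
#' @param start_s,end_s ablation start and end times in seconds
#'   (`start_s < end_s`).
#' @param blank_frames indices of blank (shuttered) frames in the stack.
#' @return object of class `ablation_event`.
#' @export
ablation_event <- function(point, start_s, end_s, blank_frames = integer(0)) {
  if (length(point) != 2L) stop("ablation point must be (x, y)")
  if (!(start_s < end_s)) stop("ablation start must precede its end")
  structure(list(point = as.numeric(point), start_s = as.numeric(start_s),
                 end_s = as.numeric(end_s),
                 blank_frames = as.integer(blank_frames)),
            class = "ablation_event")
}

#' PIV between two frames by zero-normalised FFT cross-correlation
#'
#' The frames are tiled into square interrogation windows (`window_px`,
#' overlapping by `overlap_px`). Each window pair is mean-subtracted,
#' cross-correlated via zero-padded FFT, and the integer correlation peak
#' is refined with the 3-point Gaussian sub-pixel estimator (parabolic
#' fallback when a neighbour is non-positive). Displacements are converted
#' to um/s via `pixel_size / dt`. The signal-to-noise ratio is the ratio of
#' the first correlation peak to the second peak outside a 3x3 exclusion
#' zone.
#'
#' @param frame_a,frame_b matrices or `image_frame`s of identical shape.
#' @param window_px interrogation window size (>= 16; default 32).
#' @param overlap_px window overlap (default 16; `0 <= overlap < window`).
#' @param dt time between the frames in seconds.
#' @param pixel_size um/px; taken from `frame_a` when it is an
#'   `image_frame`.
#' @param t_s optional timestamp (s) attached to the field (time of
#'   `frame_b`), used downstream for time binning.
#' @return a `velocity_field`: list with `vectors` (data.frame `x_px`,
#'   `y_px` window centres, `u`, `v` in um/s, `snr`), `dt`, `pixel_size`,
#'   `window_px`, `overlap_px`, `t_s`.
#' @export
piv_field <- function(frame_a, frame_b, window_px = 32L, overlap_px = 16L,
                      dt = 1, pixel_size = NULL, t_s = NA_real_) {
  if (is.null(pixel_size)) {
    pixel_size <- if (inherits(frame_a, "image_frame")) frame_a$pixel_size
    else stop("`pixel_size` required for bare matrices")
  }
  a <- as_intensity(frame_a); b <- as_intensity(frame_b)
  if (!identical(dim(a), dim(b))) stop("frames must have identical shape")
  window_px <- as.integer(window_px); overlap_px <- as.integer(overlap_px)
  if (window_px < 16L) stop("window must be at least 16 px")
  if (overlap_px < 0L || overlap_px >= window_px) {
    stop("overlap must satisfy 0 <= overlap < window")
  }
  if (window_px > min(dim(a))) stop("window larger than the frame")
  if (dt <= 0) stop("dt must be positive")
  step <- window_px - overlap_px
  ys <- seq(1L, nrow(a) - window_px + 1L, by = step)
  xs <- seq(1L, ncol(a) - window_px + 1L, by = step)
  m <- 2L * window_px
  res <- vector("list", length(ys) * length(xs))
  k <- 0L
  for (y0 in ys) for (x0 in xs) {
    k <- k + 1L
    wa <- a[y0:(y0 + window_px - 1L), x0:(x0 + window_px - 1L)]
    wb <- b[y0:(y0 + window_px - 1L), x0:(x0 + window_px - 1L)]
    pk <- corr_peak(wa - mean(wa), wb - mean(wb), m, window_px)
    res[[k]] <- c(x0 - 1L + (window_px - 1) / 2,
                  y0 - 1L + (window_px - 1) / 2,
                  pk)
  }
  tab <- do.call(rbind, res)
  vec <- data.frame(x_px = tab[, 1L], y_px = tab[, 2L],
                    u = tab[, 3L] * pixel_size / dt,
                    v = tab[, 4L] * pixel_size / dt,
                    snr = tab[, 5L])
  structure(list(vectors = vec, dt = dt, pixel_size = pixel_size,
                 window_px = window_px, overlap_px = overlap_px, t_s = t_s),
            class = "velocity_field")
}

# cross-correlate two zero-mean windows; return c(dx, dy, snr), where
# (dx, dy) is the displacement of the scene from window a to window b
# (b[y, x] ~= a[y - dy, x - dx]).
corr_peak <- function(wa, wb, m, window_px) {
  A <- matrix(0, m, m); B <- matrix(0, m, m)
  A[1:window_px, 1:window_px] <- wa
  B[1:window_px, 1:window_px] <- wb
  C <- Re(stats::fft(stats::fft(B) * Conj(stats::fft(A)), inverse = TRUE)) / m^2
  # displacement grid: index i (1-based) corresponds to shift i-1 mod m
  half <- window_px %/% 2L
  shift_of <- function(i) ifelse(i - 1L > m %/% 2L, i - 1L - m, i - 1L)
  dy_all <- shift_of(seq_len(m)); dx_all <- shift_of(seq_len(m))
  valid_y <- abs(dy_all) <= half; valid_x <- abs(dx_all) <= half
  Cv <- C; Cv[!valid_y, ] <- -Inf; Cv[, !valid_x] <- -Inf
  p <- which(Cv == max(Cv), arr.ind = TRUE)[1L, ]
  py <- p[1L]; px <- p[2L]
  c1 <- C[py, px]
  # second peak outside a 3x3 exclusion zone, within the valid shift range
  Cs <- Cv
  ey <- ((py - 2L):(py + 2L) - 1L) %% m + 1L
  ex <- ((px - 2L):(px + 2L) - 1L) %% m + 1L
  Cs[ey, ex] <- -Inf
  c2 <- max(Cs)
  snr <- if (is.finite(c2) && c2 > 0) c1 / c2 else Inf
  at <- function(iy, ix) C[(iy - 1L) %% m + 1L, (ix - 1L) %% m + 1L]
  sub <- function(cm, cp, cc) {
    if (cm > 0 && cp > 0 && cc > 0 && (cc > cm || cc > cp)) {
      d <- (log(cm) - log(cp)) / (2 * (log(cm) + log(cp) - 2 * log(cc)))
      if (is.finite(d) && abs(d) <= 1) d else 0
    } else {
      den <- cm + cp - 2 * cc
      if (den < 0) {
        d <- (cm - cp) / (2 * den)
        if (is.finite(d) && abs(d) <= 1) d else 0
      } else 0
    }
  }
  ddy <- sub(at(py - 1L, px), at(py + 1L, px), c1)
  ddx <- sub(at(py, px - 1L), at(py, px + 1L), c1)
  c(shift_of(px) + ddx, shift_of(py) + ddy, snr)
}

#' Filter PIV vectors by magnitude and signal-to-noise ratio
#'
#' Keeps vectors with non-zero magnitude that pass the first-to-second
#' correlation peak ratio test.
#'
#' @param field a `velocity_field`.
#' @param snr_min minimum SNR (>= 1; default 1.3).
#' @return the field with `vectors` subset.
#' @export
filter_vectors <- function(field, snr_min = 1.3) {
  stopifnot(inherits(field, "velocity_field"))
  if (snr_min < 1) stop("snr_min must be >= 1")
  v <- field$vectors
  speed <- sqrt(v$u^2 + v$v^2)
  field$vectors <- v[speed > 0 & v$snr >= snr_min, , drop = FALSE]
  field
}

#' Radial velocity component relative to the ablation site
#'
#' For each vector at location `p`, projects the velocity onto the unit
#' vector pointing away from the ablation site: positive values are recoil
#' away from the cut, negative values are movement toward it (repair).
#' Vectors exactly at the ablation site are skipped.
#'
#' @param field a `velocity_field`.
#' @param event an `ablation_event` (site within the frame).
#' @param t_s time after ablation end (s); defaults to
#'   `field$t_s - event$end_s`.
#' @return data.frame of radial records: `t_s`, `d_um`, `v_rad_um_s`,
#'   `snr`, `x_px`, `y_px`.
#' @export
radial_velocity <- function(field, event, t_s = NULL) {
  stopifnot(inherits(field, "velocity_field"),
            inherits(event, "ablation_event"))
  v <- field$vectors
  if (is.null(t_s)) {
    t_s <- if (is.finite(field$t_s)) field$t_s - event$end_s else NA_real_
  }
  rx <- v$x_px - event$point[1L]
  ry <- v$y_px - event$point[2L]
  rn <- sqrt(rx^2 + ry^2)
  keep <- rn > 0
  rx <- rx[keep] / rn[keep]; ry <- ry[keep] / rn[keep]
  data.frame(t_s = rep(t_s, sum(keep)),
             d_um = rn[keep] * field$pixel_size,
             v_rad_um_s = v$u[keep] * rx + v$v[keep] * ry,
             snr = v$snr[keep],
             x_px = v$x_px[keep], y_px = v$y_px[keep])
}

#' Distance/time binned radial velocity with bootstrap CIs
#'
#' Bins radial records into distance (um) and time (s) bins and reports the
#' mean radial velocity per bin with a seeded percentile bootstrap CI of
#' the mean. Empty bins are kept and flagged (`n = 0`, NA mean).
#'
#' @param records data.frame from [radial_velocity()] (possibly several
#'   rbind-ed fields).
#' @param distance_bins_um bin width (scalar, default 1) or explicit edges.
#' @param time_bins_s bin width or edges; `NULL` collapses time.
#' @param ci_level CI level (default 0.99).
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed integer seed.
#' @return data.frame with bin edges, `n`, `mean_v`, `ci_lo`, `ci_hi`.
#' @export
summarize_radial <- function(records, distance_bins_um = 1,
                             time_bins_s = NULL, ci_level = 0.99,
                             n_boot = 2000L, seed = 1L) {
  if (!nrow(records)) stop("no radial records to summarise")
  dedges <- bin_edges(records$d_um, distance_bins_um, origin = 0)
  tedges <- if (is.null(time_bins_s)) {
    range(records$t_s, na.rm = TRUE) + c(-1e-9, 1e-9)
  } else {
    bin_edges(records$t_s, time_bins_s)
  }
  di <- cut(records$d_um, dedges, include.lowest = TRUE, labels = FALSE)
  ti <- cut(records$t_s, tedges, include.lowest = TRUE, labels = FALSE)
  out <- expand.grid(d_bin = seq_len(length(dedges) - 1L),
                     t_bin = seq_len(length(tedges) - 1L))
  res <- lapply(seq_len(nrow(out)), function(i) {
    sel <- which(di == out$d_bin[i] & ti == out$t_bin[i])
    vv <- records$v_rad_um_s[sel]
    if (length(vv) >= 2L) {
      ci <- bootstrap_ci_mean(vv, level = ci_level, n_boot = n_boot,
                              seed = seed + i)
      c(length(vv), mean(vv), ci$lo, ci$hi)
    } else if (length(vv) == 1L) {
      c(1, vv, NA_real_, NA_real_)
    } else {
      c(0, NA_real_, NA_real_, NA_real_)
    }
  })
  res <- do.call(rbind, res)
  data.frame(d_lo = dedges[out$d_bin], d_hi = dedges[out$d_bin + 1L],
             t_lo = tedges[out$t_bin], t_hi = tedges[out$t_bin + 1L],
             n = res[, 1L], mean_v = res[, 2L],
             ci_lo = res[, 3L], ci_hi = res[, 4L])
}

bin_edges <- function(x, bins, origin = NULL) {
  if (length(bins) > 1L) return(as.numeric(bins))
  lo <- if (is.null(origin)) floor(min(x) / bins) * bins else origin
  hi <- max(x)
  edges <- seq(lo, hi + bins, by = bins)
  edges
}

#' Top fraction of PIV vectors by speed
#'
#' Vectors with speed at or above the `(1 - q)` quantile of the field's
#' speeds; ties at the threshold are included. `q = 0.1` reproduces the
#' "top 10% velocity vectors per PIV timepoint" selection.
#'
#' @param field a `velocity_field`.
#' @param q fraction in (0, 1].
#' @return the field with `vectors` subset.
#' @export
top_fraction <- function(field, q = 0.1) {
  stopifnot(inherits(field, "velocity_field"))
  if (q <= 0 || q > 1) stop("q must be in (0, 1]")
  v <- field$vectors
  if (!nrow(v)) return(field)
  speed <- sqrt(v$u^2 + v$v^2)
  thr <- stats::quantile(speed, probs = 1 - q, names = FALSE, type = 7)
  field$vectors <- v[speed >= thr, , drop = FALSE]
  field
}

#' Resample a time-lapse onto a coarser regular grid
#'
#' Keeps, for each point of the resampling grid, the frame with the nearest
#' timestamp (original timestamps are preserved; no frame is duplicated).
#' Mirrors the published 3-second resampling of ablation series.
#'
#' @param stack a `time_lapse`.
#' @param interval_s resampling interval; must be at least the native
#'   (minimum) frame interval.
#' @return a `time_lapse` with the selected frames.
#' @export
resample_stack <- function(stack, interval_s) {
  stopifnot(inherits(stack, "time_lapse"))
  native <- min(diff(stack$times))
  if (interval_s < native - 1e-9) {
    stop("resampling interval is smaller than the native frame interval")
  }
  grid <- seq(stack$times[1L], max(stack$times), by = interval_s)
  sel <- unique(vapply(grid, function(g) which.min(abs(stack$times - g)),
                       integer(1)))
  time_lapse(stack$frames[sel], stack$pixel_size, stack$times[sel])
}

#' Binary mask from the summed pre-ablation frames
#'
#' Sums all frames acquired strictly before the ablation start, applies
#' 3-class multi-Otsu thresholding to the sum, and returns the union of the
#' classes above background. Restricting PIV to this mask confines vectors
#' to the cellularization structures.
#'
#' @param stack a `time_lapse`.
#' @param event an `ablation_event`.
#' @return logical matrix mask.
#' @export
preablation_mask <- function(stack, event) {
  stopifnot(inherits(stack, "time_lapse"), inherits(event, "ablation_event"))
  pre <- which(stack$times < event$start_s)
  if (!length(pre)) stop("no pre-ablation frames")
  s <- Reduce(`+`, stack$frames[pre])
  if (diff(range(s)) == 0) {
    stop("pre-ablation sum is constant: mask undefined (empty-mask flag)")
  }
  thr <- otsu_thresholds(s, n_classes = 3L)
  s > thr[1L]
}

#' Kymograph along a line segment
#'
#' Projects each frame onto positions along a segment, summing intensity
#' across a band of `width_px` normal to it (sum, matching the published
#' kymographs). Rows are time, columns are position along the segment.
#'
#' @param stack a `time_lapse`.
#' @param line_segment list or matrix giving the endpoints `p0`, `p1`
#'   as `(x, y)` px.
#' @param width_px band width across the segment (default 20).
#' @return an `image_frame` whose rows are frames (timestamps in
#'   `attr(, "times")`) and whose columns step 1 px along the segment.
#' @export
kymograph <- function(stack, line_segment, width_px = 20) {
  stopifnot(inherits(stack, "time_lapse"))
  seg <- as_segment(line_segment)
  prof <- band_geometry(seg, width_px, dim(stack$frames[[1L]]))
  rows <- lapply(stack$frames, function(f) {
    band_reduce(f, prof, sum)
  })
  out <- do.call(rbind, rows)
  fr <- image_frame(out, stack$pixel_size, stack$times[1L])
  attr(fr, "times") <- stack$times
  fr
}

#' Receding-tip distance series after furrow ablation
#'
#' For each frame: the mean (not sum) intensity profile across a
#' `width_px`-wide band along the ablated furrow, peak detection, and the
#' separation of the two most prominent peaks in micrometres. Frames
#' without exactly two confident peaks are flagged (`ok = FALSE`) and
#' should be excluded from recoil fits.
#'
#' @param stack a `time_lapse`.
#' @param line_segment endpoints `p0`, `p1` as `(x, y)` px.
#' @param width_px band width (default 10, the published tip-profile width).
#' @param min_prominence_frac,min_distance_um passed to [detect_peaks()].
#' @return a `tip_distance_series`: data.frame `t_s`, `distance_um`, `ok`,
#'   `n_peaks`.
#' @export
tip_distance_series <- function(stack, line_segment, width_px = 10,
                                min_prominence_frac = 0.2,
                                min_distance_um = 0.5) {
  stopifnot(inherits(stack, "time_lapse"))
  seg <- as_segment(line_segment)
  prof_geom <- band_geometry(seg, width_px, dim(stack$frames[[1L]]))
  rows <- lapply(seq_along(stack$frames), function(i) {
    vals <- band_reduce(stack$frames[[i]], prof_geom, mean)
    pos <- (seq_along(vals) - 1) * stack$pixel_size
    pr <- intensity_profile(pos, vals, periodic = FALSE)
    pk <- tryCatch(detect_peaks(pr, min_prominence_frac, min_distance_um),
                   error = function(e) NULL)
    npk <- if (is.null(pk)) 0L else length(pk$positions)
    if (npk >= 2L) {
      top2 <- order(-pk$prominences)[1:2]
      d <- abs(diff(pk$positions[top2]))
      data.frame(t_s = stack$times[i], distance_um = d,
                 ok = npk == 2L, n_peaks = npk)
    } else {
      data.frame(t_s = stack$times[i], distance_um = NA_real_,
                 ok = FALSE, n_peaks = npk)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("tip_distance_series", class(out))
  out
}

#' Fit the single-exponential tip-recoil model
#'
#' Least-squares fit of `D(t) = D0 + A * (1 - exp(-t / tau))` to the
#' usable (`ok`) frames of a tip distance series, with time measured from
#' the first usable frame.
#'
#' @param series a `tip_distance_series` (or data.frame with `t_s`,
#'   `distance_um`, `ok`).
#' @return list with `D0`, `A`, `tau` (and `fitted` values).
#' @export
fit_tip_recoil <- function(series) {
  s <- series[series$ok & is.finite(series$distance_um), , drop = FALSE]
  if (nrow(s) < 4L) stop("need at least 4 usable frames to fit the recoil")
  t <- s$t_s - s$t_s[1L]
  D <- s$distance_um
  obj <- function(par) {
    D0 <- par[1L]; A <- par[2L]; tau <- exp(par[3L])
    sum((D - (D0 + A * (1 - exp(-t / tau))))^2)
  }
  init <- c(D[1L], max(D[length(D)] - D[1L], 1e-3),
            log(max(diff(range(t)) / 3, 1e-2)))
  op <- stats::optim(init, obj, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12))
  D0 <- op$par[1L]; A <- op$par[2L]; tau <- exp(op$par[3L])
  list(D0 = D0, A = A, tau = tau,
       fitted = D0 + A * (1 - exp(-t / tau)), t = t, observed = D)
}

# --- band geometry helpers ---------------------------------------------

as_segment <- function(line_segment) {
  if (is.list(line_segment)) {
    p0 <- as.numeric(line_segment[[1L]]); p1 <- as.numeric(line_segment[[2L]])
  } else {
    m <- as.matrix(line_segment)
    p0 <- as.numeric(m[1L, ]); p1 <- as.numeric(m[2L, ])
  }
  if (sqrt(sum((p1 - p0)^2)) == 0) stop("degenerate line segment")
  list(p0 = p0, p1 = p1)
}

# sample coordinates for a band of width_px centred on the segment,
# 1-px spacing along and across; errors if the band exits the frame
band_geometry <- function(seg, width_px, dm) {
  d <- seg$p1 - seg$p0
  len <- sqrt(sum(d^2))
  u <- d / len
  nvec <- c(-u[2L], u[1L])
  npos <- floor(len) + 1L
  along <- seq(0, len, length.out = npos)
  across <- seq(-(width_px - 1) / 2, (width_px - 1) / 2,
                length.out = max(1L, round(width_px)))
  xs <- outer(along, across, function(a, s) seg$p0[1L] + a * u[1L] + s * nvec[1L])
  ys <- outer(along, across, function(a, s) seg$p0[2L] + a * u[2L] + s * nvec[2L])
  if (min(xs) < 0 || max(xs) > dm[2L] - 1 || min(ys) < 0 || max(ys) > dm[1L] - 1) {
    stop("band exits the frame")
  }
  list(xs = xs, ys = ys, npos = npos)
}

band_reduce <- function(frame, geom, fun) {
  v <- bilinear_sample(frame, as.numeric(geom$xs), as.numeric(geom$ys))
  apply(matrix(v, nrow = geom$npos), 1L, fun)
}
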