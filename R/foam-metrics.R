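# Daughter-cell size estimation from membrane intensity peaks along a
# concentric ellipse, and actin-network texture dynamics via the Haralick
# Angular Second Moment (ASM).

#' Detect intensity peaks in a profile
#'
#' Local maxima with prominence at least `min_prominence_frac` of the
#' profile's dynamic range and pairwise spacing at least `min_distance_um`
#' (peaks are pruned greedily in order of decreasing height). For periodic
#' profiles the wrap-around neighbourhood is honoured both for prominence
#' and for spacing.
#'
#' @param profile an `intensity_profile` (>= 8 samples).
#' @param min_prominence_frac prominence threshold as a fraction of
#'   `max - min` (default 0.1).
#' @param min_distance_um minimum peak spacing in micrometres (default 1).
#' @return a `peak_set`: list with `positions` (um, sorted), `values`,
#'   `prominences`, `periodic`, `length_um`.
#' @export
detect_peaks <- function(profile, min_prominence_frac = 0.1,
                         min_distance_um = 1) {
  stopifnot(inherits(profile, "intensity_profile"))
  v <- profile$values; pos <- profile$positions
  n <- length(v)
  if (n < 8L) stop("profile too short for peak detection")
  rng <- diff(range(v))
  empty <- function() structure(
    list(positions = numeric(0), values = numeric(0),
         prominences = numeric(0), periodic = profile$periodic,
         length_um = profile$length_um), class = "peak_set")
  if (rng == 0) return(empty())
  if (profile$periodic) {
    # triple-tile and analyse the middle copy so wrap-around is natural
    L <- profile$length_um
    vv <- c(v, v, v)
    pp <- c(pos - L, pos, pos + L)
    keep <- (n + 1L):(2L * n)
  } else {
    vv <- v; pp <- pos; keep <- seq_len(n)
  }
  cand <- which(diff(sign(diff(vv))) < 0) + 1L
  cand <- cand[cand %in% keep]
  if (!length(cand)) return(empty())
  prom <- vapply(cand, function(i) peak_prominence(vv, i), numeric(1))
  sel <- prom >= min_prominence_frac * rng
  cand <- cand[sel]; prom <- prom[sel]
  if (!length(cand)) return(empty())
  # enforce minimum spacing, strongest first
  o <- order(-vv[cand])
  cand <- cand[o]; prom <- prom[o]
  kept <- integer(0); kprom <- numeric(0)
  for (i in seq_along(cand)) {
    d <- abs(pp[cand[i]] - pp[kept])
    if (profile$periodic && length(d)) {
      d <- pmin(d, profile$length_um - d)
    }
    if (!length(kept) || all(d >= min_distance_um)) {
      kept <- c(kept, cand[i]); kprom <- c(kprom, prom[i])
    }
  }
  o <- order(pp[kept])
  kept <- kept[o]; kprom <- kprom[o]
  # sub-sample refinement: vertex of the parabola through the peak and its
  # two neighbours (general, non-uniform abscissae)
  refine <- vapply(kept, function(i) {
    if (i <= 1L || i >= length(vv)) return(pp[i])
    x <- pp[(i - 1L):(i + 1L)]; y <- vv[(i - 1L):(i + 1L)]
    co <- tryCatch(solve(cbind(1, x, x^2), y), error = function(e) NULL)
    if (is.null(co) || co[3L] >= 0) return(pp[i])
    xv <- -co[2L] / (2 * co[3L])
    if (xv >= x[1L] && xv <= x[3L]) xv else pp[i]
  }, numeric(1))
  if (profile$periodic) refine <- refine %% profile$length_um
  o2 <- order(refine)
  structure(list(positions = refine[o2], values = vv[kept][o2],
                 prominences = kprom[o2], periodic = profile$periodic,
                 length_um = profile$length_um),
            class = "peak_set")
}

# topographic prominence of the peak at index i of v
peak_prominence <- function(v, i) {
  h <- v[i]
  left <- if (i > 1L) v[seq_len(i - 1L)] else numeric(0)
  right <- if (i < length(v)) v[(i + 1L):length(v)] else numeric(0)
  # walk outward: stretch until the first strictly higher point
  lb <- {
    s <- rev(left); higher <- which(s > h)
    stretch <- if (length(higher)) s[seq_len(higher[1L] - 1L)] else s
    if (length(stretch)) min(stretch) else h
  }
  rb <- {
    s <- right; higher <- which(s > h)
    stretch <- if (length(higher)) s[seq_len(higher[1L] - 1L)] else s
    if (length(stretch)) min(stretch) else h
  }
  h - max(lb, rb)
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peaks%s\n", length(x$positions),
              if (x$periodic) sprintf(" on a %.3g um periodic profile",
                                      x$length_um) else ""))
  invisible(x)
}

#' Peak-to-peak spacings as daughter diameters
#'
#' Consecutive spacings between membrane intensity peaks, the proxy for
#' daughter-cell diameter. For periodic profiles the closing (wrap-around)
#' gap is included, so the number of spacings equals the number of peaks
#' and the spacings sum exactly to the profile length.
#'
#' @param peaks a `peak_set` with at least 2 peaks.
#' @return numeric vector of spacings in micrometres.
#' @export
daughter_diameters <- function(peaks) {
  stopifnot(inherits(peaks, "peak_set"))
  p <- peaks$positions
  if (length(p) < 2L) stop("need at least 2 peaks for spacings")
  d <- diff(p)
  if (peaks$periodic) {
    d <- c(d, peaks$length_um - (p[length(p)] - p[1L]))
  }
  d
}

#' Coefficient of variation
#'
#' `100 * sample SD / mean`, in percent; the statistic used to summarise
#' zoospore diameter uniformity.
#'
#' @param values numeric vector, `n >= 2`, positive mean.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  if (m <= 0) stop("mean must be positive for a CV")
  100 * stats::sd(values) / m
}

#' Haralick Angular Second Moment of a frame
#'
#' Quantises intensities to `n_levels` gray levels (rank-based equal-count
#' binning by default, making the statistic invariant to affine intensity
#' rescaling), accumulates a symmetric normalised gray-level co-occurrence
#' matrix at the given pixel offset(s), and returns the Angular Second
#' Moment `sum(P^2)`. With several offsets the per-offset ASM values are
#' averaged (the usual direction-averaged Haralick convention). Masked-out
#' pixels are excluded from pair counting.
#'
#' @param frame `image_frame` or matrix.
#' @param offsets either a 2-column matrix of `(dy, dx)` pixel offsets or
#'   the default four unit offsets at 0, 45, 90, 135 degrees.
#' @param n_levels number of gray levels (>= 2, default 8).
#' @param quantize `"rank"` (equal-count, default) or `"range"`
#'   (equal-width).
#' @param mask optional logical matrix; `FALSE` pixels are excluded.
#' @param breaks optional fixed bin edges overriding `quantize`; use the
#'   same edges across the frames of a time series so that homogeneity
#'   changes (histogram concentration) are not normalised away.
#' @return ASM in (0, 1].
#' @export
glcm_asm <- function(frame, offsets = NULL, n_levels = 8L,
                     quantize = c("rank", "range"), mask = NULL,
                     breaks = NULL) {
  quantize <- match.arg(quantize)
  img <- as_intensity(frame)
  if (is.null(offsets)) {
    offsets <- rbind(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  }
  offsets <- matrix(as.integer(offsets), ncol = 2L)
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop("need at least 2 gray levels")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  lev <- quantize_levels(img[mask], n_levels, quantize, breaks)
  levmat <- matrix(NA_integer_, nrow(img), ncol(img))
  levmat[mask] <- lev
  asms <- apply(offsets, 1L, function(off) {
    glcm_asm_one(levmat, off[1L], off[2L], n_levels)
  })
  if (all(is.na(asms))) stop("fewer than 2 valid pixel pairs")
  mean(asms, na.rm = TRUE)
}

quantize_levels <- function(v, n_levels, quantize, breaks = NULL) {
  if (!length(v)) stop("no pixels to quantise")
  if (!is.null(breaks)) {
    return(as.integer(pmin(pmax(findInterval(v, breaks, all.inside = TRUE),
                                1L), n_levels)))
  }
  if (diff(range(v)) == 0) return(rep(1L, length(v)))
  if (quantize == "rank") {
    # equal-count bins; ties share one bin (midrank), so discrete inputs
    # with k <= n_levels distinct values keep exactly k bins
    as.integer(pmin(pmax(ceiling(rank(v, ties.method = "average") *
                                   n_levels / length(v)), 1L), n_levels))
  } else {
    br <- seq(min(v), max(v), length.out = n_levels + 1L)
    as.integer(findInterval(v, br, all.inside = TRUE))
  }
}

glcm_asm_one <- function(levmat, dy, dx, n_levels) {
  a <- levmat
  b <- shift_mat(levmat, -dy, -dx, NA_integer_)  # b[p] = levmat[p + (dy,dx)]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2L) return(NA_real_)
  code <- (a[ok] - 1L) * n_levels + b[ok]
  counts <- tabulate(code, nbins = n_levels^2)
  P <- matrix(counts, n_levels, n_levels, byrow = TRUE)
  P <- P + t(P)            # symmetric GLCM
  P <- P / sum(P)
  sum(P^2)
}

#' Texture series relative to a reference time point
#'
#' Divides a series of ASM values by the value at `reference_index` (the
#' frame right before treatment), so the reference maps to exactly 1 and a
#' value of 1.75 reads as a 75% increase in homogeneity.
#'
#' @param asm numeric vector of ASM values in (0, 1].
#' @param reference_index index of the reference time point.
#' @param times optional times in minutes (default frame index - 1).
#' @return a `texture_series`: list with `times`, `asm`,
#'   `reference_index`, `relative`.
#' @export
relative_homogeneity <- function(asm, reference_index, times = NULL) {
  asm <- as.numeric(asm)
  reference_index <- as.integer(reference_index)
  if (reference_index < 1L || reference_index > length(asm)) {
    stop("reference index out of range")
  }
  if (!is.finite(asm[reference_index]) || asm[reference_index] <= 0) {
    stop("reference ASM must be positive")
  }
  if (any(asm <= 0 | asm > 1, na.rm = TRUE)) {
    stop("ASM values must lie in (0, 1]")
  }
  if (is.null(times)) times <- seq_along(asm) - 1
  structure(list(times = as.numeric(times), asm = asm,
                 reference_index = reference_index,
                 relative = asm / asm[reference_index]),
            class = "texture_series")
}

#' ASM texture series for a whole stack
#'
#' Computes the Haralick ASM of every frame and the relative homogeneity
#' with respect to `reference_index` (the frame right before treatment).
#' All frames are quantised with one fixed set of bin edges derived from
#' the reference frame (equal-count bins on its intensities): per-frame
#' re-normalisation would stretch whatever residual variation a dissolved
#' network has across all gray levels and hide the homogenisation the
#' statistic is meant to report.
#'
#' @param stack a `time_lapse`.
#' @param reference_index reference frame (right before treatment).
#' @param n_levels gray levels (default 8).
#' @param ... passed to [glcm_asm()].
#' @return a `texture_series` with times in minutes.
#' @export
stack_texture_series <- function(stack, reference_index, n_levels = 8L, ...) {
  stopifnot(inherits(stack, "time_lapse"))
  reference_index <- as.integer(reference_index)
  if (reference_index < 1L || reference_index > length(stack$frames)) {
    stop("reference index out of range")
  }
  ref <- as.numeric(stack$frames[[reference_index]])
  # equal-width bins over the reference range: as a network dissolves its
  # intensity spread shrinks, concentrating mass into fewer fixed bins
  br <- seq(min(ref), max(ref), length.out = n_levels + 1L)
  asm <- vapply(stack$frames, function(f) {
    glcm_asm(f, n_levels = n_levels, breaks = br, ...)
  }, numeric(1))
  relative_homogeneity(asm, reference_index, times = stack$times / 60)
}
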