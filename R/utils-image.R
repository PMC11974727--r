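# Low-level raster utilities shared by the geometry, segmentation and
# synthetic-imaging code. All functions take plain matrices; physical units
# are handled by the callers.

#' Bilinear interpolation of a matrix at fractional pixel coordinates
#'
#' Coordinates follow the package convention: 0-based, `x` along columns,
#' `y` along rows, pixel centres at integers. Samples outside the image
#' support return `fill`.
#'
#' @param img numeric matrix.
#' @param x,y numeric vectors of equal length, 0-based pixel coordinates.
#' @param fill value for samples outside the image (default 0).
#' @return numeric vector of interpolated intensities, same length as `x`.
#' @export
bilinear_sample <- function(img, x, y, fill = 0) {
  stopifnot(is.matrix(img), length(x) == length(y))
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0;  fy <- y - y0
  # clamp integer corners; validity decided before clamping
  inside <- x >= 0 & x <= nc - 1 & y >= 0 & y <= nr - 1
  x0c <- pmin(pmax(x0, 0), nc - 1); x1c <- pmin(x0c + 1, nc - 1)
  y0c <- pmin(pmax(y0, 0), nr - 1); y1c <- pmin(y0c + 1, nr - 1)
  i00 <- y0c + 1 + nr * x0c
  i01 <- y0c + 1 + nr * x1c
  i10 <- y1c + 1 + nr * x0c
  i11 <- y1c + 1 + nr * x1c
  v <- (1 - fy) * ((1 - fx) * img[i00] + fx * img[i01]) +
       fy       * ((1 - fx) * img[i10] + fx * img[i11])
  v[!inside] <- fill
  v
}

#' Separable Gaussian blur
#'
#' Convolves a matrix with an isotropic Gaussian kernel (replicated edges).
#' Used both as the synthetic PSF and for pre-smoothing in segmentation.
#'
#' @param img numeric matrix.
#' @param sigma Gaussian standard deviation in pixels; `sigma <= 0` returns
#'   the input unchanged.
#' @return blurred matrix of the same dimension.
#' @export
gaussian_blur <- function(img, sigma) {
  stopifnot(is.matrix(img))
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  img <- conv1_cols(img, k)
  t(conv1_cols(t(img), k))
}

# 1D convolution down each column with replicate padding, vectorised over
# kernel taps.
conv1_cols <- function(img, k) {
  nr <- nrow(img)
  r <- (length(k) - 1L) %/% 2L
  pad_top <- img[rep(1L, r), , drop = FALSE]
  pad_bot <- img[rep(nr, r), , drop = FALSE]
  p <- rbind(pad_top, img, pad_bot)
  out <- matrix(0, nr, ncol(img))
  for (j in seq_along(k)) {
    out <- out + k[j] * p[j:(j + nr - 1L), , drop = FALSE]
  }
  out
}

#' Multi-level Otsu thresholds
#'
#' Exhaustive maximisation of the between-class variance over `n_classes - 1`
#' thresholds of a 256-bin histogram (the classic multi-Otsu criterion).
#'
#' @param img numeric matrix or vector of intensities.
#' @param n_classes number of classes (2 or 3 supported; default 3).
#' @param n_bins histogram resolution (default 256).
#' @return numeric vector of `n_classes - 1` thresholds on the intensity
#'   scale of `img` (upper edges of the lower classes).
#' @export
otsu_thresholds <- function(img, n_classes = 3L, n_bins = 256L) {
  v <- as.numeric(img)
  v <- v[is.finite(v)]
  if (!length(v)) stop("no finite intensities")
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stop("constant image: thresholds undefined")
  n_classes <- as.integer(n_classes)
  if (!n_classes %in% c(2L, 3L)) stop("n_classes must be 2 or 3")
  h <- tabulate(pmin(pmax(floor((v - lo) / (hi - lo) * n_bins) + 1L, 1L),
                     n_bins), nbins = n_bins)
  p <- h / sum(h)
  mids <- lo + (seq_len(n_bins) - 0.5) / n_bins * (hi - lo)
  cw <- cumsum(p)           # class weight up to bin k
  cm <- cumsum(p * mids)    # class first moment up to bin k
  tot <- cm[n_bins]
  seg_stat <- function(a, b) { # between-class contribution of bins a..b
    cwa <- ifelse(a > 1L, cw[pmax(a - 1L, 1L)], 0)
    cma <- ifelse(a > 1L, cm[pmax(a - 1L, 1L)], 0)
    w <- cw[b] - cwa
    m <- cm[b] - cma
    ifelse(w > 0, m^2 / w, 0)
  }
  if (n_classes == 2L) {
    ks <- 1:(n_bins - 1L)
    crit <- seg_stat(1L, ks) + seg_stat(ks + 1L, n_bins)
    k <- ks[which.max(crit)]
    return(mids[k])
  }
  # 3 classes: scan threshold pairs (vectorised inner loop)
  best <- -Inf; bk <- c(1L, 2L)
  for (k1 in 1:(n_bins - 2L)) {
    k2 <- (k1 + 1L):(n_bins - 1L)
    crit <- seg_stat(1L, k1) + seg_stat(k1 + 1L, k2) + seg_stat(k2 + 1L, n_bins)
    i <- which.max(crit)
    if (crit[i] > best) { best <- crit[i]; bk <- c(k1, k2[i]) }
  }
  mids[bk]
}

#' Exact Euclidean distance transform
#'
#' Felzenszwalb-Huttenlocher separable squared-distance transform. Returns,
#' for every pixel, the Euclidean distance (in pixels) to the nearest
#' background (`FALSE`) pixel.
#'
#' @param mask logical matrix; `TRUE` = foreground.
#' @return numeric matrix of distances (0 on background).
#' @export
distance_transform <- function(mask) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  m <- matrix(ifelse(mask, Inf, 0), nrow(mask), ncol(mask))
  m <- apply(m, 2L, edt_1d)
  m <- t(apply(m, 1L, edt_1d))
  sqrt(m)
}

# 1D squared distance transform (lower envelope of parabolas); infinite
# entries carry no parabola of their own
edt_1d <- function(f) {
  n <- length(f)
  sites <- which(is.finite(f))
  if (!length(sites)) return(rep(Inf, n))
  d <- numeric(n); v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- sites[1L]; z[1L] <- -Inf; z[2L] <- Inf
  for (q in sites[-1L]) {
    s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
    while (s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
    }
    k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Connected components of a binary mask
#'
#' Iterative minimum-label propagation over the 4-neighbourhood.
#'
#' @param mask logical matrix.
#' @return integer matrix of labels (0 = background), labelled 1..n in
#'   raster order of their smallest member pixel.
#' @export
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- which(mask)
  repeat {
    nb <- pmin(shift_mat(lab, 1L, 0L, Inf), shift_mat(lab, -1L, 0L, Inf))
    nb <- pmin(nb, shift_mat(lab, 0L, 1L, Inf), shift_mat(lab, 0L, -1L, Inf))
    cand <- pmin(lab, nb)
    cand[!mask] <- 0
    if (all(cand == lab)) break
    lab <- cand
  }
  # relabel consecutively
  u <- sort(unique(lab[lab > 0]))
  out <- matrix(0L, nr, nc)
  out[lab > 0] <- match(lab[lab > 0], u)
  out
}

# shift matrix by (dy, dx) filling vacated cells with `fill`
shift_mat <- function(m, dy, dx, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ys <- seq_len(nr); xs <- seq_len(nc)
  ysrc <- ys - dy; xsrc <- xs - dx
  keep_y <- ysrc >= 1 & ysrc <= nr; keep_x <- xsrc >= 1 & xsrc <= nc
  out[ys[keep_y], xs[keep_x]] <- m[ysrc[keep_y], xsrc[keep_x]]
  out
}

#' Local maxima of an image with a minimum separation
#'
#' A pixel is a candidate if it attains the maximum of its (2r+1)^2
#' neighbourhood (r = `min_distance_px`); candidates closer than the minimum
#' separation are pruned greedily in order of decreasing intensity.
#'
#' @param img numeric matrix.
#' @param min_distance_px minimum separation between reported maxima.
#' @param threshold minimum intensity for a maximum (default `-Inf`).
#' @return data.frame with 0-based columns `x`, `y` and `value`.
#' @export
local_maxima <- function(img, min_distance_px = 5, threshold = -Inf) {
  r <- max(1L, floor(min_distance_px))
  dil <- img
  for (dy in -r:r) {
    sh <- shift_mat(img, dy, 0L, -Inf)
    dil <- pmax(dil, sh)
  }
  dil2 <- dil
  for (dx in -r:r) {
    sh <- shift_mat(dil, 0L, dx, -Inf)
    dil2 <- pmax(dil2, sh)
  }
  cand <- which(img >= dil2 & img >= threshold, arr.ind = TRUE)
  if (!nrow(cand)) {
    return(data.frame(x = numeric(0), y = numeric(0), value = numeric(0)))
  }
  val <- img[cand]
  o <- order(-val)
  cand <- cand[o, , drop = FALSE]; val <- val[o]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1L) { keep[1L] <- TRUE; next }
    prev <- cand[keep, , drop = FALSE]
    d2 <- (prev[, 1L] - cand[i, 1L])^2 + (prev[, 2L] - cand[i, 2L])^2
    keep[i] <- all(d2 >= min_distance_px^2)
  }
  cand <- cand[keep, , drop = FALSE]; val <- val[keep]
  data.frame(x = cand[, 2L] - 1, y = cand[, 1L] - 1, value = val)
}

#' Marker-controlled watershed
#'
#' Floods a priority image (typically the distance transform) downhill from
#' labelled markers, restricted to a foreground mask: pixels are claimed in
#' order of decreasing priority by label propagation from already-claimed
#' neighbours (8-connectivity). Used to split touching nuclei.
#'
#' @param priority numeric matrix; higher floods first.
#' @param markers integer matrix of seed labels (0 elsewhere).
#' @param mask logical matrix restricting the flood.
#' @param n_levels number of priority quantisation levels (default 64).
#' @return integer label matrix (0 outside `mask`).
#' @export
watershed_labels <- function(priority, markers, mask, n_levels = 64L) {
  stopifnot(identical(dim(priority), dim(markers)),
            identical(dim(priority), dim(mask)))
  lab <- markers
  pr <- priority
  pr[!mask] <- -Inf
  fin <- pr[is.finite(pr)]
  if (!length(fin)) return(lab)
  lv <- rev(seq(min(fin), max(fin), length.out = n_levels))
  nbhd <- function(l) { # best (max-priority-neighbour) label for each pixel
    best <- matrix(0L, nrow(l), ncol(l))
    bestp <- matrix(-Inf, nrow(l), ncol(l))
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      nl <- shift_mat(l, dy, dx, 0L)
      np <- shift_mat(pr, dy, dx, -Inf)
      upd <- nl > 0L & np > bestp
      best[upd] <- nl[upd]; bestp[upd] <- np[upd]
    }
    best
  }
  for (level in lv) {
    repeat {
      active <- mask & lab == 0L & pr >= level
      if (!any(active)) break
      nb <- nbhd(lab)
      claim <- active & nb > 0L
      if (!any(claim)) break
      lab[claim] <- nb[claim]
    }
  }
  # unreached foreground (isolated from all markers) keeps label 0
  lab[!mask] <- 0L
  lab
}
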