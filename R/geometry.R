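# Ellipse geometry shared by every downstream analysis: direct least-squares
# ellipse fitting, concentric ("scaled") ellipses, the elliptical radius of a
# point, polar unwrapping, band line-scans, and Plateau vertex-angle
# metrology.

#' Ellipse model
#'
#' Container for a fitted sporangium perimeter ellipse: centre (px, 0-based
#' image coordinates), semi-axes `a >= b > 0` (px) and orientation `theta`
#' of the major axis in radians within `[0, pi)`.
#'
#' @param cx,cy centre, pixels.
#' @param a,b semi-major and semi-minor axes, pixels.
#' @param theta orientation of the major axis, radians.
#' @param rms optional fit residual RMS (px), `NA` for constructed ellipses.
#' @return an object of class `ellipse_model`.
#' @export
ellipse_model <- function(cx, cy, a, b, theta = 0, rms = NA_real_) {
  if (!is.finite(a) || !is.finite(b) || b <= 0 || a < b) {
    # allow callers to pass axes in either order
    if (is.finite(a) && is.finite(b) && a > 0 && b > a) {
      tmp <- a; a <- b; b <- tmp
      theta <- theta + pi / 2
    } else if (!(is.finite(a) && is.finite(b) && a >= b && b > 0)) {
      stop("ellipse axes must satisfy a >= b > 0")
    }
  }
  theta <- theta %% pi
  structure(list(cx = as.numeric(cx), cy = as.numeric(cy),
                 a = as.numeric(a), b = as.numeric(b),
                 theta = as.numeric(theta), rms = as.numeric(rms)),
            class = "ellipse_model")
}

#' @export
print.ellipse_model <- function(x, ...) {
  cat(sprintf(
    "<ellipse_model> centre (%.2f, %.2f) px, a = %.2f, b = %.2f px, theta = %.4f rad%s\n",
    x$cx, x$cy, x$a, x$b, x$theta,
    if (is.finite(x$rms)) sprintf(", fit RMS = %.3g px", x$rms) else ""))
  invisible(x)
}

#' Points on an ellipse at given parameter values
#'
#' Parametric form `c + R(theta) %*% (a cos t, b sin t)`. Shared by the
#' fitting oracle, the unwrapping code and the synthetic generators.
#'
#' @param E an `ellipse_model`.
#' @param t numeric vector of parameter values (radians).
#' @param f optional radial scale factor (default 1).
#' @return matrix with columns `x`, `y` (0-based px).
#' @export
ellipse_points <- function(E, t, f = 1) {
  ct <- cos(E$theta); st <- sin(E$theta)
  ex <- f * E$a * cos(t); ey <- f * E$b * sin(t)
  cbind(x = E$cx + ex * ct - ey * st,
        y = E$cy + ex * st + ey * ct)
}

#' Direct least-squares ellipse fit
#'
#' Fits an ellipse to boundary points by the numerically stable direct
#' conic-constrained least-squares method (Halir & Flusser variant of
#' Fitzgibbon's fit). Deterministic, no initialisation; the conic constraint
#' guarantees an ellipse (never a hyperbola) whenever the system is
#' non-degenerate.
#'
#' @param points two-column matrix or data.frame of `x`, `y` pixel
#'   coordinates; at least 6 non-collinear points.
#' @return an `ellipse_model` with the radial residual RMS in `$rms`.
#' @export
fit_ellipse <- function(points) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  if (nrow(pts) < 6L) stop("ellipse fit needs at least 6 points")
  x <- pts[, 1L]; y <- pts[, 2L]
  # collinearity guard
  if (nrow(unique(pts)) < 6L ||
      svd(cbind(x - mean(x), y - mean(y)))$d[2L] < 1e-9 * max(1, sd(x), sd(y))) {
    stop("degenerate (collinear or duplicated) boundary points")
  }
  mx <- mean(x); my <- mean(y); sc <- max(stats::sd(x), stats::sd(y))
  xs <- (x - mx) / sc; ys <- (y - my) / sc
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T2 <- -solve(S3, t(S2))
  M <- S1 + S2 %*% T2
  M <- rbind(M[3L, ] / 2, -M[2L, ], M[1L, ] / 2)
  ev <- eigen(M)
  V <- Re(ev$vectors)
  cond <- 4 * V[1L, ] * V[3L, ] - V[2L, ]^2
  k <- which(cond > 0)
  if (!length(k)) stop("degenerate input: no ellipse solution")
  a1 <- V[, k[1L]]
  coefs <- c(a1, T2 %*% a1)   # A B C D E F in scaled coordinates
  # undo normalisation: substitute xs = (x-mx)/sc etc.
  A <- coefs[1L] / sc^2; B <- coefs[2L] / sc^2; C <- coefs[3L] / sc^2
  D <- coefs[4L] / sc - 2 * A * mx - B * my
  E_ <- coefs[5L] / sc - 2 * C * my - B * mx
  F_ <- coefs[6L] + A * mx^2 + B * mx * my + C * my^2 -
        coefs[4L] * mx / sc - coefs[5L] * my / sc
  den <- B^2 - 4 * A * C
  if (den >= 0) stop("degenerate input: not an ellipse")
  cx <- (2 * C * D - B * E_) / den
  cy <- (2 * A * E_ - B * D) / den
  num <- 2 * (A * E_^2 + C * D^2 - B * D * E_ + den * F_)
  s <- sqrt((A - C)^2 + B^2)
  axa <- -sqrt(num * (A + C + s)) / den
  axb <- -sqrt(num * (A + C - s)) / den
  if (!is.finite(axa) || !is.finite(axb)) stop("degenerate ellipse fit")
  theta <- if (abs(B) < .Machine$double.eps^0.75) {
    if (A <= C) 0 else pi / 2
  } else {
    atan2(C - A - s, B)
  }
  Efit <- ellipse_model(cx, cy, max(axa, axb), min(axa, axb),
                        if (axa >= axb) theta else theta + pi / 2)
  f <- point_radius_factor(pts, Efit)
  Efit$rms <- sqrt(mean(((f - 1) * sqrt((x - cx)^2 + (y - cy)^2))^2))
  Efit
}

#' Scale an ellipse about its centre
#'
#' Returns the concentric ellipse with both radii multiplied by `f` (area
#' scales by `f^2`). `f = 0.70` is the donut/disk boundary used for the
#' cortical nuclear ratio; `f = sqrt(0.5)` is the exact equal-area split;
#' `f = 0.85` is the daughter-size line-scan ellipse.
#'
#' @param E an `ellipse_model`.
#' @param f positive scale factor.
#' @return an `ellipse_model`.
#' @export
scale_ellipse <- function(E, f) {
  stopifnot(inherits(E, "ellipse_model"))
  if (!is.numeric(f) || length(f) != 1L || f <= 0) {
    stop("scale factor must be > 0")
  }
  ellipse_model(E$cx, E$cy, E$a * f, E$b * f, E$theta)
}

#' Elliptical radius factor of points
#'
#' For each point, the factor `f >= 0` such that the point lies on
#' `scale_ellipse(E, f)`; reduces to (distance / radius) for circles. This
#' is the package's definition of "radius" inside an ellipse.
#'
#' @param points two-column matrix/data.frame of `x`, `y` (px).
#' @param E an `ellipse_model`.
#' @return numeric vector of factors.
#' @export
point_radius_factor <- function(points, E) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  dx <- pts[, 1L] - E$cx; dy <- pts[, 2L] - E$cy
  ct <- cos(E$theta); st <- sin(E$theta)
  xr <- dx * ct + dy * st
  yr <- -dx * st + dy * ct
  sqrt((xr / E$a)^2 + (yr / E$b)^2)
}

#' Classify points against a donut/disk partition of an ellipse
#'
#' Points with elliptical radius factor `<= f` are `inner` (disk), factors
#' in `(f, 1]` are `outer` (donut), factors `> 1` are `outside` and are
#' excluded from cortical ratios.
#'
#' @param points two-column matrix/data.frame of `x`, `y` (px).
#' @param E an `ellipse_model`.
#' @param f boundary factor in (0, 1); default 0.70 (the published donut
#'   boundary; `sqrt(0.5)` is the exact equal-area alternative).
#' @return list with integer counts `inner`, `outer`, `outside` and the
#'   factor vector `radius_factor`.
#' @export
classify_points <- function(points, E, f = 0.70) {
  stopifnot(inherits(E, "ellipse_model"))
  if (!is.numeric(f) || length(f) != 1L || f <= 0 || f >= 1) {
    stop("boundary factor must be in (0, 1)")
  }
  fac <- point_radius_factor(points, E)
  zone <- ifelse(fac <= f, "inner", ifelse(fac <= 1, "outer", "outside"))
  list(inner = sum(zone == "inner"),
       outer = sum(zone == "outer"),
       outside = sum(zone == "outside"),
       radius_factor = fac, zone = zone)
}

#' Unsigned angle between two rays from a vertex
#'
#' Mirrors a three-point angle tool: the angle at `v` between rays `v -> p1`
#' and `v -> p2`, in degrees within `[0, 180]`.
#'
#' @param v,p1,p2 length-2 numeric vectors `(x, y)` in px.
#' @return angle in degrees.
#' @export
vertex_angle <- function(v, p1, p2) {
  u <- as.numeric(p1) - as.numeric(v)
  w <- as.numeric(p2) - as.numeric(v)
  nu <- sqrt(sum(u^2)); nw <- sqrt(sum(w^2))
  if (nu == 0 || nw == 0) stop("zero-length ray in vertex angle")
  cosang <- sum(u * w) / (nu * nw)
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Vertex annotation for a tri-furrow node
#'
#' @param vertex length-2 `(x, y)` of the node (px).
#' @param rays 3 x 2 matrix of ray endpoints (px).
#' @return object of class `vertex_annotation`.
#' @export
vertex_annotation <- function(vertex, rays) {
  rays <- as.matrix(rays)
  if (!identical(dim(rays), c(3L, 2L))) stop("need exactly three ray endpoints")
  len <- sqrt(rowSums((rays - matrix(vertex, 3L, 2L, byrow = TRUE))^2))
  if (any(len == 0)) stop("rays must have nonzero length")
  structure(list(vertex = as.numeric(vertex), rays = rays),
            class = "vertex_annotation")
}

#' The three angles around a tri-furrow vertex
#'
#' Returns the consecutive angles between the three rays, ordered by ray
#' bearing (counter-clockwise from +x); they always sum to 360 degrees.
#'
#' @param ann a `vertex_annotation`.
#' @return numeric vector of three angles (degrees).
#' @export
trifurrow_angles <- function(ann) {
  stopifnot(inherits(ann, "vertex_annotation"))
  d <- ann$rays - matrix(ann$vertex, 3L, 2L, byrow = TRUE)
  bearing <- atan2(d[, 2L], d[, 1L]) %% (2 * pi)
  b <- sort(bearing)
  ang <- c(diff(b), 2 * pi - (b[3L] - b[1L])) * 180 / pi
  if (any(ang < 1e-9)) stop("coincident rays at vertex")
  ang
}

#' Ellipse perimeter (Ramanujan's second approximation)
#'
#' @param E an `ellipse_model`.
#' @param f optional scale factor applied first (default 1).
#' @return perimeter in pixels.
#' @export
ellipse_perimeter <- function(E, f = 1) {
  a <- E$a * f; b <- E$b * f
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Polar (or log-polar) unwrap of an ellipse interior
#'
#' Resamples the interior of a fitted ellipse onto a rectangular grid:
#' columns are the elliptical angle parameter (0 to 2*pi, counter-clockwise
#' from the major axis) and rows are the elliptical radius factor, with the
#' cell wall (factor 1) at the top so furrows invade downwards. In `log`
#' mode rows are spaced uniformly in log-radius between 1 and `f_min`.
#' Intensity is bilinearly interpolated; samples outside the image get
#' `fill`.
#'
#' @param frame an `image_frame` (or matrix).
#' @param E an `ellipse_model` lying within the frame.
#' @param mode `"linear"` or `"log"`.
#' @param n_theta,n_r output grid size (columns, rows).
#' @param f_min smallest radius factor in log mode (default 0.05).
#' @param fill value outside the image support (default 0).
#' @return an `image_frame` of the unwrapped image (pixel_size preserved).
#' @export
polar_unwrap <- function(frame, E, mode = c("linear", "log"),
                         n_theta = 360L, n_r = 128L, f_min = 0.05,
                         fill = 0) {
  mode <- match.arg(mode)
  img <- as_intensity(frame)
  check_ellipse_inside(E, dim(img))
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[seq_len(n_theta)]
  fr <- if (mode == "linear") {
    seq(1, 0, length.out = n_r)
  } else {
    exp(seq(log(1), log(f_min), length.out = n_r))
  }
  G <- expand.grid(t = th, f = fr)   # theta varies fastest
  P <- ellipse_points(E, G$t, G$f)
  v <- bilinear_sample(img, P[, "x"], P[, "y"], fill = fill)
  out <- matrix(v, nrow = n_r, ncol = n_theta, byrow = TRUE)
  ps <- if (inherits(frame, "image_frame")) frame$pixel_size else 1
  ts <- if (inherits(frame, "image_frame")) frame$timestamp else 0
  image_frame(out, ps, ts)
}

check_ellipse_inside <- function(E, dm) {
  t_dense <- seq(0, 2 * pi, length.out = 256L)
  P <- ellipse_points(E, t_dense)
  if (min(P[, "x"]) < 0 || max(P[, "x"]) > dm[2L] - 1 ||
      min(P[, "y"]) < 0 || max(P[, "y"]) > dm[1L] - 1) {
    stop("ellipse does not lie within the frame")
  }
  invisible(TRUE)
}

#' Intensity line scan along a concentric ellipse
#'
#' Mean intensity in a band of `band_px` total width normal to the ellipse
#' scaled by `f`, sampled at `n_samples` equally spaced parameter values.
#' Positions are reported as cumulative arc length (micrometres) along the
#' scaled ellipse, and the profile is flagged periodic. This is the line
#' scan used for daughter-size estimation along the 85%-radii ellipse.
#'
#' @param frame an `image_frame`.
#' @param E an `ellipse_model`.
#' @param f radial scale factor of the scan ellipse (default 0.85).
#' @param n_samples number of samples (>= 16; default 720).
#' @param band_px band width across the ellipse, pixels (default 3).
#' @return an `intensity_profile` (see [intensity_profile()]).
#' @export
ellipse_band_profile <- function(frame, E, f = 0.85, n_samples = 720L,
                                 band_px = 3) {
  stopifnot(inherits(frame, "image_frame"), inherits(E, "ellipse_model"))
  if (n_samples < 16L) stop("need at least 16 samples")
  img <- frame$intensity
  Es <- scale_ellipse(E, f)
  t <- seq(0, 2 * pi, length.out = n_samples + 1L)[seq_len(n_samples)]
  P <- ellipse_points(Es, t)
  # outward unit normal of the ellipse at parameter t
  ct <- cos(Es$theta); st <- sin(Es$theta)
  tx <- -Es$a * sin(t) * ct - Es$b * cos(t) * st
  ty <- -Es$a * sin(t) * st + Es$b * cos(t) * ct
  nl <- sqrt(tx^2 + ty^2)
  nx <- ty / nl; ny <- -tx / nl
  offs <- seq(-(band_px - 1) / 2, (band_px - 1) / 2, length.out = max(1L, round(band_px)))
  acc <- 0
  for (s in offs) {
    xs <- P[, "x"] + s * nx; ys <- P[, "y"] + s * ny
    if (any(xs < 0 | xs > ncol(img) - 1 | ys < 0 | ys > nrow(img) - 1)) {
      stop("band exits the image")
    }
    acc <- acc + bilinear_sample(img, xs, ys)
  }
  vals <- acc / length(offs)
  # arc length along the scaled ellipse at the sample parameters
  seg <- sqrt(tx^2 + ty^2) * (2 * pi / n_samples)  # local speed * dt
  pos <- (cumsum(seg) - seg) * frame$pixel_size
  total <- sum(seg) * frame$pixel_size
  intensity_profile(pos, vals, periodic = TRUE, length_um = total)
}

#' Intensity profile container
#'
#' @param positions strictly increasing positions in micrometres.
#' @param values intensities at those positions.
#' @param periodic whether the profile wraps around.
#' @param length_um total (period) length for periodic profiles; defaults to
#'   the position span for aperiodic ones.
#' @return object of class `intensity_profile`.
#' @export
intensity_profile <- function(positions, values, periodic = FALSE,
                              length_um = NULL) {
  stopifnot(length(positions) == length(values))
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  if (is.null(length_um)) {
    length_um <- if (periodic) {
      stop("periodic profiles need an explicit total length")
    } else {
      diff(range(positions))
    }
  }
  structure(list(positions = as.numeric(positions),
                 values = as.numeric(values),
                 periodic = isTRUE(periodic),
                 length_um = as.numeric(length_um)),
            class = "intensity_profile")
}
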