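# Seeded synthetic-imaging generators. Every generator is fully determined
# by its arguments (including the seed) and returns both the rendered
# scene and its ground truth, in the same units the analyses report (um,
# um/s, degrees, minutes), so truth-vs-estimate comparisons need no
# conversion. The optical model is deliberately simple: isotropic Gaussian
# PSF (default sigma 1.5 px, roughly diffraction at 0.11 um/px) plus
# Gaussian read noise and optional Poisson shot noise.

# --- shared rendering helpers ------------------------------------------

render_spots <- function(shape, centers, amplitude = 1, sigma = 1.5) {
  img <- matrix(0, shape[1L], shape[2L])
  if (!nrow(centers)) return(img)
  xs <- matrix(rep(0:(shape[2L] - 1L), each = shape[1L]), shape[1L])
  ys <- matrix(rep(0:(shape[1L] - 1L), shape[2L]), shape[1L])
  for (i in seq_len(nrow(centers))) {
    img <- img + amplitude *
      exp(-((xs - centers[i, 1L])^2 + (ys - centers[i, 2L])^2) /
            (2 * sigma^2))
  }
  img
}

# binary ridge of given thickness along segments (matrix of x0,y0,x1,y1)
render_segments <- function(shape, segs, thickness_px = 3, amplitude = 1) {
  xs <- matrix(rep(0:(shape[2L] - 1L), each = shape[1L]), shape[1L])
  ys <- matrix(rep(0:(shape[1L] - 1L), shape[2L]), shape[1L])
  img <- matrix(0, shape[1L], shape[2L])
  half <- thickness_px / 2
  for (i in seq_len(nrow(segs))) {
    p0 <- segs[i, 1:2]; p1 <- segs[i, 3:4]
    d <- p1 - p0
    L2 <- sum(d^2)
    t <- ((xs - p0[1L]) * d[1L] + (ys - p0[2L]) * d[2L]) / L2
    t <- pmin(pmax(t, 0), 1)
    dx <- xs - (p0[1L] + t * d[1L]); dy <- ys - (p0[2L] + t * d[2L])
    img <- pmax(img, amplitude * (sqrt(dx^2 + dy^2) <= half))
  }
  img
}

apply_noise <- function(img, noise_sd = 0, poisson = FALSE,
                        poisson_scale = 100) {
  if (poisson) {
    img <- stats::rpois(length(img), pmax(img, 0) * poisson_scale) /
      poisson_scale
    img <- matrix(img, nrow = NROW(img))
  }
  if (noise_sd > 0) {
    img <- img + matrix(stats::rnorm(length(img), sd = noise_sd),
                        nrow(img), ncol(img))
  }
  pmax(img, 0)
}

# area-uniform sample of n points inside an ellipse at max radius factor
sample_in_ellipse <- function(n, E, f_max = 1) {
  r <- f_max * sqrt(stats::runif(n))
  phi <- stats::runif(n, 0, 2 * pi)
  ellipse_points_polar(E, r, phi)
}

ellipse_points_polar <- function(E, r, phi) {
  ct <- cos(E$theta); st <- sin(E$theta)
  ex <- E$a * r * cos(phi); ey <- E$b * r * sin(phi)
  cbind(x = E$cx + ex * ct - ey * st, y = E$cy + ex * st + ey * ct)
}

# --- tri-furrow vertices (Fig-1E-style artificial controls) ------------

#' Synthetic three-way junction image
#'
#' Renders three ridges radiating from a central vertex at bearings that
#' realise the requested consecutive angles (which must sum to 360
#' degrees), blurred by the PSF, with optional Gaussian read noise. These
#' are the artificial 120-degree controls used to gauge angle-measurement
#' error.
#'
#' @param angles_deg three consecutive angles, summing to 360.
#' @param thickness_px ridge thickness (default 5).
#' @param length_px ray length (default 40).
#' @param noise_sd Gaussian read-noise SD as an absolute intensity
#'   (ridge amplitude is 1; default 0).
#' @param seed integer seed.
#' @param shape image shape in px (default 128 x 128).
#' @param psf_sigma PSF sigma in px (default 1.5).
#' @param bearing0_deg bearing of the first ray (default 0).
#' @param pixel_size um/px (default 0.11).
#' @return list with `frame` (an `image_frame`) and `truth` (list with
#'   `annotation` (a [vertex_annotation()]), `bearings_deg`,
#'   `angles_deg`).
#' @export
make_trifurrow <- function(angles_deg = c(120, 120, 120), thickness_px = 5,
                           length_px = 40, noise_sd = 0, seed = 1L,
                           shape = c(128L, 128L), psf_sigma = 1.5,
                           bearing0_deg = 0, pixel_size = 0.11) {
  if (length(angles_deg) != 3L || abs(sum(angles_deg) - 360) > 1e-9) {
    stop("the three angles must sum to 360 degrees")
  }
  bearings <- (bearing0_deg + cumsum(c(0, angles_deg[1:2]))) %% 360
  v <- (rev(shape) - 1) / 2   # (x, y) centre
  ends <- cbind(v[1L] + length_px * cos(bearings * pi / 180),
                v[2L] + length_px * sin(bearings * pi / 180))
  segs <- cbind(v[1L], v[2L], ends)
  img <- render_segments(shape, segs, thickness_px)
  img <- gaussian_blur(img, psf_sigma)
  img <- with_seed(seed, apply_noise(img, noise_sd))
  list(frame = image_frame(img, pixel_size),
       truth = list(annotation = vertex_annotation(v, ends),
                    bearings_deg = bearings,
                    angles_deg = angles_deg))
}

#' Estimate tri-furrow ray bearings from an image
#'
#' Image-based counterpart of the manual annotation: samples the intensity
#' on a circle around the vertex, finds the three angular peaks (periodic
#' peak detection), and returns a [vertex_annotation()] built from those
#' bearings. Used to measure angle error on noisy synthetic junctions.
#'
#' @param frame `image_frame` or matrix.
#' @param vertex `(x, y)` of the node in px.
#' @param radius_px sampling circle radius (default 15).
#' @param n_theta angular samples (default 720).
#' @return a `vertex_annotation`.
#' @export
estimate_trifurrow_rays <- function(frame, vertex, radius_px = 15,
                                    n_theta = 720L, annulus_px = 8) {
  img <- as_intensity(frame)
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[seq_len(n_theta)]
  radii <- seq(max(3, radius_px - annulus_px / 2),
               radius_px + annulus_px / 2, by = 1)
  v <- 0
  for (r in radii) {
    v <- v + bilinear_sample(img, vertex[1L] + r * cos(th),
                             vertex[2L] + r * sin(th))
  }
  v <- v / length(radii)
  prof <- intensity_profile(th * radius_px, v, periodic = TRUE,
                            length_um = 2 * pi * radius_px)
  pk <- detect_peaks(prof, min_prominence_frac = 0.2,
                     min_distance_um = radius_px * 30 * pi / 180)
  if (length(pk$positions) < 3L) stop("could not find three rays")
  top3 <- sort(pk$positions[order(-pk$prominences)][1:3])
  bearings <- vapply(top3 / radius_px, function(b0) {
    # intensity-weighted circular centroid in a +-15 degree window
    dth <- (th - b0 + pi) %% (2 * pi) - pi
    w <- v - min(v)
    w[abs(dth) > 15 * pi / 180] <- 0
    (b0 + sum(w * dth) / sum(w)) %% (2 * pi)
  }, numeric(1))
  ends <- cbind(vertex[1L] + radius_px * cos(bearings),
                vertex[2L] + radius_px * sin(bearings))
  vertex_annotation(vertex, ends)
}

# --- foam cross-section -------------------------------------------------

#' Synthetic foam cross-section of a cellularized sporangium
#'
#' Seeds `n_cells` points in an ellipse, relaxes them with Lloyd iterations
#' of a discrete (pixel-grid) Voronoi tessellation, and renders the cell
#' boundaries as PSF-blurred bright ridges with one nuclear spot per cell
#' at its centroid. Ground truth lists the junction vertices (with the
#' bearings of their incident edges) and per-cell equivalent diameters in
#' micrometres.
#'
#' @param n_cells number of cells (>= 8; default 20).
#' @param shape image shape (default 192 x 192).
#' @param pixel_size um/px (default 0.11).
#' @param n_lloyd Lloyd relaxation iterations (default 5).
#' @param ridge_px membrane ridge thickness (default 2).
#' @param psf_sigma PSF sigma (default 1.5).
#' @param noise_sd read-noise SD (default 0.02).
#' @param spot_amplitude nuclear spot amplitude (default 0.6).
#' @param seed integer seed.
#' @return list with `frame`, `labels` (cell label matrix), and `truth`
#'   (vertices with incident-edge bearings, cell centroids, equivalent
#'   diameters in um, the boundary ellipse).
#' @export
make_foam_section <- function(n_cells = 20L, shape = c(192L, 192L),
                              pixel_size = 0.11, n_lloyd = 5L,
                              ridge_px = 2, psf_sigma = 1.5,
                              noise_sd = 0.02, spot_amplitude = 0.6,
                              seed = 1L) {
  if (n_cells < 8L) stop("need at least 8 cells")
  E <- ellipse_model((shape[2L] - 1) / 2, (shape[1L] - 1) / 2,
                     0.44 * shape[2L], 0.38 * shape[1L], 0)
  cell_area <- pi * E$a * E$b / n_cells
  if (cell_area < (3 * ridge_px)^2) {
    stop("too many cells for this ellipse at the stated ridge thickness")
  }
  xs <- matrix(rep(0:(shape[2L] - 1L), each = shape[1L]), shape[1L])
  ys <- matrix(rep(0:(shape[1L] - 1L), shape[2L]), shape[1L])
  inside <- matrix(point_radius_factor(cbind(as.numeric(xs), as.numeric(ys)),
                                       E) <= 1, shape[1L], shape[2L])
  px <- xs[inside]; py <- ys[inside]
  seeds <- with_seed(seed, sample_in_ellipse(n_cells, E, f_max = 0.95))
  assign_lab <- function(seeds) {
    d2 <- outer(px, seeds[, 1L], function(a, b) (a - b)^2) +
      outer(py, seeds[, 2L], function(a, b) (a - b)^2)
    max.col(-d2)
  }
  lab_v <- assign_lab(seeds)
  for (it in seq_len(n_lloyd)) {
    for (i in seq_len(n_cells)) {
      sel <- lab_v == i
      if (any(sel)) seeds[i, ] <- c(mean(px[sel]), mean(py[sel]))
    }
    lab_v <- assign_lab(seeds)
  }
  labels <- matrix(0L, shape[1L], shape[2L])
  labels[inside] <- lab_v
  # ridges: pixels adjacent to a different (nonzero) label, plus the wall
  ridge <- matrix(FALSE, shape[1L], shape[2L])
  for (sh in list(c(0L, 1L), c(1L, 0L))) {
    nb <- shift_mat(labels, sh[1L], sh[2L], 0L)
    ridge <- ridge | (labels > 0L & nb > 0L & labels != nb)
  }
  wall <- inside & !shift_all_inside(inside)
  ridge <- ridge | wall
  if (ridge_px > 1) ridge <- distance_transform(!ridge) <= ridge_px / 2
  centroids <- t(vapply(seq_len(n_cells), function(i) {
    sel <- lab_v == i
    c(mean(px[sel]), mean(py[sel]))
  }, numeric(2)))
  areas <- tabulate(lab_v, nbins = n_cells)
  diam_um <- 2 * sqrt(areas / pi) * pixel_size
  vertices <- foam_vertices(labels, inside)
  img <- pmax(as.numeric(ridge), 0)
  img <- matrix(img, shape[1L], shape[2L])
  img <- gaussian_blur(img, psf_sigma)
  img <- img + render_spots(shape, centroids, spot_amplitude, psf_sigma)
  img <- with_seed(seed + 1L, apply_noise(img, noise_sd))
  list(frame = image_frame(img, pixel_size), labels = labels,
       truth = list(vertices = vertices, centroids = centroids,
                    equivalent_diameter_um = diam_um, ellipse = E,
                    areas_px = areas))
}

shift_all_inside <- function(inside) {
  out <- inside
  for (sh in list(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L))) {
    out <- out & shift_mat(inside, sh[1L], sh[2L], FALSE)
  }
  out
}

# junction vertices of a label image: 2x2 blocks containing >= 3 distinct
# nonzero labels, clustered; incident-edge bearings from nearby ridge
# pixels
foam_vertices <- function(labels, inside) {
  nr <- nrow(labels); nc <- ncol(labels)
  a <- labels[-nr, -nc]; b <- labels[-nr, -1L]
  c_ <- labels[-1L, -nc]; d <- labels[-1L, -1L]
  ndist <- matrix(mapply(function(...) length(unique(setdiff(c(...), 0L))),
                         a, b, c_, d), nr - 1L, nc - 1L)
  cand <- which(ndist >= 3L, arr.ind = TRUE)
  if (!nrow(cand)) return(list())
  pts <- cbind(x = cand[, 2L] - 0.5, y = cand[, 1L] - 0.5)
  # cluster candidates within 3 px
  used <- rep(FALSE, nrow(pts)); verts <- list()
  for (i in seq_len(nrow(pts))) {
    if (used[i]) next
    d2 <- (pts[, 1L] - pts[i, 1L])^2 + (pts[, 2L] - pts[i, 2L])^2
    grp <- which(!used & d2 <= 9)
    used[grp] <- TRUE
    ctr <- c(mean(pts[grp, 1L]), mean(pts[grp, 2L]))
    labs <- unique(setdiff(as.integer(c(
      a[cand[grp, , drop = FALSE]], b[cand[grp, , drop = FALSE]],
      c_[cand[grp, , drop = FALSE]], d[cand[grp, , drop = FALSE]])), 0L))
    verts[[length(verts) + 1L]] <-
      list(xy = ctr, n_labels = length(labs),
           bearings_deg = junction_bearings(labels, ctr))
  }
  verts
}

# bearings of boundary directions around a junction: sample labels on a
# small circle; edges sit where the label changes
junction_bearings <- function(labels, ctr, radius = 5, n_theta = 360L) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[seq_len(n_theta)]
  xi <- round(ctr[1L] + radius * cos(th)) + 1L
  yi <- round(ctr[2L] + radius * sin(th)) + 1L
  ok <- xi >= 1L & xi <= ncol(labels) & yi >= 1L & yi <= nrow(labels)
  lv <- rep(NA_integer_, n_theta)
  lv[ok] <- labels[cbind(yi[ok], xi[ok])]
  chg <- which(lv != c(lv[-1L], lv[1L]))
  ((th[chg] + pi / n_theta) * 180 / pi) %% 360
}

# --- cortical migration movie ------------------------------------------

#' Synthetic nuclear-migration movie
#'
#' Nuclei are placed area-uniformly inside the sporangium ellipse; during
#' a Gaussian pulse centred at `t0_min` their elliptical radius factor is
#' multiplied by `1 + A * exp(-(t - t0)^2 / (2 sigma_t^2))` (clipped to
#' the ellipse), emulating the transient cortical enrichment at
#' cellularization onset. Spots are rendered with the PSF and read noise.
#'
#' @param n_nuclei number of nuclei (>= 10; default 60).
#' @param n_frames number of frames (default 41).
#' @param interval_min frame interval, minutes (default 1).
#' @param A pulse amplitude (default 0.25; 0 gives the uniform null).
#' @param t0_min pulse centre, minutes (default mid-movie).
#' @param sigma_t_min pulse width, minutes (default 5, the ~10-minute
#'   enrichment window).
#' @param shape image shape (default 192 x 192).
#' @param pixel_size um/px (default 0.11).
#' @param psf_sigma spot/PSF sigma in px (default 2).
#' @param noise_sd read-noise SD (default 0.02).
#' @param jitter_px per-frame Brownian jitter of nuclei (default 0.3).
#' @param seed integer seed.
#' @return list with `stack` (a `time_lapse`, times in seconds), `truth`
#'   (ellipse, per-frame centroids, `t0_min`, `A`, pulse factor per
#'   frame).
#' @export
make_migration_movie <- function(n_nuclei = 60L, n_frames = 41L,
                                 interval_min = 1, A = 0.25, t0_min = NULL,
                                 sigma_t_min = 5, shape = c(192L, 192L),
                                 pixel_size = 0.11, psf_sigma = 2,
                                 noise_sd = 0.02, jitter_px = 0.3,
                                 seed = 1L) {
  if (n_nuclei < 10L) stop("need at least 10 nuclei")
  E <- ellipse_model((shape[2L] - 1) / 2, (shape[1L] - 1) / 2,
                     0.44 * shape[2L], 0.38 * shape[1L], 0)
  tmin <- interval_min * (seq_len(n_frames) - 1L)
  if (is.null(t0_min)) t0_min <- stats::median(tmin)
  out <- with_seed(seed, {
    r <- sqrt(stats::runif(n_nuclei))
    phi <- stats::runif(n_nuclei, 0, 2 * pi)
    jit <- array(stats::rnorm(n_nuclei * 2L * n_frames, sd = jitter_px),
                 dim = c(n_nuclei, 2L, n_frames))
    noise_seeds <- sample.int(1e6, n_frames)
    list(r = r, phi = phi, jit = jit, noise_seeds = noise_seeds)
  })
  pulse <- 1 + A * exp(-(tmin - t0_min)^2 / (2 * sigma_t_min^2))
  frames <- vector("list", n_frames)
  cents <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    rk <- pmin(out$r * pulse[k], 0.96)
    P <- ellipse_points_polar(E, rk, out$phi)
    P <- P + out$jit[, , k]
    img <- render_spots(shape, P, amplitude = 1, sigma = psf_sigma)
    frames[[k]] <- with_seed(out$noise_seeds[k], apply_noise(img, noise_sd))
    cents[[k]] <- P
  }
  list(stack = time_lapse(frames, pixel_size, tmin * 60),
       truth = list(ellipse = E, centroids = cents, t0_min = t0_min,
                    A = A, pulse = pulse, times_min = tmin))
}

# --- ablation recoil movie ---------------------------------------------

#' Synthetic laser-ablation recoil movie
#'
#' A filamentous band-pass texture is advected away from the ablation site
#' with radial velocity `v(p, t) = v0 * exp(-t / tau) * g(d)` where
#' `g(d)` is a bounded bump profile with `g(0) = 0` at the cut (fastest
#' motion near `d_peak_um`). Frames are generated by backward-mapping the
#' base texture with the time-integrated displacement. The ablation gap is
#' inserted as blank frames, and an optional inward repair phase reverses
#' the sign after `t_repair_s`. Acquisition is 1 Hz, mirroring the
#' published imaging.
#'
#' @param shape image shape (default 160 x 160).
#' @param pixel_size um/px (default 0.11).
#' @param v0 peak recoil speed, um/s (default 0.2).
#' @param tau recoil decay time, s (default 4).
#' @param d_peak_um distance of fastest recoil, um (default 3).
#' @param d_sigma_um width of the recoil bump, um (default 1.5).
#' @param n_pre pre-ablation frames (default 5).
#' @param n_gap blank frames during ablation (default 2).
#' @param n_post post-ablation frames (default 30).
#' @param noise_sd read-noise SD (default 0.02).
#' @param t_repair_s optional start of the inward repair phase (s after
#'   ablation end).
#' @param v_repair repair speed scale, um/s (default `v0 / 4`).
#' @param tau_repair repair decay, s (default `2 * tau`).
#' @param seed integer seed.
#' @return list with `stack`, `event` (an `ablation_event`), and `truth`
#'   (`v0`, `tau`, `d_peak_um`, `d_sigma_um`, site, per-frame
#'   displacement amplitudes).
#' @export
make_recoil_movie <- function(shape = c(160L, 160L), pixel_size = 0.11,
                              v0 = 0.2, tau = 4, d_peak_um = 3,
                              d_sigma_um = 1.5, n_pre = 5L, n_gap = 2L,
                              n_post = 30L, noise_sd = 0.02,
                              t_repair_s = NULL, v_repair = v0 / 4,
                              tau_repair = 2 * tau, seed = 1L) {
  n_frames <- n_pre + n_gap + n_post
  times <- seq_len(n_frames) - 1  # 1 Hz
  site <- (rev(shape) - 1) / 2
  start_s <- times[n_pre] + 0.1
  end_s <- times[n_pre] + n_gap + 0.1 - 1  # last blank frame + ~0.1
  blank_idx <- n_pre + seq_len(n_gap)
  event <- ablation_event(site, start_s, end_s, blank_idx)
  base <- with_seed(seed, {
    n1 <- matrix(stats::runif(prod(shape)), shape[1L], shape[2L])
    bp <- gaussian_blur(n1, 1.2) - gaussian_blur(n1, 5)
    bp <- (bp - min(bp)) / diff(range(bp))
    bp
  })
  xs <- matrix(rep(0:(shape[2L] - 1L), each = shape[1L]), shape[1L])
  ys <- matrix(rep(0:(shape[1L] - 1L), shape[2L]), shape[1L])
  dxp <- xs - site[1L]; dyp <- ys - site[2L]
  dpx <- sqrt(dxp^2 + dyp^2)
  d_um <- dpx * pixel_size
  g <- exp(-(d_um - d_peak_um)^2 / (2 * d_sigma_um^2)) *
    (1 - exp(-(d_um / 0.75)^2))
  # per-frame scalar velocity amplitude (um/s) as a function of time since
  # ablation end, integrated to a displacement amplitude per frame
  vel_amp <- function(ts) {
    if (ts < 0) return(0)
    if (!is.null(t_repair_s) && ts >= t_repair_s) {
      -v_repair * exp(-(ts - t_repair_s) / tau_repair)
    } else {
      v0 * exp(-ts / tau)
    }
  }
  frames <- vector("list", n_frames)
  disp_amp <- numeric(n_frames)  # cumulative displacement amplitude (um)
  noise_seeds <- with_seed(seed + 1L, sample.int(1e6, n_frames))
  acc <- 0; ts_prev <- 0
  for (k in seq_len(n_frames)) {
    if (k %in% blank_idx) {
      frames[[k]] <- with_seed(noise_seeds[k],
                               apply_noise(matrix(0, shape[1L], shape[2L]),
                                           noise_sd))
      disp_amp[k] <- acc
      next
    }
    if (times[k] > end_s) {
      # midpoint-rule integral of the velocity amplitude since last frame
      ts_now <- times[k] - end_s
      tgrid <- seq(ts_prev, ts_now, length.out = 9L)
      mid <- tgrid[-1L] - diff(tgrid) / 2
      acc <- acc + sum(vapply(mid, vel_amp, numeric(1)) * diff(tgrid))
      ts_prev <- ts_now
    }
    disp_amp[k] <- acc
    if (acc == 0) {
      img <- base
    } else {
      shift_px <- acc * g / pixel_size
      max_step <- max(abs(shift_px))
      if (max_step > 16) stop("displacement exceeds half a PIV window")
      rr <- pmax(dpx, 1e-6)
      sx <- xs - shift_px * dxp / rr
      sy <- ys - shift_px * dyp / rr
      img <- matrix(bilinear_sample(base, as.numeric(sx), as.numeric(sy)),
                    shape[1L], shape[2L])
    }
    frames[[k]] <- with_seed(noise_seeds[k], apply_noise(img, noise_sd))
  }
  list(stack = time_lapse(frames, pixel_size, times), event = event,
       truth = list(v0 = v0, tau = tau, d_peak_um = d_peak_um,
                    d_sigma_um = d_sigma_um, site = site,
                    disp_amp_um = disp_amp,
                    t_repair_s = t_repair_s))
}

# --- furrow tip recoil movie -------------------------------------------

#' Synthetic receding-tip recoil movie
#'
#' Two Gaussian furrow tips on a horizontal line separate as
#' `D(t) = D0 + A * (1 - exp(-t / tau))`, rendered with the PSF and read
#' noise. Frames where the tips are closer than twice the PSF sigma are
#' flagged unresolvable in the truth.
#'
#' @param D0 initial tip separation, um (default 2).
#' @param A recoil amplitude, um (default 2, the published ~2 um fast
#'   recoil).
#' @param tau recoil time constant, s (default 5).
#' @param n_frames frames at 1 Hz (default 40).
#' @param shape image shape (default 128 x 128).
#' @param pixel_size um/px (default 0.11).
#' @param psf_sigma PSF sigma, px (default 1.5).
#' @param noise_sd read-noise SD (default 0.02).
#' @param seed integer seed.
#' @return list with `stack`, `segment` (profile line for
#'   [tip_distance_series()]), and `truth` (`D0`, `A`, `tau`, `D_um` per
#'   frame, `resolvable` flags).
#' @export
make_tip_recoil_movie <- function(D0 = 2, A = 2, tau = 5, n_frames = 40L,
                                  shape = c(128L, 128L), pixel_size = 0.11,
                                  psf_sigma = 1.5, noise_sd = 0.02,
                                  seed = 1L) {
  times <- seq_len(n_frames) - 1
  D <- D0 + A * (1 - exp(-times / tau))
  ctr <- (rev(shape) - 1) / 2
  if (max(D) / pixel_size / 2 + 6 * psf_sigma > min(ctr)) {
    stop("tips exit the frame")
  }
  noise_seeds <- with_seed(seed, sample.int(1e6, n_frames))
  frames <- lapply(seq_len(n_frames), function(k) {
    half <- D[k] / 2 / pixel_size
    cents <- rbind(c(ctr[1L] - half, ctr[2L]), c(ctr[1L] + half, ctr[2L]))
    img <- render_spots(shape, cents, amplitude = 1, sigma = psf_sigma)
    with_seed(noise_seeds[k], apply_noise(img, noise_sd))
  })
  margin <- max(D) / pixel_size / 2 + 5 * psf_sigma
  segment <- list(c(ctr[1L] - margin, ctr[2L]), c(ctr[1L] + margin, ctr[2L]))
  list(stack = time_lapse(frames, pixel_size, times), segment = segment,
       truth = list(D0 = D0, A = A, tau = tau, D_um = D,
                    resolvable = D >= 2 * psf_sigma * pixel_size))
}

# --- actin network dissolution movie -----------------------------------

#' Synthetic network-dissolution movie
#'
#' A static dense filamentous texture (the field of view inside a
#' sporangium filled with actin network) whose contrast decays
#' exponentially toward the spatial mean after drug onset and recovers
#' after washout, emulating LatB-driven disassembly and reassembly.
#' Ground truth is the contrast amplitude curve.
#'
#' @param n_frames number of frames (default 30).
#' @param interval_min frame interval, minutes (default 1).
#' @param onset_min drug onset, minutes (default 10).
#' @param offset_min washout, minutes (default 20; `NULL` for none).
#' @param tau_min dissolution/recovery time constant, minutes (default
#'   1.5, within the published five-minute disassembly).
#' @param floor residual contrast at full dissolution (default 0.05).
#' @param noise_sd read-noise SD (default 0.02).
#' @param shape image shape (default 160 x 160).
#' @param pixel_size um/px (default 0.11).
#' @param seed integer seed.
#' @return list with `stack` (times in seconds), `truth` (`amplitude`
#'   per frame, `onset_min`, `offset_min`).
#' @export
make_dissolution_movie <- function(n_frames = 30L, interval_min = 1,
                                   onset_min = 10, offset_min = 20,
                                   tau_min = 1.5, floor = 0.05,
                                   noise_sd = 0.02, shape = c(160L, 160L),
                                   pixel_size = 0.11, seed = 1L) {
  base <- with_seed(seed, {
    n1 <- matrix(stats::runif(prod(shape)), shape[1L], shape[2L])
    bp <- gaussian_blur(n1, 1.2) - gaussian_blur(n1, 5)
    (bp - min(bp)) / diff(range(bp))
  })
  mu <- mean(base)
  tmin <- interval_min * (seq_len(n_frames) - 1L)
  amp <- vapply(tmin, function(t) {
    if (t < onset_min) return(1)
    if (is.null(offset_min) || t < offset_min) {
      return(floor + (1 - floor) * exp(-(t - onset_min) / tau_min))
    }
    a_at_off <- floor + (1 - floor) * exp(-(offset_min - onset_min) / tau_min)
    1 - (1 - a_at_off) * exp(-(t - offset_min) / tau_min)
  }, numeric(1))
  noise_seeds <- with_seed(seed + 2L, sample.int(1e6, n_frames))
  frames <- lapply(seq_len(n_frames), function(k) {
    with_seed(noise_seeds[k],
              apply_noise(mu + amp[k] * (base - mu), noise_sd))
  })
  list(stack = time_lapse(frames, pixel_size, tmin * 60),
       truth = list(amplitude = amp, onset_min = onset_min,
                    offset_min = offset_min, times_min = tmin))
}

# --- peripheral daughter ring ------------------------------------------

#' Synthetic peripheral daughter-cell layer
#'
#' Renders bright radial furrow segments crossing the 0.85-factor ellipse
#' at arc spacings drawn from a jittered distribution around
#' `mean_spacing_um` (the spacings are renormalised to close the ring
#' exactly). Ground truth is the realised spacing list.
#'
#' @param n_daughters number of daughters (>= 6; default 12).
#' @param mean_spacing_um target mean peak-to-peak spacing, um (default
#'   3.25, matching the published 3-3.5 um control diameters).
#' @param jitter_frac spacing jitter as a fraction of the mean (default
#'   0.05).
#' @param shape image shape; `NULL` (default) sizes the image so the
#'   0.85-ellipse perimeter equals `n_daughters * mean_spacing_um`.
#' @param pixel_size um/px (default 0.11).
#' @param aspect b/a of the sporangium ellipse (default 0.9).
#' @param spoke_thickness_px furrow segment thickness (default 2).
#' @param psf_sigma PSF sigma (default 1.5).
#' @param noise_sd read-noise SD (default 0.02).
#' @param seed integer seed.
#' @return list with `frame`, `ellipse`, and `truth` (`spacings_um`,
#'   `arc_positions_um`, `perimeter_um`).
#' @export
make_ring_layer <- function(n_daughters = 12L, mean_spacing_um = 3.25,
                            jitter_frac = 0.05, shape = NULL,
                            pixel_size = 0.11, aspect = 0.9,
                            spoke_thickness_px = 2, psf_sigma = 1.5,
                            noise_sd = 0.02, seed = 1L) {
  if (n_daughters < 6L) stop("need at least 6 daughters")
  P_target_px <- n_daughters * mean_spacing_um / pixel_size
  # size the 0.85 ellipse to the target perimeter
  E1 <- ellipse_model(0, 0, 1, aspect, 0)
  s <- P_target_px / ellipse_perimeter(E1, 0.85)
  a <- s; b <- s * aspect
  if (is.null(shape)) {
    half <- ceiling(a + 8 * psf_sigma + 4)
    shape <- c(2L * half + 1L, 2L * half + 1L)
  }
  E <- ellipse_model((shape[2L] - 1) / 2, (shape[1L] - 1) / 2, a, b, 0)
  if (mean_spacing_um * (1 - 3 * jitter_frac) <
      2 * spoke_thickness_px * pixel_size) {
    stop("spokes overlap at the stated thickness")
  }
  sp <- with_seed(seed, {
    raw <- stats::rnorm(n_daughters, mean_spacing_um,
                        jitter_frac * mean_spacing_um)
    raw <- pmax(raw, 0.25 * mean_spacing_um)
    raw
  })
  per_um <- ellipse_perimeter(E, 0.85) * pixel_size
  sp <- sp * per_um / sum(sp)         # close the ring exactly
  arc <- cumsum(sp) - sp              # spoke positions (arc length, um)
  # invert arc length -> parameter on the 0.85 ellipse
  tt <- seq(0, 2 * pi, length.out = 4096L)
  Pd <- ellipse_points(E, tt, 0.85)
  seg <- c(0, cumsum(sqrt(diff(Pd[, 1L])^2 + diff(Pd[, 2L])^2))) * pixel_size
  t_of_arc <- stats::approx(seg, tt, xout = arc, rule = 2)$y
  inner <- ellipse_points(E, t_of_arc, 0.70)
  outer <- ellipse_points(E, t_of_arc, 1.0)
  segs <- cbind(inner, outer)
  img <- render_segments(shape, segs, spoke_thickness_px)
  # faint cell wall ring
  wallt <- seq(0, 2 * pi, length.out = 1024L)
  wp <- ellipse_points(E, wallt)
  wsegs <- cbind(wp[-nrow(wp), , drop = FALSE], wp[-1L, , drop = FALSE])
  img <- pmax(img, 0.4 * render_segments(shape, wsegs, 1.5))
  img <- gaussian_blur(img, psf_sigma)
  img <- with_seed(seed + 1L, apply_noise(img, noise_sd))
  list(frame = image_frame(img, pixel_size), ellipse = E,
       truth = list(spacings_um = sp, arc_positions_um = arc,
                    perimeter_um = per_um))
}
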