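# geometry core: ellipse fitting, concentric constructions, angles,
# unwrapping, band profiles

test_that("fit_ellipse recovers parameters from parametric samples", {
  # circle identity
  C <- ellipse_model(50, 50, 10, 10, 0)
  Fc <- fit_ellipse(ellipse_points(C, seq(0, 2 * pi, length.out = 33)[1:32]))
  expect_equal(c(Fc$cx, Fc$cy, Fc$a, Fc$b), c(50, 50, 10, 10),
               tolerance = 1e-9)

  # axis-aligned and rotated ellipses, several geometries
  cases <- list(c(20, 10, 0), c(20, 10, 0.6), c(35, 13, 2.1),
                c(60, 59, 1.0))
  for (cs in cases) {
    E <- ellipse_model(80, 70, cs[1], cs[2], cs[3])
    pts <- ellipse_points(E, seq(0, 2 * pi, length.out = 65)[1:64])
    Ef <- fit_ellipse(pts)
    expect_equal(Ef$cx, E$cx, tolerance = 1e-6)
    expect_equal(Ef$cy, E$cy, tolerance = 1e-6)
    expect_equal(Ef$a, E$a, tolerance = 1e-6)
    expect_equal(Ef$b, E$b, tolerance = 1e-6)
    dtheta <- min(abs(Ef$theta - E$theta),
                  pi - abs(Ef$theta - E$theta))
    tol_theta <- if (abs(cs[1] - cs[2]) < 2) 1e-3 else 1e-6
    expect_lt(dtheta, tol_theta)
    expect_lt(Ef$rms, 1e-6)
  }
})

test_that("fit_ellipse rejects degenerate input", {
  expect_error(fit_ellipse(cbind(1:5, 1:5)), "at least 6")
  expect_error(fit_ellipse(cbind(1:20, 2 * (1:20) + 3)), "collinear")
  expect_error(fit_ellipse(cbind(rep(1, 10), rep(2, 10))),
               "collinear|duplicated")
})

test_that("scale_ellipse scales radii and area as expected", {
  E <- ellipse_model(0, 0, 20, 10, 0.3)
  E70 <- scale_ellipse(E, 0.70)
  expect_equal(c(E70$a, E70$b), c(14, 7))
  expect_equal(c(E70$cx, E70$cy, E70$theta), c(0, 0, 0.3))
  expect_identical(scale_ellipse(E, 1)$a, E$a)
  # f = sqrt(0.5) halves the area exactly
  Eh <- scale_ellipse(E, sqrt(0.5))
  expect_equal(pi * Eh$a * Eh$b, pi * E$a * E$b / 2, tolerance = 1e-12)
  expect_error(scale_ellipse(E, 0), "> 0")
  expect_error(scale_ellipse(E, -1), "> 0")
})

test_that("classify_points partitions inner/outer/outside", {
  E <- ellipse_model(50, 50, 20, 10, 0)
  expect_equal(classify_points(cbind(50, 50), E, 0.70)$inner, 1L)
  # point at 0.9 of the major radius is in the donut for f = 0.70
  cl <- classify_points(cbind(50 + 0.9 * 20, 50), E, 0.70)
  expect_equal(cl$outer, 1L)
  expect_equal(classify_points(cbind(95, 50), E, 0.70)$outside, 1L)

  # Monte-Carlo: f = sqrt(0.5) splits the area in half
  set.seed(42)
  n <- 10000
  r <- sqrt(runif(n)); phi <- runif(n, 0, 2 * pi)
  pts <- cbind(50 + 20 * r * cos(phi), 50 + 10 * r * sin(phi))
  cl <- classify_points(pts, E, sqrt(0.5))
  expect_equal(cl$inner + cl$outer + cl$outside, n)
  expect_equal(cl$outside, 0L)
  # |inner - outer| within ~4 SD of the binomial difference (SD = sqrt(n))
  expect_lt(abs(cl$inner - cl$outer), 4 * sqrt(n))
})

test_that("classify_points counts are invariant under rigid rotation", {
  E <- ellipse_model(0, 0, 20, 10, 0.4)
  set.seed(7)
  pts <- cbind(rnorm(200, 0, 12), rnorm(200, 0, 8))
  base <- classify_points(pts, E, 0.7)
  for (ang in c(0.3, 1.2, 2.9)) {
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
    rot <- classify_points(pts %*% t(R),
                           ellipse_model(0, 0, 20, 10, (0.4 + ang) %% pi),
                           0.7)
    expect_identical(rot[c("inner", "outer", "outside")],
                     base[c("inner", "outer", "outside")])
  }
})

test_that("vertex_angle matches the three-point angle tool", {
  expect_equal(vertex_angle(c(0, 0), c(1, 0), c(0, 1)), 90)
  expect_equal(vertex_angle(c(0, 0), c(1, 0), c(-1, 0)), 180)
  expect_equal(vertex_angle(c(2, 3), c(5, 3), c(2, 9)), 90)
  # three equally spaced rays: every adjacent pair is 120 apart
  b <- c(0, 120, 240) * pi / 180
  p <- cbind(cos(b), sin(b))
  expect_equal(vertex_angle(c(0, 0), p[1, ], p[2, ]), 120)
  expect_equal(vertex_angle(c(0, 0), p[2, ], p[3, ]), 120)
  expect_error(vertex_angle(c(0, 0), c(0, 0), c(1, 0)), "zero-length")
})

test_that("trifurrow_angles orders by bearing and sums to 360", {
  a120 <- trifurrow_angles(vertex_annotation(
    c(0, 0), rbind(c(1, 0), c(cos(2 * pi / 3), sin(2 * pi / 3)),
                   c(cos(4 * pi / 3), sin(4 * pi / 3)))))
  expect_equal(a120, c(120, 120, 120))
  a <- trifurrow_angles(vertex_annotation(
    c(0, 0), rbind(c(1, 0), c(0, 1), c(-1, 0))))
  expect_equal(sort(a), c(90, 90, 180))
  # property: sums to 360 for random bearings
  set.seed(11)
  for (i in 1:50) {
    b <- sort(runif(3, 0, 2 * pi))
    ann <- vertex_annotation(c(5, 5),
                             cbind(5 + cos(b), 5 + sin(b)))
    expect_equal(sum(trifurrow_angles(ann)), 360, tolerance = 1e-9)
  }
  expect_error(trifurrow_angles(vertex_annotation(
    c(0, 0), rbind(c(1, 0), c(2, 0), c(0, 1)))), "coincident")
})

test_that("polar_unwrap maps rings to rows and rays to columns", {
  E <- ellipse_model(60, 60, 40, 30, 0.4)
  img <- matrix(0, 121, 121)
  P <- ellipse_points(E, seq(0, 2 * pi, length.out = 2000), 0.85)
  img[cbind(round(P[, "y"]) + 1, round(P[, "x"]) + 1)] <- 1
  img <- gaussian_blur(img, 1)
  un <- polar_unwrap(image_frame(img, 0.11), E, "linear", n_theta = 180,
                     n_r = 100)
  # ring at factor 0.85 -> single bright row near (1 - 0.85) of the way down
  rowmax <- which.max(rowMeans(un$intensity))
  expect_lt(abs(rowmax - (1 + 0.15 * 99)), 3)

  # bright ray at fixed parameter angle -> single bright column
  img2 <- matrix(0, 121, 121)
  t0 <- 1.1
  for (f in seq(0.1, 0.98, by = 0.005)) {
    q <- ellipse_points(E, t0, f)
    img2[round(q[, "y"]) + 1, round(q[, "x"]) + 1] <- 1
  }
  img2 <- gaussian_blur(img2, 1)
  un2 <- polar_unwrap(image_frame(img2, 0.11), E, "linear", n_theta = 180,
                      n_r = 100)
  colmax <- which.max(colMeans(un2$intensity))
  expect_lt(abs(colmax - (1 + t0 / (2 * pi) * 180)), 3)

  # uniform image stays uniform (away from the boundary rows)
  un3 <- polar_unwrap(image_frame(matrix(3, 121, 121), 0.11), E, "linear",
                      n_theta = 90, n_r = 50)
  expect_lt(max(abs(un3$intensity[2:49, ] - 3)), 1e-9)

  expect_error(polar_unwrap(image_frame(matrix(0, 50, 50), 1), E),
               "within the frame")
})

test_that("unwrap of a rotationally symmetric image homogenises with n_theta", {
  E <- ellipse_model(40, 40, 25, 25, 0)
  xs <- matrix(rep(0:80, each = 81), 81); ys <- t(xs)
  img <- exp(-((xs - 40)^2 + (ys - 40)^2) / 200)
  v <- vapply(c(30, 120, 480), function(nt) {
    un <- polar_unwrap(image_frame(img, 1), E, "linear", n_theta = nt,
                       n_r = 40)
    mean(apply(un$intensity, 1, stats::var))
  }, numeric(1))
  expect_lt(v[3], 1e-6)
  expect_true(all(diff(v) <= 1e-12))
})

test_that("ellipse_band_profile: constants, spokes, arc length", {
  E <- ellipse_model(60, 60, 40, 32, 0.2)
  fr <- image_frame(matrix(2.5, 121, 121), 0.11)
  prof <- ellipse_band_profile(fr, E, f = 0.85, n_samples = 360, band_px = 3)
  expect_lt(diff(range(prof$values)), 1e-9)
  expect_true(prof$periodic)

  # k bright radial spokes -> k near-equally spaced peaks
  k <- 8
  tk <- seq(0, 2 * pi, length.out = k + 1)[1:k]
  segs <- cbind(ellipse_points(E, tk, 0.7), ellipse_points(E, tk, 1.0))
  img <- gaussian_blur(foamquant:::render_segments(c(121, 121), segs, 2), 1)
  pk <- detect_peaks(ellipse_band_profile(image_frame(img, 0.11), E,
                                          f = 0.85, n_samples = 720),
                     min_prominence_frac = 0.2, min_distance_um = 0.5)
  expect_equal(length(pk$positions), k)
  sp <- daughter_diameters(pk)
  expect_lt(max(abs(sp - mean(sp))) / mean(sp), 0.15)

  # arc-length total matches the Ramanujan perimeter (exact on a circle)
  Ecirc <- ellipse_model(60, 60, 40, 40, 0)
  pr <- ellipse_band_profile(fr, Ecirc, f = 0.85, n_samples = 2000)
  expect_equal(pr$length_um, ellipse_perimeter(Ecirc, 0.85) * 0.11,
               tolerance = 1e-3)
  Ebig <- ellipse_model(60, 60, 58, 50, 0)
  expect_error(ellipse_band_profile(fr, Ebig, f = 1.0, band_px = 9),
               "exits the image")
})

test_that("point_radius_factor defines concentric membership", {
  E <- ellipse_model(10, 20, 8, 4, 1.1)
  for (f in c(0.3, 0.7, 1)) {
    P <- ellipse_points(E, seq(0.1, 6, length.out = 7), f)
    expect_equal(point_radius_factor(P, E), rep(f, 7), tolerance = 1e-12)
  }
})
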