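# PIV, radial decomposition, summaries, kymographs, tip recoil

test_that("piv_field recovers constructed integer and sub-pixel shifts", {
  a <- smooth_noise(128, 128, 1, seed = 1)
  b <- circ_shift(a, 1, 3)
  f <- piv_field(a, b, 32, 16, dt = 1, pixel_size = 1)
  expect_lt(max(abs(f$vectors$u - 3)), 0.2)
  expect_lt(max(abs(f$vectors$v - 1)), 0.2)

  # identical frames -> zero field
  f0 <- piv_field(a, a, 32, 16, dt = 1, pixel_size = 1)
  expect_lt(max(abs(c(f0$vectors$u, f0$vectors$v))), 1e-9)

  # 0.4 px sub-pixel shift via interpolated resampling
  g <- expand.grid(y = 0:127, x = 0:127)
  bs <- matrix(bilinear_sample(a, (g$x - 0.4) %% 128, g$y), 128, 128)
  fs <- piv_field(a, bs, 32, 16, dt = 1, pixel_size = 1)
  expect_lt(abs(mean(fs$vectors$u) - 0.4), 0.1)
  expect_lt(abs(mean(fs$vectors$v)), 0.05)

  # units: pixel_size/dt scaling
  f2 <- piv_field(a, b, 32, 16, dt = 2, pixel_size = 0.11)
  expect_equal(mean(f2$vectors$u), mean(f$vectors$u) * 0.11 / 2,
               tolerance = 1e-9)
  expect_error(piv_field(a, b[1:64, 1:64], 32, 16, 1, 1), "identical shape")
  expect_error(piv_field(a, b, 256, 16, 1, 1), "larger than the frame")
  expect_error(piv_field(a, b, 32, 40, 1, 1), "overlap")
})

test_that("piv_field agrees with the brute-force correlation oracle", {
  a <- smooth_noise(64, 64, 1, seed = 12)
  for (sh in list(c(0, 2), c(-2, 1), c(3, -3))) {
    b <- circ_shift(a, sh[1], sh[2])
    f <- piv_field(a, b, 32, 0, dt = 1, pixel_size = 1)
    k <- 0
    for (y0 in c(1, 33)) for (x0 in c(1, 33)) {
      k <- k + 1
      wa <- a[y0:(y0 + 31), x0:(x0 + 31)]
      wb <- b[y0:(y0 + 31), x0:(x0 + 31)]
      oracle <- brute_piv_window(wa, wb, 16)
      expect_lt(abs(f$vectors$u[k] - oracle["dx"]), 0.1)
      expect_lt(abs(f$vectors$v[k] - oracle["dy"]), 0.1)
    }
  }
})

test_that("piv_field matches scikit-image phase correlation (oracle)", {
  a <- smooth_noise(64, 64, 1, seed = 7)
  b <- circ_shift(a, 2, -3)
  fa <- tempfile(fileext = ".csv"); fb <- tempfile(fileext = ".csv")
  write.table(a, fa, sep = ",", row.names = FALSE, col.names = FALSE)
  write.table(b, fb, sep = ",", row.names = FALSE, col.names = FALSE)
  out <- run_python(sprintf(paste0(
    "import numpy as np\n",
    "from skimage.registration import phase_cross_correlation\n",
    "a = np.loadtxt('%s', delimiter=',')\n",
    "b = np.loadtxt('%s', delimiter=',')\n",
    "sh, _, _ = phase_cross_correlation(b, a, upsample_factor=50)\n",
    "print('SHIFT %%.4f %%.4f' %% (sh[1], sh[0]))\n"), fa, fb))
  sh <- as.numeric(strsplit(sub("SHIFT ", "",
                                grep("^SHIFT", out, value = TRUE)),
                            " ")[[1]])
  f <- piv_field(a, b, 64, 0, dt = 1, pixel_size = 1)
  expect_lt(abs(f$vectors$u[1] - sh[1]), 0.1)
  expect_lt(abs(f$vectors$v[1] - sh[2]), 0.1)
})

test_that("filter_vectors applies magnitude and SNR rules", {
  fld <- structure(list(
    vectors = data.frame(x_px = 1:3, y_px = 1:3,
                         u = c(0, 1, 2), v = c(0, 0, 0),
                         snr = c(9, 1.0, 2.5)),
    dt = 1, pixel_size = 1, window_px = 32, overlap_px = 16, t_s = NA),
    class = "velocity_field")
  kept <- filter_vectors(fld, snr_min = 1.3)$vectors
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$u, 2)
  expect_error(filter_vectors(fld, snr_min = 0.5), ">= 1")
  # constructed-shift scenes retain nearly all vectors at snr_min = 1.3
  a <- smooth_noise(128, 128, 1, seed = 3)
  f <- piv_field(a, circ_shift(a, 0, 3), 32, 16, 1, 1)
  expect_gte(nrow(filter_vectors(f, 1.3)$vectors) / nrow(f$vectors), 0.9)
})

test_that("radial_velocity sign and magnitude identities", {
  ev <- ablation_event(c(10, 10), 0, 1)
  mk <- function(x, y, u, v) structure(list(
    vectors = data.frame(x_px = x, y_px = y, u = u, v = v, snr = 2),
    dt = 1, pixel_size = 1, window_px = 32, overlap_px = 16, t_s = 5),
    class = "velocity_field")
  # pointing directly away at speed s
  r <- radial_velocity(mk(20, 10, 0.05, 0), ev)
  expect_equal(r$v_rad_um_s, 0.05)
  expect_equal(r$d_um, 10)
  # tangential -> zero radial component
  r2 <- radial_velocity(mk(20, 10, 0, 0.07), ev)
  expect_equal(r2$v_rad_um_s, 0, tolerance = 1e-12)
  # pointing at the site -> -s
  r3 <- radial_velocity(mk(10, 25, 0, -0.03), ev)
  expect_equal(r3$v_rad_um_s, -0.03)
  # vector at the site is skipped
  r4 <- radial_velocity(mk(10, 10, 1, 1), ev)
  expect_equal(nrow(r4), 0L)
  expect_equal(r$t_s, 4)  # field time minus ablation end
})

test_that("radial_velocity is rotation-equivariant", {
  ev <- ablation_event(c(0, 0), 0, 1)
  set.seed(4)
  x <- rnorm(40, 0, 10); y <- rnorm(40, 0, 10)
  u <- rnorm(40, 0, 0.1); v <- rnorm(40, 0, 0.1)
  mk <- function(x, y, u, v) structure(list(
    vectors = data.frame(x_px = x, y_px = y, u = u, v = v, snr = 2),
    dt = 1, pixel_size = 0.11, window_px = 32, overlap_px = 16, t_s = 3),
    class = "velocity_field")
  base <- radial_velocity(mk(x, y, u, v), ev)
  ang <- 1.1
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  pr <- cbind(x, y) %*% t(R); vr <- cbind(u, v) %*% t(R)
  rot <- radial_velocity(mk(pr[, 1], pr[, 2], vr[, 1], vr[, 2]), ev)
  expect_equal(rot$v_rad_um_s, base$v_rad_um_s, tolerance = 1e-12)
  expect_equal(rot$d_um, base$d_um, tolerance = 1e-12)
})

test_that("divergent fields project to their radial profile; solenoidal to 0", {
  ev <- ablation_event(c(0, 0), 0, 1)
  th <- seq(0, 2 * pi, length.out = 81)[1:80]
  d <- rep(c(5, 10, 20), each = 80)
  x <- d * cos(th); y <- d * sin(th)
  speed <- 0.1 * exp(-d / 10)
  div <- structure(list(
    vectors = data.frame(x_px = x, y_px = y,
                         u = speed * cos(th), v = speed * sin(th), snr = 2),
    dt = 1, pixel_size = 1, window_px = 32, overlap_px = 16, t_s = 2),
    class = "velocity_field")
  r <- radial_velocity(div, ev)
  expect_equal(r$v_rad_um_s, speed, tolerance = 1e-12)
  sol <- div
  sol$vectors$u <- -speed * sin(th); sol$vectors$v <- speed * cos(th)
  r2 <- radial_velocity(sol, ev)
  expect_lt(max(abs(r2$v_rad_um_s)), 1e-12)
})

test_that("summarize_radial bins, flags empties, zero-width CIs", {
  recs <- data.frame(t_s = rep(c(1, 4), each = 10),
                     d_um = rep(seq(0.5, 5, 0.5), 2),
                     v_rad_um_s = 0.05, snr = 2,
                     x_px = 0, y_px = 0)
  s <- summarize_radial(recs, distance_bins_um = 1, time_bins_s = 3,
                        n_boot = 100, seed = 1)
  filled <- s[s$n > 0, ]
  expect_true(all(abs(filled$mean_v - 0.05) < 1e-12))
  expect_true(all(abs(filled$ci_lo[filled$n >= 2] - 0.05) < 1e-12))
  expect_true(all(abs(filled$ci_hi[filled$n >= 2] - 0.05) < 1e-12))
  expect_true(any(s$n == 0 & is.na(s$mean_v)))
  expect_error(summarize_radial(recs[0, ]), "no radial records")
})

test_that("top_fraction keeps the fastest vectors with ties", {
  mk <- function(u) structure(list(
    vectors = data.frame(x_px = seq_along(u), y_px = 0, u = u, v = 0,
                         snr = 2),
    dt = 1, pixel_size = 1, window_px = 32, overlap_px = 16, t_s = NA),
    class = "velocity_field")
  expect_equal(top_fraction(mk(1:10), 0.1)$vectors$u, 10)
  expect_equal(nrow(top_fraction(mk(rep(2, 6)), 0.1)$vectors), 6L)
  expect_equal(nrow(top_fraction(mk(1:10), 1)$vectors), 10L)
  expect_error(top_fraction(mk(1:3), 0), "in \\(0, 1\\]")
})

test_that("resample_stack keeps nearest frames without duplication", {
  st <- time_lapse(replicate(10, matrix(0, 4, 4), simplify = FALSE), 1,
                   times = 0:9)
  r3 <- resample_stack(st, 3)
  expect_equal(r3$times, c(0, 3, 6, 9))
  expect_equal(resample_stack(st, 1)$times, 0:9)
  # irregular timestamps: brute-force nearest selection
  ti <- c(0, 0.9, 2.2, 3.1, 5.0, 5.9, 8.4)
  sti <- time_lapse(replicate(7, matrix(0, 4, 4), simplify = FALSE), 1,
                    times = ti)
  rs <- resample_stack(sti, 2)
  grid <- seq(0, 8.4, by = 2)
  expected <- unique(vapply(grid, function(g) ti[which.min(abs(ti - g))],
                            numeric(1)))
  expect_equal(rs$times, expected)
  expect_false(any(duplicated(rs$times)))
  expect_error(resample_stack(st, 0.5), "smaller than the native")
})

test_that("preablation_mask covers the static network", {
  net <- foamquant:::render_segments(c(64, 64),
                                     rbind(c(10, 20, 50, 20),
                                           c(30, 5, 30, 60)), 3)
  net <- gaussian_blur(net, 1)
  frames <- lapply(1:4, function(i) net + 0.01 * i)
  st <- time_lapse(frames, 0.11, times = 0:3)
  ev <- ablation_event(c(30, 20), 2.5, 4.5)
  m <- preablation_mask(st, ev)
  skel <- net > 0.5 * max(net)
  expect_true(all(m[skel]))
  # all-zero stack -> explicit failure
  st0 <- time_lapse(replicate(3, matrix(0, 8, 8), simplify = FALSE), 1,
                    times = 0:2)
  expect_error(preablation_mask(st0, ablation_event(c(4, 4), 1.5, 2.5)),
               "mask undefined")
  expect_error(preablation_mask(st, ablation_event(c(30, 20), -1, 0.5)),
               "no pre-ablation frames")
})

test_that("kymograph renders static stripes, motion slopes, blank rows", {
  n <- 12
  mkframe <- function(cx) foamquant:::render_spots(c(48, 64),
                                                   rbind(c(cx, 24)), 1, 2)
  static <- time_lapse(replicate(n, mkframe(30), simplify = FALSE), 1,
                       times = 0:(n - 1))
  seg <- list(c(8, 24), c(56, 24))
  ky <- kymograph(static, seg, width_px = 20)
  expect_equal(nrow(ky$intensity), n)
  cols <- apply(ky$intensity, 1, which.max)
  expect_true(all(cols == cols[1]))  # vertical stripe

  # constant-speed spot -> diagonal stripe of matching slope
  moving <- time_lapse(lapply(0:(n - 1), function(i) mkframe(14 + 2 * i)),
                       1, times = 0:(n - 1))
  ky2 <- kymograph(moving, seg, width_px = 10)
  cols2 <- apply(ky2$intensity, 1, which.max)
  slope <- stats::coef(stats::lm(cols2 ~ seq_len(n)))[2]
  expect_equal(unname(slope), 2, tolerance = 0.1)

  # blank ablation frames appear as dark rows
  fr <- replicate(5, mkframe(30), simplify = FALSE)
  fr[[3]] <- matrix(0, 48, 64)
  ky3 <- kymograph(time_lapse(fr, 1, times = 0:4), seg, width_px = 20)
  expect_lt(max(ky3$intensity[3, ]), 1e-9)
  expect_error(kymograph(static, list(c(-5, 24), c(56, 24)), 20),
               "exits the frame")
})

test_that("tip_distance_series measures static and receding tips", {
  # two static Gaussian tips 5 um apart
  px <- 0.11
  sep_px <- 5 / px
  ctr <- 63.5
  img <- foamquant:::render_spots(c(128, 128),
                                  rbind(c(ctr - sep_px / 2, 64),
                                        c(ctr + sep_px / 2, 64)), 1, 1.5)
  st <- time_lapse(replicate(6, img, simplify = FALSE), px, times = 0:5)
  seg <- list(c(10, 64), c(117, 64))
  ts <- tip_distance_series(st, seg, width_px = 10)
  expect_true(all(ts$ok))
  expect_equal(ts$distance_um, rep(5, 6), tolerance = 0.1)

  # single-peak frames are flagged and excluded
  one <- time_lapse(replicate(4, foamquant:::render_spots(
    c(128, 128), rbind(c(ctr, 64)), 1, 1.5), simplify = FALSE),
    px, times = 0:3)
  ts1 <- tip_distance_series(one, seg, width_px = 10)
  expect_true(all(!ts1$ok))
  expect_error(fit_tip_recoil(ts1), "usable frames")
})

test_that("tip recoil fit recovers A and tau within 10%", {
  tp <- make_tip_recoil_movie(D0 = 2, A = 2, tau = 5, seed = 6)
  ts <- tip_distance_series(tp$stack, tp$segment)
  fit <- fit_tip_recoil(ts)
  expect_lt(abs(fit$A - 2) / 2, 0.1)
  expect_lt(abs(fit$tau - 5) / 5, 0.1)
  expect_lt(abs(fit$D0 - 2) / 2, 0.1)
  # A = 0: constant series at D0
  tp0 <- make_tip_recoil_movie(D0 = 3, A = 0, tau = 5, n_frames = 10,
                               seed = 2)
  ts0 <- tip_distance_series(tp0$stack, tp0$segment)
  expect_lt(max(abs(ts0$distance_um - 3), na.rm = TRUE), 0.15)
  # unresolvable tips are declared in the truth
  expect_error(make_tip_recoil_movie(D0 = 2, A = 40, tau = 5),
               "exit the frame")
  tpn <- make_tip_recoil_movie(D0 = 0.2, A = 2, tau = 5, n_frames = 6,
                               seed = 3)
  expect_false(tpn$truth$resolvable[1])
})

test_that("ablation_event validates its fields", {
  expect_error(ablation_event(c(1, 2), 5, 5), "precede")
  expect_error(ablation_event(1, 0, 1), "\\(x, y\\)")
})
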