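# peaks, daughter spacings, CV, GLCM texture

test_that("detect_peaks finds sinusoid peaks with wrap-around", {
  # period 3 um over a 30 um periodic profile -> 10 peaks spaced 3 um
  pos <- seq(0, 30, length.out = 301)[1:300]
  prof <- intensity_profile(pos, sin(2 * pi * pos / 3), periodic = TRUE,
                            length_um = 30)
  pk <- detect_peaks(prof, min_prominence_frac = 0.1, min_distance_um = 1)
  expect_equal(length(pk$positions), 10L)
  expect_equal(daughter_diameters(pk), rep(3, 10), tolerance = 1e-3)

  # flat profile -> no peaks
  flat <- intensity_profile(pos, rep(2, 300), periodic = TRUE,
                            length_um = 30)
  expect_equal(length(detect_peaks(flat)$positions), 0L)

  expect_error(detect_peaks(intensity_profile(1:5, rnorm(5))), "too short")
})

test_that("daughter_diameters closes periodic rings exactly", {
  pk <- structure(list(positions = c(0, 3, 6, 9), values = rep(1, 4),
                       prominences = rep(1, 4), periodic = TRUE,
                       length_um = 12), class = "peak_set")
  expect_equal(daughter_diameters(pk), c(3, 3, 3, 3))
  pk2 <- structure(list(positions = c(0, 4), values = c(1, 1),
                        prominences = c(1, 1), periodic = FALSE,
                        length_um = 4), class = "peak_set")
  expect_equal(daughter_diameters(pk2), 4)
  pk1 <- pk2; pk1$positions <- 1; pk1$values <- 1; pk1$prominences <- 1
  expect_error(daughter_diameters(pk1), "at least 2")
  # periodic spacings always sum to the profile length
  set.seed(13)
  for (i in 1:20) {
    p <- sort(runif(sample(3:12, 1), 0, 20))
    pkr <- structure(list(positions = p, values = seq_along(p),
                          prominences = seq_along(p), periodic = TRUE,
                          length_um = 20), class = "peak_set")
    expect_equal(sum(daughter_diameters(pkr)), 20, tolerance = 1e-12)
  }
})

test_that("ring-layer scenes are recovered within tolerance", {
  rl <- make_ring_layer(n_daughters = 12, jitter_frac = 0, seed = 1)
  prof <- ellipse_band_profile(rl$frame, rl$ellipse, f = 0.85)
  pk <- detect_peaks(prof, 0.1, 1)
  expect_equal(length(pk$positions), 12L)
  sp <- daughter_diameters(pk)
  expect_equal(mean(sp), rl$truth$perimeter_um / 12, tolerance = 1e-6)
  expect_lt(stats::sd(sp) / mean(sp), 0.05)

  rl2 <- make_ring_layer(n_daughters = 12, jitter_frac = 0.05, seed = 2)
  pk2 <- detect_peaks(ellipse_band_profile(rl2$frame, rl2$ellipse), 0.1, 1)
  expect_equal(length(pk2$positions), 12L)
  m <- mean(daughter_diameters(pk2))
  expect_lt(abs(m - mean(rl2$truth$spacings_um)) /
              mean(rl2$truth$spacings_um), 0.02)
  # per-spacing recovery, matched cyclically by nearest position
  sp2 <- sort(daughter_diameters(pk2))
  expect_lt(max(abs(sp2 - sort(rl2$truth$spacings_um))), 0.35)
})

test_that("coefficient_of_variation matches hand arithmetic", {
  expect_equal(coefficient_of_variation(c(8, 10, 12)), 20)
  expect_equal(coefficient_of_variation(rep(5, 10)), 0)
  expect_error(coefficient_of_variation(7), "at least 2")
  expect_error(coefficient_of_variation(c(-3, 1)), "positive")
  # lognormal with sigma_log = 0.17 has CV ~= sqrt(exp(s^2)-1) ~= 17.1%
  set.seed(17)
  v <- rlnorm(20000, meanlog = 1, sdlog = 0.17)
  expect_equal(coefficient_of_variation(v),
               100 * sqrt(exp(0.17^2) - 1), tolerance = 0.03)
})

test_that("glcm_asm reproduces hand-checkable cases", {
  expect_equal(glcm_asm(matrix(5, 16, 16), offsets = rbind(c(0, 1))), 1)
  cb <- outer(1:16, 1:16, function(i, j) (i + j) %% 2)
  expect_equal(glcm_asm(cb, offsets = rbind(c(0, 1))), 0.5)
  # i.i.d. uniform 8-level noise -> ASM -> 1/64
  set.seed(1)
  u <- matrix(sample(0:7, 300 * 300, TRUE), 300)
  expect_equal(glcm_asm(u, offsets = rbind(c(0, 1))), 1 / 64,
               tolerance = 0.02)
  expect_error(glcm_asm(matrix(1, 1, 1), offsets = rbind(c(0, 1))),
               "pixel pairs|pixels")
})

test_that("glcm_asm is invariant to affine rescaling under rank binning", {
  img <- smooth_noise(80, 80, 2, seed = 6)
  a1 <- glcm_asm(img)
  expect_equal(glcm_asm(3.7 * img + 11), a1, tolerance = 1e-12)
  expect_equal(glcm_asm(-2 * img + 5),
               glcm_asm(-img), tolerance = 1e-12)
})

test_that("glcm_asm honours masks", {
  img <- smooth_noise(40, 40, 1, seed = 2)
  msk <- matrix(TRUE, 40, 40); msk[, 21:40] <- FALSE
  a_l <- glcm_asm(img[, 1:20], offsets = rbind(c(0, 1)))
  a_m <- glcm_asm(img, offsets = rbind(c(0, 1)), mask = msk)
  expect_equal(a_m, a_l, tolerance = 1e-12)
})

test_that("relative_homogeneity is ratio arithmetic with a unit reference", {
  ts <- relative_homogeneity(c(0.2, 0.2, 0.3, 0.35), reference_index = 2)
  expect_equal(ts$relative, c(1, 1, 1.5, 1.75))
  expect_equal(ts$relative[ts$reference_index], 1)
  expect_equal(relative_homogeneity(rep(0.4, 5), 3)$relative, rep(1, 5))
  expect_error(relative_homogeneity(c(0, 0.1), 1), "positive")
  expect_error(relative_homogeneity(c(0.1, 0.2), 5), "out of range")
})

test_that("dissolution movies homogenise after onset and recover", {
  dm <- make_dissolution_movie(n_frames = 30, onset_min = 10,
                               offset_min = 20, seed = 3)
  ts <- stack_texture_series(dm$stack, reference_index = 10)
  pre <- ts$relative[1:10]
  expect_lt(max(abs(pre - 1)), 0.05)
  # monotone non-decreasing rise during dissolution (to the floor plateau)
  rise <- ts$relative[11:20]
  expect_true(all(diff(rise) > -0.05 * max(rise)))
  expect_gt(max(rise), 2)
  # washout returns within 10% of the reference
  expect_lt(abs(ts$relative[30] - 1), 0.1)
})
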