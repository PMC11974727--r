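# synthetic-imaging generators: determinism, ground truth consistency

test_that("identical configs produce bit-identical scenes", {
  a <- make_trifurrow(c(100, 130, 130), noise_sd = 0.05, seed = 7)
  b <- make_trifurrow(c(100, 130, 130), noise_sd = 0.05, seed = 7)
  expect_identical(a$frame$intensity, b$frame$intensity)
  c <- make_trifurrow(c(100, 130, 130), noise_sd = 0.05, seed = 8)
  expect_false(identical(a$frame$intensity, c$frame$intensity))

  m1 <- make_migration_movie(n_nuclei = 15, n_frames = 3, seed = 4)
  m2 <- make_migration_movie(n_nuclei = 15, n_frames = 3, seed = 4)
  expect_identical(m1$stack$frames, m2$stack$frames)

  r1 <- make_recoil_movie(n_post = 4, seed = 5)
  r2 <- make_recoil_movie(n_post = 4, seed = 5)
  expect_identical(r1$stack$frames, r2$stack$frames)
})

test_that("trifurrow scenes: truth angles and noisy image measurement", {
  tf <- make_trifurrow(c(120, 120, 120), seed = 1)
  expect_equal(trifurrow_angles(tf$truth$annotation), c(120, 120, 120),
               tolerance = 1e-9)
  tf2 <- make_trifurrow(c(90, 90, 180), seed = 1)
  expect_equal(sort(trifurrow_angles(tf2$truth$annotation)),
               c(90, 90, 180), tolerance = 1e-9)
  expect_error(make_trifurrow(c(100, 100, 100)), "sum to 360")

  # image-based measurement within 3 degrees at 10% ridge-amplitude noise
  for (sd in 1:3) {
    tfn <- make_trifurrow(c(120, 120, 120), noise_sd = 0.1, seed = sd)
    ann <- estimate_trifurrow_rays(tfn$frame, tfn$truth$annotation$vertex)
    expect_lt(max(abs(trifurrow_angles(ann) - 120)), 3)
  }
})

test_that("foam sections honour Voronoi genericity and Lloyd convergence", {
  fs <- make_foam_section(n_cells = 20, seed = 4)
  expect_gte(length(fs$truth$vertices), 10)
  n3 <- vapply(fs$truth$vertices, function(v) v$n_labels, integer(1))
  expect_gte(mean(n3 == 3L), 0.9)  # generic junctions are 3-way

  # measured angles at 3-way truth vertices track the truth bearings
  errs <- c()
  for (v in fs$truth$vertices) {
    if (v$n_labels != 3L || length(v$bearings_deg) != 3L) next
    b <- sort(v$bearings_deg)
    truth_angles <- c(diff(b), 360 - (b[3] - b[1]))
    ends <- cbind(v$xy[1] + 10 * cos(v$bearings_deg * pi / 180),
                  v$xy[2] + 10 * sin(v$bearings_deg * pi / 180))
    meas <- trifurrow_angles(vertex_annotation(v$xy, ends))
    errs <- c(errs, abs(sort(meas) - sort(truth_angles)))
  }
  expect_lt(mean(errs), 5)

  # Lloyd relaxation homogenises cell sizes
  cv0 <- coefficient_of_variation(
    make_foam_section(n_cells = 20, n_lloyd = 0,
                      seed = 4)$truth$equivalent_diameter_um)
  cv5 <- coefficient_of_variation(fs$truth$equivalent_diameter_um)
  expect_lt(cv5, cv0)
  expect_error(make_foam_section(n_cells = 4), "at least 8")
})

test_that("migration movies scale sampling noise with nucleus count", {
  sd_of <- function(n, seed) {
    mm <- make_migration_movie(n_nuclei = n, n_frames = 8, A = 0,
                               seed = seed)
    ratios <- vapply(mm$truth$centroids, function(p) {
      cortical_ratio(p, mm$truth$ellipse, f = sqrt(0.5))$ratio
    }, numeric(1))
    stats::sd(ratios)
  }
  s1 <- mean(vapply(1:6, function(s) sd_of(40, s), numeric(1)))
  s2 <- mean(vapply(1:6, function(s) sd_of(160, s), numeric(1)))
  expect_lt(s2, s1)           # noise shrinks with n
  expect_lt(s2 / s1, 0.75)    # roughly binomial ~ 1/sqrt(4) = 0.5
})

test_that("recoil movies: zero velocity gives a null field; repair flips sign", {
  rc0 <- make_recoil_movie(v0 = 0, n_post = 4, noise_sd = 0, seed = 2)
  post <- which(rc0$stack$times > rc0$event$end_s)
  f <- piv_field(rc0$stack$frames[[post[1]]], rc0$stack$frames[[post[2]]],
                 32, 16, 1, rc0$stack$pixel_size)
  expect_lt(max(abs(c(f$vectors$u, f$vectors$v))), 1e-6)

  rcr <- make_recoil_movie(v0 = 0.25, tau = 3, t_repair_s = 8,
                           v_repair = 0.12, n_post = 18, seed = 9)
  recs <- piv_recoil_records(rcr$stack, rcr$event, resample_s = 3)
  early <- recs[recs$t_s > 0 & recs$t_s <= 6, ]
  late <- recs[recs$t_s > 9 & recs$t_s <= 15, ]
  expect_gt(mean(early$v_rad_um_s), 0)
  expect_lt(mean(late$v_rad_um_s), 0)
  expect_error(make_recoil_movie(v0 = 40, tau = 50),
               "half a PIV window")
})

test_that("generators emit truth in analysis units", {
  rl <- make_ring_layer(n_daughters = 10, seed = 3)
  expect_equal(sum(rl$truth$spacings_um), rl$truth$perimeter_um,
               tolerance = 1e-9)
  tp <- make_tip_recoil_movie(seed = 1, n_frames = 5)
  expect_equal(tp$truth$D_um[1], tp$truth$D0)
  dm <- make_dissolution_movie(n_frames = 5, onset_min = 10, seed = 1)
  expect_equal(dm$truth$amplitude, rep(1, 5))
})
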