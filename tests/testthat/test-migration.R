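test_that("speed filtering removes sub-threshold vectors, keeping the boundary", {
  f <- tibble::tibble(u_um_h = c(5, 10, 15), v_um_h = 0)
  kept <- speed_filter(f)
  expect_equal(kept$speed_um_h, c(10, 15))
  expect_equal(nrow(speed_filter(tibble::tibble(u_um_h = rep(5, 4),
                                                v_um_h = 0))), 0L)
  # retained count matches a brute-force filter on a seeded mixed field
  sim <- sim_velocity_fields(static_fraction = 0.4, seed = 8)
  speeds <- sqrt(sim$fields$u_um_h^2 + sim$fields$v_um_h^2)
  expect_equal(nrow(speed_filter(sim$fields)), sum(speeds >= 10))
})

test_that("a delta distribution concentrates in one bin", {
  f <- tibble::tibble(u_um_h = rep(20, 7), v_um_h = 0)
  d <- angular_distribution(f)
  zero_bin <- which(d$bin_start_deg <= 0 & d$bin_end_deg > 0)
  expect_equal(d$frequency[zero_bin], 1)
  expect_equal(d$relative_angular_speed_um_h[zero_bin], 20)
  expect_true(all(d$relative_angular_speed_um_h[-zero_bin] == 0))
})

test_that("a hand-computed two-vector case gives the stated bin statistics", {
  f <- tibble::tibble(u_um_h = c(10, 0), v_um_h = c(0, 30))
  d <- angular_distribution(f)
  b0 <- which(d$bin_start_deg <= 0 & d$bin_end_deg > 0)
  b90 <- which(d$bin_start_deg <= 90 & d$bin_end_deg > 90)
  expect_equal(d$frequency[c(b0, b90)], c(0.5, 0.5))
  expect_equal(d$relative_angular_speed_um_h[c(b0, b90)], c(5, 15))
})

test_that("frequencies sum to one and weighted speeds sum to the mean", {
  sim <- sim_velocity_fields(mean_angle_deg = 35, kappa = 1.5, seed = 12)
  retained <- speed_filter(sim$fields)
  d <- angular_distribution(retained)
  expect_lt(abs(sum(d$frequency) - 1), 1e-12)
  expect_lt(abs(sum(d$relative_angular_speed_um_h) - mean(retained$speed_um_h)),
            1e-12)
  expect_error(angular_distribution(tibble::tibble(u_um_h = 1, v_um_h = 0)
                                    [0, ]), "retained")
})

test_that("rotating all vectors by one bin shifts the histogram by one bin", {
  sim <- sim_velocity_fields(mean_angle_deg = 10, kappa = 2, seed = 21)
  retained <- speed_filter(sim$fields)
  d1 <- angular_distribution(retained)
  th <- 30 * pi / 180
  rot <- dplyr::mutate(retained,
                       u2 = u_um_h * cos(th) - v_um_h * sin(th),
                       v2 = u_um_h * sin(th) + v_um_h * cos(th),
                       u_um_h = u2, v_um_h = v2)
  d2 <- angular_distribution(rot)
  expect_equal(d2$frequency, d1$frequency[c(12, 1:11)], tolerance = 1e-12)
})

test_that("the Gaussian fit finds the major angle of synthetic flows", {
  # symmetric unimodal histogram centered on zero
  sym <- c(-1, -0.7, -0.35, 0, 0, 0.35, 0.7, 1)
  f <- tibble::tibble(u_um_h = 20 * cos(sym), v_um_h = 20 * sin(sym))
  fit0 <- gaussian_major_angle(angular_distribution(f))
  expect_lt(abs(fit0$mean_deg), 5)
  expect_gt(fit0$amplitude, 0)
  # seeded von Mises fields recover the generating direction within 5 deg
  for (ang in c(0, 40, -120)) {
    sim <- sim_velocity_fields(mean_angle_deg = ang, kappa = 4,
                               static_fraction = 0.1, seed = 33 + ang)
    fit <- gaussian_major_angle(angular_distribution(speed_filter(sim$fields)))
    diff <- abs(((fit$mean_deg - ang + 180) %% 360) - 180)
    expect_lt(diff, 5)
  }
  expect_error(gaussian_major_angle(
    angular_distribution(tibble::tibble(u_um_h = 20, v_um_h = 0))), "nonzero")
})

test_that("major-angle comparisons separate distinct conditions", {
  set.seed(3)
  fits <- tibble::tibble(condition = rep(c("wt", "kd"), each = 5),
                         mean_deg = c(rnorm(5, 0, 5), rnorm(5, 45, 5)))
  res <- compare_major_angles(fits)
  expect_lt(res$anova$p.value, 0.01)
  same <- tibble::tibble(condition = rep(c("a", "b"), each = 5),
                         mean_deg = rep(rnorm(5, 0, 5), 2))
  expect_gt(compare_major_angles(same)$anova$p.value, 0.95)
  expect_error(compare_major_angles(fits[1:5, ]), ">= 2")
})

test_that("tissue segmentation selects the textured region", {
  set.seed(9)
  img <- matrix(0.5, 60, 60)
  img[, 1:30] <- img[, 1:30] + runif(60 * 30)
  mask <- segment_tissue(img)
  expect_gt(mean(mask[, 1:28]), 0.9)
  expect_lt(mean(mask[, 33:60]), 0.1)
  expect_error(segment_tissue(matrix(1, 20, 20)), "uniform")
  # idempotent on its own output region: mask of the masked texture stays put
  img2 <- img; img2[!mask] <- 0.5
  mask2 <- segment_tissue(img2)
  expect_gt(sum(mask2 & mask) / sum(mask2), 0.95)
})

test_that("block velocimetry recovers rigid shifts and flags flat fields", {
  set.seed(14)
  big <- matrix(runif(96 * 96), 96, 96)
  a <- big[1:64, 1:64]
  b <- big[1:64 + 3, 1:64]      # content moved up by 3 rows
  vf <- block_velocimetry(a, b, window = 32, overlap = 0.5, dt_h = 1,
                          px_um = 1)
  # interior windows (the true match of the first row leaves the frame)
  int <- vf$y_um > 20
  expect_true(all(vf$valid[int]))
  expect_true(all(abs(vf$v_um_h[int] - (-3)) < 1e-9))
  expect_true(all(vf$u_um_h[int] == 0))
  vf0 <- block_velocimetry(a, a, window = 32)
  expect_true(all(vf0$u_um_h == 0 & vf0$v_um_h == 0))
  flat <- matrix(1, 64, 64)
  vff <- block_velocimetry(flat, flat, window = 32)
  expect_true(all(!vff$valid))
})
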