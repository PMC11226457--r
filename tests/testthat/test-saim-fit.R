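sweep <- angle_sweep()
optics <- layer_stack()

test_that("noiseless profiles are recovered to 0.1 nm and 0.1% in A, B", {
  for (h in c(25, 55.93, 100, 147)) {
    I <- 500 * excitation_profile(h, sweep, optics) + 50
    fit <- fit_saim_pixel(I, sweep, optics)
    expect_lt(abs(fit$height_nm - h), 0.1)
    expect_lt(abs(fit$amplitude - 500) / 500, 0.001)
    expect_lt(abs(fit$offset - 50) / 50, 0.001)
    expect_true(fit$converged)
  }
})

test_that("multi-start LM equals the exhaustive grid-search oracle", {
  set.seed(41)
  for (i in 1:20) {
    h <- runif(1, 5, 195)
    A <- runif(1, 100, 1000)
    B <- runif(1, 0, 200)
    I <- A * excitation_profile(h, sweep, optics) + B
    fit <- fit_saim_pixel(I, sweep, optics)
    oracle <- oracle_grid_fit(I, sweep, optics)
    expect_lt(abs(fit$height_nm - oracle$h), 0.011)
    expect_lte(fit$residual_ss, oracle$rss + 1e-8)
  }
})

test_that("forward-inverse consistency holds over a grid of heights", {
  for (h in seq(10, 150, by = 10)) {
    I <- 300 * excitation_profile(h, sweep, optics) + 20
    fit <- fit_saim_pixel(I, sweep, optics)
    expect_lt(abs(fit$height_nm - h), 0.1)
  }
})

test_that("all-constant intensities are flagged unidentifiable", {
  fit <- fit_saim_pixel(rep(100, length(sweep)), sweep, optics)
  expect_false(fit$converged)
  expect_error(fit_saim_pixel(c(NA, rep(1, 13)), sweep, optics), "finite")
})

test_that("uniform synthetic stacks fit to the true height everywhere", {
  sim <- sim_saim_stack(80, nrow = 8, ncol = 8, noise_frac = 0, seed = 1)
  res <- fit_saim_stack(sim$image_stack, sweep, optics)
  expect_true(all(abs(res$fits$height_nm - 80) < 0.1))
})

test_that("a two-level phantom recovers both region heights", {
  hm <- matrix(50, 10, 10)
  hm[, 6:10] <- 90
  sim <- sim_saim_stack(hm, noise_frac = 0.01, seed = 3)
  res <- fit_saim_stack(sim$image_stack, sweep, optics)
  left <- roi_zcenter(res$height_map, col(hm) <= 5, "left")
  right <- roi_zcenter(res$height_map, col(hm) > 5, "right")
  expect_lt(abs(left$z_center_nm - 50), 2)
  expect_lt(abs(right$z_center_nm - 90), 2)
})

test_that("fits are computed only inside the mask", {
  sim <- sim_saim_stack(70, nrow = 6, ncol = 6, noise_frac = 0, seed = 1)
  mask <- matrix(FALSE, 6, 6)
  mask[, 1:3] <- TRUE
  res <- fit_saim_stack(sim$image_stack, sweep, optics, mask = mask)
  expect_true(all(is.na(res$height_map[!mask])))
  expect_true(all(is.finite(res$height_map[mask])))
  expect_identical(nrow(res$fits), sum(mask))
  expect_error(fit_saim_stack(sim$image_stack, sweep, optics,
                              mask = matrix(FALSE, 6, 6)), "no pixels")
})

test_that("per-pixel height errors stay under 2 nm at 2% noise", {
  sim <- sim_saim_stack(55.93, nrow = 32, ncol = 32, noise_frac = 0.02, seed = 11)
  res <- fit_saim_stack(sim$image_stack, sweep, optics)
  err <- res$fits$height_nm - 55.93
  expect_lt(abs(median(err)), 2)
})

test_that("the ROI median follows the stated conventions", {
  m <- matrix(46.56, 4, 4)
  expect_equal(roi_zcenter(m)$z_center_nm, 46.56)
  m2 <- matrix(c(50, 60, NA, NaN), 2, 2)
  z <- roi_zcenter(m2)
  expect_equal(z$z_center_nm, 55)        # even-count median convention
  expect_equal(z$n_pixels, 2L)
  expect_equal(z$n_nonfinite, 2L)
  expect_error(roi_zcenter(matrix(NA_real_, 2, 2)), "finite")
})

test_that("the ROI median is permutation-invariant and outlier-robust", {
  set.seed(5)
  vals <- runif(101, 60, 70)
  m <- matrix(c(vals, rep(NA, 43)), 12, 12)
  z1 <- roi_zcenter(m)$z_center_nm
  m2 <- matrix(c(sample(vals), rep(NA, 43)), 12, 12)
  expect_equal(roi_zcenter(m2)$z_center_nm, z1)
  # replace 49 of 101 values by in-bounds outliers: median moves < spread
  vals3 <- vals
  vals3[1:49] <- 200
  m3 <- matrix(c(vals3, rep(NA, 43)), 12, 12)
  expect_lt(roi_zcenter(m3)$z_center_nm, 70)
})

test_that("topographic rendering is deterministic and clamps its range", {
  hm <- matrix(c(10, 80, 200, 90), 2, 2)
  p1 <- plot_height_map(hm)
  expect_s3_class(p1, "ggplot")
  expect_equal(range(p1$data$height_nm), c(40, 140))
  expect_identical(p1$data, plot_height_map(hm)$data)
  expect_error(plot_height_map(hm, c(100, 50)))
})
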