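make_track <- function(d, times = seq(-6, 30, by = 2)) {
  tr <- tibble::tibble(time_s = times,
                       e1x_um = -d / 2, e1y_um = 0,
                       e2x_um = d / 2, e2y_um = 0)
  attr(tr, "ablation_time_s") <- 0
  tr
}

test_that("edge distance is Euclidean", {
  tr <- tibble::tibble(time_s = 0:1, e1x_um = 0, e1y_um = 0,
                       e2x_um = c(0, 3), e2y_um = c(0, 4))
  expect_equal(edge_distance(tr)$distance_um, c(0, 5))
  expect_error(edge_distance(dplyr::mutate(tr, e1x_um = NA)), "finite")
})

test_that("edge distance is invariant under rigid motions", {
  sim <- sim_recoil_track(noise_um = 0.02, seed = 4)
  d0 <- edge_distance(sim$track)$distance_um
  th <- 0.7
  rot <- function(x, y) list(x = cos(th) * x - sin(th) * y,
                             y = sin(th) * x + cos(th) * y)
  tr <- sim$track
  a <- rot(tr$e1x_um, tr$e1y_um); b <- rot(tr$e2x_um, tr$e2y_um)
  tr2 <- dplyr::mutate(tr, e1x_um = a$x + 5, e1y_um = a$y - 2,
                       e2x_um = b$x + 5, e2y_um = b$y - 2)
  expect_equal(edge_distance(tr2)$distance_um, d0, tolerance = 1e-12)
})

test_that("the synthetic recoil track matches its analytic distance law", {
  sim <- sim_recoil_track(ballistic_rate = 1.5, saturation_tau = 8,
                          d0 = 2, noise_um = 0, seed = 1)
  d <- edge_distance(sim$track)
  tt <- d$time_s
  d_ball_end <- 2 + 1.5 * 4
  d_plat <- d_ball_end + 1.5 * 8 / 2
  expected <- ifelse(tt < 0, 2,
                     ifelse(tt <= 4, 2 + 1.5 * tt,
                            d_plat - (d_plat - d_ball_end) * exp(-(tt - 4) / 8)))
  expect_equal(d$distance_um, expected, tolerance = 1e-9)
})

test_that("initial recoil is the first-2-s secant", {
  # separation grows 1 um per 2-s frame -> 0.5 um/s
  d <- c(rep(2, 3), 2 + (0:15))
  expect_equal(initial_recoil(make_track(d))$initial_rate_um_s, 0.5)
  expect_equal(initial_recoil(make_track(rep(2, 19)))$initial_rate_um_s, 0)
  # noiseless generator: secant equals the ballistic rate exactly
  sim <- sim_recoil_track(ballistic_rate = 1.77, noise_um = 0, seed = 1)
  expect_equal(initial_recoil(sim$track)$initial_rate_um_s, 1.77)
})

test_that("missing post-ablation frames are reported", {
  tr <- make_track(c(2, 2, 2, 3, 4), times = c(-6, -4, -2, 0, 8))
  expect_error(initial_recoil(tr), "gap")
})

test_that("seeded noisy tracks recover the configured rate within 5%", {
  rates <- vapply(1:20, function(i) {
    sim <- sim_recoil_track(ballistic_rate = 1.77, noise_um = 0.05, seed = i)
    initial_recoil(sim$track)$initial_rate_um_s
  }, numeric(1))
  expect_lt(abs(mean(rates) - 1.77) / 1.77, 0.05)
})

test_that("recoil trajectories conserve n per frame", {
  tracks <- lapply(1:5, function(i) sim_recoil_track(noise_um = 0.05,
                                                     seed = i)$track)
  traj <- recoil_trajectory(tracks)
  expect_true(all(traj$n == 5))
  expect_equal(nrow(traj), 19)
})

test_that("condition comparisons separate distinct recoil rates", {
  gen <- function(cond, rate, seeds) {
    tibble::tibble(condition = cond,
                   initial_rate_um_s = vapply(seeds, function(i) {
                     initial_recoil(sim_recoil_track(ballistic_rate = rate,
                                                     noise_um = 0.2,
                                                     seed = i)$track
                                    )$initial_rate_um_s
                   }, numeric(1)))
  }
  wt <- gen("wt", 1.77, 1:20)
  kd <- gen("kd", 1.34, 21:40)
  res <- compare_recoil(dplyr::bind_rows(wt, kd))
  expect_lt(res$anova$p.value, 0.001)
  expect_lt(res$pairwise$p_sidak[1], 0.001)
  # identical groups: adjusted p near 1
  same <- dplyr::bind_rows(wt, dplyr::mutate(gen("wt2", 1.77, 1:20),
                                             condition = "wt2"))
  expect_gt(compare_recoil(same)$pairwise$p_sidak[1], 0.9)
  expect_error(compare_recoil(wt), ">= 2")
})
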