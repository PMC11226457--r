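test_that("double normalization reproduces a hand-evaluated example", {
  # 2 pre-bleach frames with ref = frap = 100 over background 10, then a
  # frame with ref 100, frap 55: background-subtracted pre means are 90,
  # i_norm = (90/90) * (45/90) = 0.5
  tr <- tibble::tibble(time_s = 0:2,
                       i_frap = c(100, 100, 55),
                       i_ref = c(100, 100, 100),
                       i_back = 10)
  out <- frap_double_normalize(tr, bleach_index = 2)
  expect_equal(out$i_norm[3], 0.5)
  expect_equal(out$i_norm[1:2], c(1, 1))
})

test_that("identical ROIs and constant signals normalize to one", {
  tr <- tibble::tibble(time_s = 0:9, i_frap = seq(200, 110, by = -10),
                       i_ref = seq(200, 110, by = -10), i_back = 25)
  expect_equal(frap_double_normalize(tr)$i_norm, rep(1, 10))
  tr2 <- tibble::tibble(time_s = 0:9, i_frap = 300, i_ref = 300, i_back = 0)
  expect_equal(frap_double_normalize(tr2)$i_norm, rep(1, 10))
})

test_that("degenerate traces fail with named frames", {
  tr <- tibble::tibble(time_s = 0:5, i_frap = 100,
                       i_ref = c(100, 100, 100, 5, 100, 100), i_back = 10)
  expect_error(frap_double_normalize(tr), "frame\\(s\\) 4")
  tr2 <- tibble::tibble(time_s = 0:5, i_frap = 10, i_ref = 100, i_back = 10)
  expect_error(frap_double_normalize(tr2), "zero")
})

test_that("full-scale calibration reproduces a hand-evaluated example", {
  # i_norm_pre = 1, bleach value 0.2: 0.6 maps to (0.6-0.2)/0.8 = 0.5
  tr <- tibble::tibble(time_s = 0:4, i_norm = c(1, 1, 0.2, 0.6, 1))
  attr(tr, "bleach_index") <- 2
  out <- frap_full_scale(tr)
  expect_equal(out$i_norm1, c(1, 1, 0, 0.5, 1))
  flat <- tibble::tibble(time_s = 0:4, i_norm = rep(1, 5))
  attr(flat, "bleach_index") <- 2
  expect_error(frap_full_scale(flat), "bleach depth")
})

test_that("the normalization chain anchors pre-bleach at 1 and bleach at 0", {
  for (seed in 1:5) {
    sim <- sim_frap_trace(p = 0.5, k = 0.04, noise_sd = 0.05, seed = seed)
    out <- frap_normalize(sim$trace)
    expect_lt(abs(mean(out$i_norm1[1:4]) - 1), 1e-12)
    expect_lt(abs(out$i_norm1[5]), 1e-12)
  }
})

test_that("normalization is invariant under common rescaling of raw channels", {
  sim <- sim_frap_trace(noise_sd = 0.03, seed = 9)
  a <- frap_normalize(sim$trace)
  scaled <- dplyr::mutate(sim$trace, i_frap = i_frap * 3.7,
                          i_ref = i_ref * 3.7, i_back = i_back * 3.7)
  b <- frap_normalize(scaled)
  expect_equal(b$i_norm1, a$i_norm1, tolerance = 1e-12)
})

test_that("noiseless recovery fits return the generating parameters", {
  k <- 0.0341
  sim <- sim_frap_trace(p = 0.4, k = k, noise_sd = 0, photobleach_rate = 0.004,
                        seed = 1)
  fit <- fit_frap_recovery(frap_normalize(sim$trace))
  expect_lt(abs(fit$p - 0.4), 1e-6)
  expect_lt(abs(fit$k - k), 1e-6)
  # half-life identity
  expect_equal(fit$half_life_s, log(2) / fit$k)
  k2 <- log(2) / 29.02
  sim2 <- sim_frap_trace(p = 0.331, k = k2, noise_sd = 0, seed = 1)
  fit2 <- fit_frap_recovery(frap_normalize(sim2$trace))
  expect_equal(fit2$half_life_s, 29.02, tolerance = 1e-5)
})

test_that("acquisition photobleaching is removed by the normalization", {
  sim <- sim_frap_trace(p = 0.6, k = 0.05, noise_sd = 0,
                        photobleach_rate = 0.01, seed = 1)
  fit <- fit_frap_recovery(frap_normalize(sim$trace))
  expect_lt(abs(fit$p - 0.6), 1e-6)
})

test_that("parameter recovery over a (p, k) grid stays within tolerance", {
  p_err <- c(); k_rel <- c()
  i <- 0
  for (p in c(0.2, 0.5, 0.8)) {
    for (k in c(0.01, 0.05, 0.1)) {
      i <- i + 1
      sim <- sim_frap_trace(p = p, k = k, noise_sd = 0.05, seed = 300 + i)
      fit <- fit_frap_recovery(frap_normalize(sim$trace))
      p_err <- c(p_err, abs(fit$p - p))
      k_rel <- c(k_rel, abs(fit$k - k) / k)
    }
  }
  expect_lt(median(p_err), 0.03)
  expect_lt(median(k_rel), 0.10)
})

test_that("tidy and glance expose the fitted quantities", {
  sim <- sim_frap_trace(seed = 2)
  fit <- fit_frap_recovery(frap_normalize(sim$trace))
  td <- tidy(fit)
  expect_identical(td$term, c("p", "k"))
  gl <- glance(fit)
  expect_true(all(c("mobile_fraction", "half_life_s", "converged") %in% names(gl)))
  expect_s3_class(autoplot(fit, frap_normalize(sim$trace)), "ggplot")
})

test_that("group summaries and ANOVA behave on simulated conditions", {
  set.seed(17)
  make_group <- function(cond, mu, n = 20) {
    tibble::tibble(condition = cond,
                   mobile_fraction = rnorm(n, mu, 0.02),
                   half_life_s = rnorm(n, 29, 2))
  }
  same <- dplyr::bind_rows(make_group("a", 0.4), make_group("b", 0.4))
  res <- summarize_frap_groups(same)
  expect_gt(res$anova$p.value[res$anova$quantity == "mobile_fraction"], 0.05)
  sep <- dplyr::bind_rows(make_group("wt", 0.33), make_group("kd", 0.55))
  res2 <- summarize_frap_groups(sep)
  expect_lt(res2$anova$p.value[res2$anova$quantity == "mobile_fraction"], 0.001)
  expect_error(summarize_frap_groups(make_group("only", 0.4)), ">= 2")
})
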