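test_that("relative_rank agrees with the count-and-interpolate oracle", {
  set.seed(11)
  for (rep in 1:20) {
    stats <- sample(round(rnorm(20), 2))  # rounded: ties occur
    rd <- make_rd(stats)
    probes <- c(runif(100, min(stats) - 0.5, max(stats) + 0.5),
                sample(stats, 5))
    got <- relative_rank(rd, probes)
    want <- vapply(probes, oracle_relative_rank, 0, stats = stats)
    expect_equal(got, want, tolerance = 1e-12)
    expect_true(all(got > 0 & got < 1))
  }
})

test_that("relative_rank clamps, centers and tie-breaks as specified", {
  rd <- make_rd(seq_len(1001))  # odd R, distinct values
  expect_equal(relative_rank(rd, 501), 0.5)
  rd1000 <- make_rd(seq_len(1000) / 10)
  expect_equal(relative_rank(rd1000, -5), 0.5 / 1000)
  expect_equal(relative_rank(rd1000, 1e6), 1 - 0.5 / 1000)
  # tied run takes the midpoint of its plotting positions
  rd_tie <- make_rd(c(1, 2, 2, 2, 3))
  expect_equal(relative_rank(rd_tie, 2), 0.5)
  expect_equal(relative_rank(rd_tie, 2), oracle_relative_rank(c(1, 2, 2, 2, 3), 2))
})

test_that("build_rd reproduces the enumerated two-draw mean distribution", {
  # n = 3 values {1,2,3}, m = 2, estimator mean: 9 equiprobable ordered
  # draws give support {1, 1.5, 2, 2.5, 3} with weights 1,2,3,2,1 (/9)
  support <- c(1, 1.5, 2, 2.5, 3)
  weights <- c(1, 2, 3, 2, 1) / 9
  mu <- sum(support * weights)
  sigma <- sqrt(sum(support^2 * weights) - mu^2)
  rd <- build_rd(c(1, 2, 3), m = 2, R = 10000, estimator = "mean", seed = 5)
  expect_true(all(rd$sorted_stats %in% support))
  expect_lt(abs(mean(rd$sorted_stats) - mu), 3 * sigma / sqrt(10000))
})

test_that("build_rd is deterministic and validates the resampling range", {
  x <- rnorm(50)
  a <- build_rd(x, 5, 600, "sd", seed = 3)
  b <- build_rd(x, 5, 600, "sd", seed = 3)
  expect_identical(a$sorted_stats, b$sorted_stats)
  expect_error(build_rd(x, 5, 100, "sd"), class = "resa_config_error")
  expect_error(build_rd(x, 5, 20000, "sd"), class = "resa_config_error")
  # degenerate population: RD of zeros for sd
  rd0 <- build_rd(rep(4, 30), 5, 500, "sd", seed = 1)
  expect_true(all(rd0$sorted_stats == 0))
  # a ratio estimator can never stabilize on a constant population
  expect_error(build_rd(rep(4, 30), 5, 500, "mean_over_sd", seed = 1),
               class = "resa_degenerate_rd")
})

test_that("GPD maximum likelihood recovers known tail parameters", {
  # single-fit sampling error at these n is comparable to the recovery
  # tolerance, so the check averages independent fits: the mean estimate
  # isolates bias from Monte Carlo noise
  recover <- function(n, shape, scale, reps = 20) {
    fits <- vapply(seq_len(reps), function(s) {
      y <- resanno:::with_seed(2000 + s, roracle_gpd(n, shape, scale))
      f <- fit_gpd(y)
      expect_true(f$converged)
      c(f$shape, f$scale)
    }, numeric(2))
    rowMeans(fits)
  }
  # exponential exceedances are the shape-zero limit
  est_exp <- recover(200, 0, 1)
  expect_lt(abs(est_exp[1]), 0.15)
  expect_lt(abs(est_exp[2] - 1), 0.15)
  # heavy tail, shape 0.3, scale 2
  est <- recover(500, 0.3, 2)
  expect_lt(abs(est[1] - 0.3), 0.1)
  expect_lt(abs(est[2] - 2) / 2, 0.10)
  expect_error(fit_gpd(c(1, 2, 3, 4, 5)), class = "resa_config_error")
})

test_that("fit_gpd_tail validates the tail fraction and exceedance count", {
  x <- resanno:::with_seed(30, rnorm(300))
  rd <- build_rd(x, 8, 1000, "mean", seed = 2)
  expect_error(fit_gpd_tail(rd, "upper", 0.5), class = "resa_config_error")
  expect_error(fit_gpd_tail(rd, "upper", 0.005), class = "resa_config_error")
  fit <- fit_gpd_tail(rd, "upper", 0.02)
  expect_equal(fit$n_exceedances, 20L)
  expect_equal(fit$threshold, rd$sorted_stats[980])
})

test_that("p-values follow the clamp, sidedness and GPD contracts", {
  rd <- make_rd(seq_len(1001))
  expect_equal(p_value(rd, 501, "two_sided", gpd = FALSE)$p, 1.0)
  rd1000 <- make_rd(sort(resanno:::with_seed(7, rnorm(1000))))
  mx <- max(rd1000$sorted_stats)
  pv_off <- p_value(rd1000, mx + 1, "upper", gpd = FALSE)
  expect_equal(pv_off$p, 0.0005)
  expect_equal(pv_off$method, "empirical_interpolated")
  pv_on <- p_value(rd1000, mx + 1, "upper", gpd = TRUE)
  expect_equal(pv_on$method, "gpd_upper")
  expect_gt(pv_on$p, 0)
  expect_lt(pv_on$p, 0.02)
  pv_lo <- p_value(rd1000, min(rd1000$sorted_stats) - 1, "lower", gpd = TRUE)
  expect_equal(pv_lo$method, "gpd_lower")
  expect_gt(pv_lo$p, 0)
})

test_that("empirical and GPD tail probabilities agree at the threshold", {
  x <- resanno:::with_seed(41, rnorm(500))
  rd <- build_rd(x, 10, 1000, "sd", seed = 9)
  for (tail in c("upper", "lower")) {
    fit <- fit_gpd_tail(rd, tail, 0.02)
    expect_true(fit$converged)
    p_gpd <- resanno:::gpd_tail_prob(fit, fit$threshold)
    rr <- relative_rank(rd, fit$threshold)
    p_emp <- if (tail == "upper") 1 - rr else rr
    expect_lt(abs(p_emp - p_gpd), 0.005)
  }
})

test_that("one-sided p is monotone in the statistic, two-sided peaks at the median", {
  rd <- make_rd(sort(resanno:::with_seed(12, rnorm(999))))
  grid <- seq(min(rd$sorted_stats) - 1, max(rd$sorted_stats) + 1, length = 200)
  p_up <- vapply(grid, function(e) p_value(rd, e, "upper", gpd = FALSE)$p, 0)
  expect_true(all(diff(p_up) <= 1e-12))
  p_two <- vapply(grid, function(e) p_value(rd, e, "two_sided", gpd = FALSE)$p, 0)
  med <- stats::median(rd$sorted_stats)
  expect_equal(p_value(rd, med, "two_sided", gpd = FALSE)$p, 1.0)
  expect_true(all(p_two <= 1))
  # resolution floor with GPD off: 0.5 / R one-sided
  expect_equal(min(p_up), 0.5 / rd$R)
})

test_that("the RD cache shares distributions across terms of equal size", {
  x <- resanno:::with_seed(50, rnorm(200))
  cache <- rd_cache()
  rd_a <- rd_cache_get_or_build(cache, x, 11, 500, "sd", base_seed = 1)
  rd_b <- rd_cache_get_or_build(cache, x, 11, 500, "sd", base_seed = 1)
  rd_c <- rd_cache_get_or_build(cache, x, 12, 500, "sd", base_seed = 1)
  expect_identical(rd_a$sorted_stats, rd_b$sorted_stats)
  expect_equal(cache$n_built, 2L)
  expect_equal(cache$n_reused, 1L)
  expect_false(identical(rd_a$sorted_stats, rd_c$sorted_stats))
  # a fresh cache rebuilds identically under the same base seed
  cache2 <- rd_cache()
  rd_a2 <- rd_cache_get_or_build(cache2, x, 11, 500, "sd", base_seed = 1)
  expect_identical(rd_a2$sorted_stats, rd_a$sorted_stats)
})
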