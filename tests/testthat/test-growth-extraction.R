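test_that("log-growth curves are exact for clean exponentials", {
  times <- seq(0, 168, by = 4)
  mu_h <- 0.05  # per hour
  series <- data.frame(replicate_id = "rep1", row = 2L, col = 3L,
                       time_h = times,
                       intensity = 80 + 1000 * exp(mu_h * times),
                       n0_cells = 3L)
  curve <- to_growth_curve(series, background = 80)
  expect_s3_class(curve, "growth_curve")
  expect_identical(curve$log_ratio[1], 0)
  expect_equal(curve$log_ratio, mu_h * times, tolerance = 1e-12)
  # constant intensity -> all-zero log ratio
  flat <- series; flat$intensity <- 500
  expect_equal(to_growth_curve(flat, 80)$log_ratio, rep(0, length(times)))
})

test_that("habitats without signal are excluded, noisy dips are masked", {
  times <- seq(0, 168, by = 4)
  empty <- data.frame(replicate_id = "rep1", row = 1L, col = 1L,
                      time_h = times, intensity = 80, n0_cells = 0L)
  ex <- to_growth_curve(empty, 80)
  expect_s3_class(ex, "growth_exclusion")
  expect_identical(ex$reason, "EMPTY")
  below <- data.frame(replicate_id = "rep1", row = 1L, col = 1L,
                      time_h = times, intensity = 70, n0_cells = 2L)
  expect_identical(to_growth_curve(below, 80)$reason, "NONPOSITIVE_I0")
  # a single dip below background is masked, not dropped
  dip <- data.frame(replicate_id = "rep1", row = 1L, col = 1L,
                    time_h = times, intensity = 80 + 100 * exp(0.02 * times),
                    n0_cells = 2L)
  dip$intensity[10] <- 60
  curve <- to_growth_curve(dip, 80)
  expect_identical(curve$n_masked, 1L)
  expect_true(is.na(curve$log_ratio[10]))
  expect_length(curve$log_ratio, length(times))
})

test_that("a perfectly linear curve returns its slope for every window", {
  times <- seq(0, 168, by = 4)
  curve <- make_curve(times, 0.05 * times)  # 0.05 / h = 1.2 / day
  rec <- sliding_window_rate(curve, n = 9, min_time_days = 1.3)
  expect_equal(rec$mu, 1.2, tolerance = 1e-12)
  expect_true(rec$window_center_time >= 1.3 * 24)
  # exact ties (integer-exact slope values) resolve to the earliest window
  exact <- make_curve(times, 0.25 * times)  # every product exact in binary
  rec2 <- sliding_window_rate(exact, n = 9, min_time_days = 1.3)
  expect_identical(rec2$mu, 6)
  first_ok <- which(rec2$all_centers >= 1.3 * 24)[1]
  expect_identical(rec2$window_index, first_ok)
})

test_that("sliding-window extractor agrees with brute-force enumeration", {
  set.seed(2024)
  for (i in 1:60) {
    curve <- random_curve()
    rec <- sliding_window_rate(curve, n = 9, min_time_days = 1.3)
    oracle <- brute_force_rate(curve$times, curve$log_ratio, 9, 1.3)
    expect_equal(rec$mu, oracle$mu, tolerance = 1e-10)
    expect_equal(rec$window_center_time, oracle$center)
    expect_identical(rec$window_index, oracle$index)
  }
})

test_that("the time threshold excludes early transients", {
  times <- seq(0, 168, by = 4)
  # steep rise over before every admissible window, flat afterwards
  lr <- pmin(0.2 * times, 0.2 * 12)
  curve <- make_curve(times, lr)
  rec <- sliding_window_rate(curve, n = 9, min_time_days = 1.3)
  expect_lt(rec$mu, 0.05)  # flat-region slope, not the early 4.8 / day rise
  # errors are explicit
  short <- make_curve(times[1:5], lr[1:5])
  expect_error(sliding_window_rate(short, n = 9), "TOO_SHORT")
  expect_error(sliding_window_rate(curve, n = 9, min_time_days = 10),
               "NO_WINDOW")
  expect_error(sliding_window_rate(curve, n = 1), "n must be >= 2")
})

test_that("standard error around the maximum follows the k-window rule", {
  times <- seq(0, 168, by = 4)
  curve <- make_curve(times, 0.05 * times)
  rec <- sliding_window_rate(curve)
  rec <- se_around_max(curve, rec, k = 4)
  expect_equal(rec$se, 0, tolerance = 1e-12)  # noise-free: equal slopes
  # hand-computed oracle on four known slopes
  vals <- c(1.0, 1.2, 1.1, 0.9)
  rec2 <- rec
  rec2$all_slopes <- vals
  rec2$window_index <- 2L
  rec2 <- se_around_max(curve, rec2, k = 4)
  expect_equal(rec2$se, stats::sd(vals) / 2, tolerance = 1e-12)
  # k beyond the number of windows degrades gracefully with a warning
  expect_warning(se_around_max(curve, rec, k = 1000), "available")
})

test_that("extraction recovers model rates on a noise-free array", {
  env <- default_env()
  ts <- simulate_array(noise_free_config(n_replicates = 2, seed = 13))
  res <- extract_growth_rates(ts, env, background = 100)
  expect_identical(nrow(res$matrix), 2L * 64L)
  expect_identical(nrow(res$exclusions), 0L)
  pred <- growth_rate_multiplicative(res$matrix$par, res$matrix$nitrogen_uM,
                                     ref_params())
  expect_equal(res$matrix$mu_per_day, pred, tolerance = 1e-6)
  expect_true(all(res$matrix$se_per_day < 1e-12))
  expect_setequal(unique(res$matrix$replicate_id), c("rep1", "rep2"))
})

test_that("empty habitats are excluded with reason codes, not dropped silently", {
  cfg <- noise_free_config(n_replicates = 3, seed = 19, p_empty = 0.3)
  ts <- simulate_array(cfg)
  res <- extract_growth_rates(ts, default_env(), background = 100)
  n_empty <- sum(ts$n0_cells[ts$time_h == 0] == 0)
  expect_identical(nrow(res$matrix), 3L * 64L - n_empty)
  expect_identical(nrow(res$exclusions), n_empty)
  expect_true(all(res$exclusions$reason == "EMPTY"))
  # habitat index outside the grid errors
  bad <- ts; bad$row[1] <- 99L
  expect_error(extract_growth_rates(bad, default_env(), background = 100),
               "outside")
})

test_that("estimates are stable in window length and sampling interval", {
  env <- environment_grid(rep(30.8, 1), rep(41.4, 1))
  base <- simulation_config(
    env = env, params = ref_params(), n_replicates = 1,
    seeding = list(min_cells = 2, max_cells = 2, p_empty = 0),
    noise = list(intensity_cv = 0.02, background_level = 100,
                 background_sd = 0), seed = 23)
  ts <- simulate_array(base)
  curve <- to_growth_curve(ts, background = 100)
  mus <- vapply(5:25, function(n) sliding_window_rate(curve, n)$mu,
                numeric(1))
  # low-noise curves: the estimate varies by less than the noise scale
  expect_lt(max(mus) - min(mus), 0.1)
  # doubling the sampling interval leaves a clean slope unchanged
  t4 <- seq(0, 168, by = 4); t8 <- seq(0, 168, by = 8)
  mu4 <- sliding_window_rate(make_curve(t4, 0.03 * t4))$mu
  mu8 <- sliding_window_rate(make_curve(t8, 0.03 * t8))$mu
  expect_equal(mu4, mu8, tolerance = 1e-12)
})

test_that("rate matrices round-trip through CSV", {
  ts <- simulate_array(noise_free_config(n_replicates = 1, seed = 29))
  res <- extract_growth_rates(ts, default_env(), background = 100)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_rate_matrix_csv(res$matrix, tmp)
  back <- read_rate_matrix_csv(tmp)
  expect_equal(back$mu_per_day, res$matrix$mu_per_day, tolerance = 1e-12)
  expect_equal(back$nitrogen_uM, res$matrix$nitrogen_uM, tolerance = 1e-12)
  expect_error(read_rate_matrix_csv(
    {f <- withr::local_tempfile(fileext = ".csv")
     writeLines("a,b\n1,2", f); f}), "missing column")
})
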