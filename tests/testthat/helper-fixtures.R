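# Reference parameter set used throughout: the fitted colimitation
# parameters (mu_max fixed, cells nitrogen-starved so N0 = 0).
ref_params <- function() {
  monod_params(mu_max = 2.4, L0 = 50.8, K_L = 57.2, N0 = 0, K_N = 2.8)
}

default_env <- function() {
  environment_grid(row_nitrogen_profile(), col_light_profile())
}

# Noise-free simulation config over the default 8x8 array.
noise_free_config <- function(n_replicates = 3, seed = 7, p_empty = 0, ...) {
  simulation_config(
    env = default_env(), params = ref_params(),
    n_replicates = n_replicates,
    seeding = list(min_cells = 1, max_cells = 6, p_empty = p_empty),
    noise = list(intensity_cv = 0, background_level = 100,
                 background_sd = 0),
    seed = seed, ...)
}

# Independent brute-force window-rate oracle: enumerates every length-n
# window, fits lm(), applies the center-time threshold, ties -> earliest.
brute_force_rate <- function(times_h, log_ratio, n = 9, min_time_days = 1.3) {
  best <- NULL
  for (s in seq_len(length(times_h) - n + 1)) {
    idx <- s:(s + n - 1)
    center <- mean(times_h[idx])
    if (center < min_time_days * 24) next
    y <- log_ratio[idx]
    if (anyNA(y)) next
    slope <- unname(stats::coef(stats::lm(y ~ times_h[idx]))[2]) * 24
    if (is.null(best) || slope > best$mu)
      best <- list(mu = slope, center = center, index = s)
  }
  best
}

# A random growth curve on the standard imaging schedule (43 points, 4 h).
random_curve <- function() {
  times <- seq(0, 168, by = 4)
  lr <- cumsum(stats::rnorm(length(times), mean = 0.02, sd = 0.15))
  lr <- lr - lr[1]
  structure(list(habitat = c(row = 1L, col = 1L), replicate_id = "rep1",
                 times = times, log_ratio = lr, n_masked = 0L),
            class = "growth_curve")
}

make_curve <- function(times, log_ratio) {
  structure(list(habitat = c(row = 1L, col = 1L), replicate_id = "rep1",
                 times = times, log_ratio = log_ratio, n_masked = 0L),
            class = "growth_curve")
}
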