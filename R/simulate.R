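#' Configuration for a synthetic microhabitat-array growth experiment
#'
#' Describes everything needed to generate replicate fluorescence
#' time-series with the statistical structure of a gradient-array
#' experiment: the environment grid, the true growth model, seeding
#' statistics, the imaging schedule, and the fluorescence noise model.
#'
#' Defaults mirror the study design: an 8x8 array under a 5.3-27.8 uM
#' nitrogen gradient and 0.1-45 PAR light gradient, 3 replicates, imaging
#' every 4 h for 7 days, and 1-6 cells seeded per habitat with occasional
#' empty habitats.
#'
#' @param env [environment_grid()] of per-row nitrogen and per-column PAR.
#' @param params True [monod_params()] generating growth.
#' @param model_form Growth-law used by the generator:
#'   `"multiplicative_storage"` (default) or `"liebig_min"`.
#' @param duration_days Experiment length in days (default 7).
#' @param sample_interval_h Imaging interval in hours (default 4).
#' @param n_replicates Number of replicate experiments (default 3).
#' @param seeding List `min_cells`, `max_cells`, `p_empty`: initial counts
#'   are uniform integers on `[min_cells, max_cells]`, with a habitat left
#'   empty with probability `p_empty` (`0 <= p_empty < 1`).
#' @param carrying_capacity Optional cap (cells); when set, trajectories
#'   follow logistic rather than exponential growth. Default `NULL` (off).
#' @param noise List `intensity_cv` (coefficient of variation of the
#'   multiplicative intensity noise), `background_level` (additive
#'   fluorescence background, intensity units), `background_sd` (Gaussian
#'   sd of the background).
#' @param gain Fluorescence intensity units per cell (default 1000).
#' @param lag_h Optional lag phase (hours) during which growth rate is 0
#'   everywhere (default 0: no lag).
#' @param seed Integer RNG seed; identical configs give identical output.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(env = environment_grid(row_nitrogen_profile(),
                                                     col_light_profile()),
                              params = monod_params(mu_max = 2.4, L0 = 50.8,
                                                    K_L = 57.2, N0 = 0,
                                                    K_N = 2.8),
                              model_form = "multiplicative_storage",
                              duration_days = 7, sample_interval_h = 4,
                              n_replicates = 3,
                              seeding = list(min_cells = 1, max_cells = 6,
                                             p_empty = 0.05),
                              carrying_capacity = NULL,
                              noise = list(intensity_cv = 0.05,
                                           background_level = 100,
                                           background_sd = 5),
                              gain = 1000, lag_h = 0, seed = 1L) {
  cfg <- list(env = env, params = params, model_form = model_form,
              duration_days = duration_days,
              sample_interval_h = sample_interval_h,
              n_replicates = n_replicates, seeding = seeding,
              carrying_capacity = carrying_capacity, noise = noise,
              gain = gain, lag_h = lag_h, seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  stopifnot(inherits(cfg$env, "environment_grid"))
  validate_monod_params(cfg$params)
  if (!cfg$model_form %in% c("multiplicative_storage", "liebig_min"))
    stop("model_form must be multiplicative_storage or liebig_min")
  if (!isTRUE(cfg$duration_days > 0)) stop("duration_days must be > 0")
  if (!isTRUE(cfg$sample_interval_h > 0)) stop("sample_interval_h must be > 0")
  if (!isTRUE(cfg$n_replicates >= 1)) stop("n_replicates must be >= 1")
  s <- cfg$seeding
  if (is.null(s$min_cells) || is.null(s$max_cells) || is.null(s$p_empty))
    stop("seeding needs min_cells, max_cells, p_empty")
  if (s$min_cells < 1 || s$max_cells < s$min_cells)
    stop("seeding requires 1 <= min_cells <= max_cells")
  if (s$p_empty < 0 || s$p_empty >= 1)
    stop("p_empty must be in [0, 1)")
  if (!is.null(cfg$carrying_capacity) && cfg$carrying_capacity <= s$max_cells)
    stop("carrying_capacity must exceed max initial cell count")
  nz <- cfg$noise
  if (is.null(nz$intensity_cv) || nz$intensity_cv < 0)
    stop("noise$intensity_cv must be >= 0")
  if (is.null(nz$background_level) || nz$background_level < 0)
    stop("noise$background_level must be >= 0")
  if (is.null(nz$background_sd) || nz$background_sd < 0)
    stop("noise$background_sd must be >= 0")
  if (cfg$gain <= 0) stop("gain must be > 0")
  if (cfg$lag_h < 0) stop("lag_h must be >= 0")
  invisible(cfg)
}

#' Draw an initial cell count for one habitat
#'
#' Random seeding leaves a habitat empty with probability `p_empty`;
#' otherwise the count is uniform on the integers
#' `[min_cells, max_cells]`.
#'
#' @param seeding List `min_cells`, `max_cells`, `p_empty`.
#' @param n Number of draws.
#' @return Integer vector of length `n` (0 = empty).
#' @export
seed_counts <- function(seeding, n = 1L) {
  empty <- stats::runif(n) < seeding$p_empty
  counts <- sample(seq.int(seeding$min_cells, seeding$max_cells), n,
                   replace = TRUE)
  counts[empty] <- 0L
  as.integer(counts)
}

# Lognormal multiplier with mean 1 and coefficient of variation cv.
noise_multiplier <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

# Closed-form trajectory: exponential, or logistic when capped. Lag phase
# holds the population at n0 until lag_h.
cell_trajectory <- function(n0, mu_per_day, times_h, capacity = NULL,
                            lag_h = 0) {
  t_eff <- pmax(times_h - lag_h, 0) / 24
  if (is.null(capacity)) {
    n0 * exp(mu_per_day * t_eff)
  } else {
    capacity * n0 / (n0 + (capacity - n0) * exp(-mu_per_day * t_eff))
  }
}

#' Simulate replicate array-microhabitat growth experiments
#'
#' For each replicate and habitat: draws an initial cell count, grows it by
#' the exact exponential (or logistic, if a carrying capacity is set)
#' closed form at the habitat's model growth rate, and converts cells to
#' fluorescence intensity as `gain * cells * m + background`, where `m` is
#' a mean-1 lognormal multiplier with coefficient of variation
#' `intensity_cv` and the background is Gaussian around
#' `background_level`. Cell numbers are treated as continuous; the
#' environment is held at its steady-state values (the perfused device
#' maintains the gradient).
#'
#' @param cfg A [simulation_config()].
#' @return A data.frame of class `array_timeseries` with columns
#'   `replicate_id`, `row`, `col`, `time_h`, `intensity`, `n0_cells`, and
#'   attributes `seed` and `config`.
#' @examples
#' cfg <- simulation_config(n_replicates = 1, seed = 42)
#' ts <- simulate_array(cfg)
#' head(ts)
#' @export
simulate_array <- function(cfg) {
  validate_simulation_config(cfg)
  set.seed(cfg$seed)
  times_h <- seq(0, cfg$duration_days * 24, by = cfg$sample_interval_h)
  env <- cfg$env
  grid <- expand.grid(row = seq_len(env$n_rows), col = seq_len(env$n_cols))
  rate_fun <- if (cfg$model_form == "liebig_min") growth_rate_liebig else
    growth_rate_multiplicative
  mu <- rate_fun(env$col_par[grid$col], env$row_nitrogen[grid$row],
                 cfg$params)
  out <- vector("list", cfg$n_replicates * nrow(grid))
  k <- 0L
  for (rep_i in seq_len(cfg$n_replicates)) {
    rid <- sprintf("rep%d", rep_i)
    n0 <- seed_counts(cfg$seeding, nrow(grid))
    for (h in seq_len(nrow(grid))) {
      cells <- if (n0[h] == 0L) rep(0, length(times_h)) else
        cell_trajectory(n0[h], mu[h], times_h, cfg$carrying_capacity,
                        cfg$lag_h)
      m <- noise_multiplier(length(times_h), cfg$noise$intensity_cv)
      bg <- cfg$noise$background_level +
        if (cfg$noise$background_sd > 0)
          stats::rnorm(length(times_h), 0, cfg$noise$background_sd) else 0
      k <- k + 1L
      out[[k]] <- data.frame(replicate_id = rid, row = grid$row[h],
                             col = grid$col[h], time_h = times_h,
                             intensity = pmax(cfg$gain * cells * m + bg, 0),
                             n0_cells = n0[h])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "seed") <- cfg$seed
  attr(res, "config") <- cfg
  class(res) <- c("array_timeseries", "data.frame")
  res
}

#' Simulate per-habitat growth-rate matrices directly
#'
#' Generates replicate growth-rate matrices by evaluating the model on the
#' environment grid and adding independent Gaussian noise on the rate
#' scale — the quick route to fitting inputs when the intensity-level
#' detail of [simulate_array()] is not needed. Each record's standard
#' error is set to the injected noise sd.
#'
#' @param env [environment_grid()].
#' @param params True [monod_params()].
#' @param noise_sd Gaussian sd of the rate noise (day^-1); 0 gives
#'   noise-free matrices.
#' @param n_replicates Number of replicate matrices.
#' @param form `"multiplicative_storage"` or `"liebig_min"`.
#' @param seed Integer RNG seed.
#' @return A `growth_rate_matrix` data.frame (see
#'   [extract_growth_rates()] for the schema).
#' @export
simulate_rate_matrix <- function(env, params, noise_sd = 0,
                                 n_replicates = 3,
                                 form = "multiplicative_storage",
                                 seed = 1L) {
  stopifnot(inherits(env, "environment_grid"), noise_sd >= 0)
  set.seed(as.integer(seed))
  rate_fun <- if (form == "liebig_min") growth_rate_liebig else
    growth_rate_multiplicative
  grid <- expand.grid(row = seq_len(env$n_rows), col = seq_len(env$n_cols))
  mu0 <- rate_fun(env$col_par[grid$col], env$row_nitrogen[grid$row], params)
  out <- lapply(seq_len(n_replicates), function(rep_i) {
    data.frame(replicate_id = sprintf("rep%d", rep_i),
               row = grid$row, col = grid$col,
               nitrogen_uM = env$row_nitrogen[grid$row],
               par = env$col_par[grid$col],
               mu_per_day = mu0 + stats::rnorm(length(mu0), 0, noise_sd),
               se_per_day = noise_sd,
               window_center_h = NA_real_)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("growth_rate_matrix", "data.frame")
  res
}

ts_columns <- c("replicate_id", "row", "col", "time_h", "intensity",
                "n0_cells")

#' Write / read array time-series CSV
#'
#' CSV with exact column order `replicate_id, row, col, time_h, intensity,
#' n0_cells`, preceded by `#`-prefixed header comment lines recording the
#' RNG seed. Round trips are lossless (values written at full precision).
#'
#' @param series An `array_timeseries` data.frame from [simulate_array()].
#' @param path File path.
#' @return `read_timeseries_csv` returns the `array_timeseries`
#'   data.frame.
#' @export
write_timeseries_csv <- function(series, path) {
  if (!all(ts_columns %in% names(series)))
    stop("time series must have columns: ", paste(ts_columns, collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  seed <- attr(series, "seed")
  writeLines(sprintf("# colimfit array time series; seed=%s",
                     if (is.null(seed)) "NA" else seed), con)
  df <- as.data.frame(series)[, ts_columns]
  df$time_h <- format(df$time_h, digits = 17, trim = TRUE, scientific = FALSE)
  df$intensity <- format(df$intensity, digits = 17, trim = TRUE)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timeseries_csv
#' @export
read_timeseries_csv <- function(path) {
  first <- readLines(path, n = 20)
  n_comment <- sum(cumprod(startsWith(first, "#")))
  seed <- NA_integer_
  if (n_comment > 0) {
    m <- regmatches(first[1], regexpr("seed=[-0-9]+", first[1]))
    if (length(m)) seed <- as.integer(sub("seed=", "", m))
  }
  df <- utils::read.csv(path, skip = n_comment, stringsAsFactors = FALSE)
  missing <- setdiff(ts_columns, names(df))
  if (length(missing))
    stop("time-series CSV missing column(s): ", paste(missing, collapse = ", "))
  df <- df[, ts_columns]
  df$time_h <- as.numeric(df$time_h)
  df$intensity <- as.numeric(df$intensity)
  bad <- which(!stats::complete.cases(df))
  if (length(bad))
    stop("time-series CSV has incomplete data at row ", bad[1])
  # canonical ordering: keys are (replicate, habitat, time)
  df <- df[order(df$replicate_id, df$row, df$col, df$time_h), ]
  rownames(df) <- NULL
  key <- interaction(df$replicate_id, df$row, df$col, drop = TRUE)
  for (g in split(seq_len(nrow(df)), key)) {
    tt <- df$time_h[g]
    if (length(tt) > 1) {
      dt <- diff(tt)
      if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-9 * max(dt[1], 1))
        stop("non-uniform or non-increasing time grid for series starting at row ",
             g[1])
    }
  }
  attr(df, "seed") <- seed
  class(df) <- c("array_timeseries", "data.frame")
  df
}
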