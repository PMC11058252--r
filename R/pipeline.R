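# Polynomial rolling hash of a string: a stable 8-hex-digit config
# fingerprint for provenance lines (not cryptographic).
fnv1a_hex <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

# Per-stage seeds derived from one master seed, so stages can be rerun
# independently yet reproducibly. Offsets keep derived seeds < 2^31.
stage_seed <- function(master, stage) {
  offs <- c(simulate = 101, extract = 211, fit = 307, compare = 401,
            predict = 503)
  as.integer((as.numeric(master) * 1009 + offs[[stage]]) %% 2147483587)
}

provenance_lines <- function(stage, seed, cfg_hash) {
  c(sprintf("# stage=%s seed=%s config_hash=%s colimfit_version=%s",
            stage, seed, cfg_hash,
            as.character(utils::packageVersion("colimfit"))))
}

#' Load a pipeline / simulation configuration file
#'
#' Reads a JSON or YAML configuration and builds a validated
#' [simulation_config()] plus extraction and fitting settings. Every
#' stage's settings are validated before any stage runs. Unknown keys are
#' rejected by name.
#'
#' Top-level keys (all optional, defaults as in the stage functions):
#' `simulation` (any [simulation_config()] argument except `env` and
#' `params`, which are given as `environment` =
#' `{c_source, c_sink, par_min, par_max, n_rows, n_cols}` and
#' `true_params` = `{mu_max, L0, K_L, N0, K_N}`), `extraction` =
#' `{n, min_time_days, k, background}`, `fitting` =
#' `{form, acetate, B}`, and `seed`.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A `pipeline_config` list with `sim_cfg`, `extraction`,
#'   `fitting`, `seed`, `hash`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- c("simulation", "environment", "true_params", "extraction",
             "fitting", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  seed <- if (is.null(raw$seed)) 1L else as.integer(raw$seed)
  e <- raw$environment
  env <- environment_grid(
    row_nitrogen_profile(
      c_source = e$c_source %||% 35.3, c_sink = e$c_sink %||% 5.3,
      n_rows = e$n_rows %||% 8,
      geometry = default_geometry(
        row_centerlines = seq(0, 0.75 * 2308,
                              length.out = e$n_rows %||% 8))),
    col_light_profile(par_min = e$par_min %||% 0.1,
                      par_max = e$par_max %||% 45,
                      n_cols = e$n_cols %||% 8))
  tp <- raw$true_params
  params <- monod_params(mu_max = tp$mu_max %||% 2.4, L0 = tp$L0 %||% 50.8,
                         K_L = tp$K_L %||% 57.2, N0 = tp$N0 %||% 0,
                         K_N = tp$K_N %||% 2.8)
  sim_args <- raw$simulation %||% list()
  bad <- setdiff(names(sim_args),
                 setdiff(names(formals(simulation_config)),
                         c("env", "params", "seed")))
  if (length(bad))
    stop("unknown simulation key(s): ", paste(bad, collapse = ", "))
  sim_cfg <- do.call(simulation_config,
                     c(list(env = env, params = params,
                            seed = stage_seed(seed, "simulate")), sim_args))
  ex <- raw$extraction %||% list()
  extraction <- list(n = ex$n %||% 9, min_time_days = ex$min_time_days %||% 1.3,
                     k = ex$k %||% 4, background = ex$background)
  ft <- raw$fitting %||% list()
  fitting <- list(form = ft$form %||% "multiplicative_storage",
                  acetate = ft$acetate %||% TRUE, B = ft$B %||% 1000)
  cfg_txt <- jsonlite::toJSON(raw, auto_unbox = TRUE, digits = NA)
  structure(list(sim_cfg = sim_cfg, extraction = extraction,
                 fitting = fitting, seed = seed, hash = fnv1a_hex(cfg_txt)),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pipeline stage: simulate
#'
#' Generates the synthetic replicate experiments and writes the time
#' series and environment CSVs (with provenance headers) to `out_dir`.
#'
#' @param cfg A [simulation_config()].
#' @param out_dir Output directory (created if absent).
#' @param cfg_hash Optional configuration fingerprint for provenance.
#' @return Invisibly, paths `timeseries` and `environment`.
#' @export
run_simulation <- function(cfg, out_dir, cfg_hash = "none") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ts <- simulate_array(cfg)
  ts_path <- file.path(out_dir, "timeseries.csv")
  write_timeseries_csv(ts, ts_path)
  env_path <- file.path(out_dir, "environment.csv")
  write_environment_csv(cfg$env, env_path)
  prov <- file.path(out_dir, "provenance_simulate.txt")
  writeLines(provenance_lines("simulate", cfg$seed, cfg_hash), prov)
  message(sprintf("simulated %d replicates x %d habitats x %d time points",
                  cfg$n_replicates, cfg$env$n_rows * cfg$env$n_cols,
                  length(seq(0, cfg$duration_days * 24,
                             by = cfg$sample_interval_h))))
  invisible(list(timeseries = ts_path, environment = env_path))
}

#' Pipeline stage: extract
#'
#' Reads the time-series and environment CSVs, extracts the growth-rate
#' matrix, and writes it plus the exclusion log.
#'
#' @param ts_path,env_path Input CSV paths.
#' @param out_dir Output directory.
#' @param n,min_time_days,k,background Extraction settings, see
#'   [extract_growth_rates()].
#' @param cfg_hash Optional configuration fingerprint.
#' @return Invisibly, paths `matrix` and `exclusions`.
#' @export
run_extraction <- function(ts_path, env_path, out_dir, n = 9,
                           min_time_days = 1.3, k = 4, background = NULL,
                           cfg_hash = "none") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ts <- read_timeseries_csv(ts_path)
  env <- read_environment_csv(env_path)
  res <- extract_growth_rates(ts, env, background = background, n = n,
                              min_time_days = min_time_days, k = k)
  mat_path <- file.path(out_dir, "rate_matrix.csv")
  write_rate_matrix_csv(res$matrix, mat_path)
  excl_path <- file.path(out_dir, "exclusions.txt")
  excl_lines <- provenance_lines("extract", attr(ts, "seed"), cfg_hash)
  if (nrow(res$exclusions) > 0)
    excl_lines <- c(excl_lines,
                    apply(res$exclusions, 1, paste, collapse = "\t"))
  writeLines(excl_lines, excl_path)
  message(sprintf("extracted %d growth rates; %d habitat(s) excluded",
                  nrow(res$matrix), nrow(res$exclusions)))
  invisible(list(matrix = mat_path, exclusions = excl_path))
}

#' Pipeline stage: fit
#'
#' Reads one or more growth-rate matrix CSVs and runs the weighted
#' bootstrap fit, writing the JSON fit report (and optionally the raw
#' bootstrap samples).
#'
#' @param matrix_paths Character vector of rate-matrix CSV paths.
#' @param out_dir Output directory.
#' @param form Model form (see [model_spec()]).
#' @param acetate Acetate present? Fixes `L0 = 0` when `FALSE`.
#' @param B Bootstrap runs (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param dump_samples Write `bootstrap_samples.csv` (param columns, B
#'   rows)?
#' @param cfg_hash Optional configuration fingerprint.
#' @return Invisibly, the `colim_boot` object (report path in attribute
#'   `report`).
#' @export
run_fitting <- function(matrix_paths, out_dir,
                        form = "multiplicative_storage", acetate = TRUE,
                        B = 1000, seed = 1L, dump_samples = FALSE,
                        cfg_hash = "none") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mats <- lapply(matrix_paths, read_rate_matrix_csv)
  spec <- model_spec(form, acetate = acetate)
  boot <- bootstrap_fit(mats, spec, B = B, seed = seed)
  report <- file.path(out_dir, "fit_report.json")
  fit_report_json(boot, report)
  writeLines(provenance_lines("fit", seed, cfg_hash),
             file.path(out_dir, "provenance_fit.txt"))
  if (dump_samples)
    utils::write.csv(as.data.frame(boot$samples),
                     file.path(out_dir, "bootstrap_samples.csv"),
                     row.names = FALSE)
  message(sprintf("fitted %s to %d records over B = %d bootstrap runs",
                  form, boot$point_fit$n_obs, B))
  attr(boot, "report") <- report
  invisible(boot)
}

#' Pipeline stage: predict
#'
#' Reads a fit report JSON and writes the growth-rate lookup map over the
#' requested grid.
#'
#' @param report_path Path to a [fit_report_json()] file.
#' @param out_dir Output directory.
#' @param L_grid,N_grid Ascending grids (defaults 0-150 PAR, 0-100 uM).
#' @param cfg_hash Optional configuration fingerprint.
#' @return Invisibly, the map matrix (path in attribute `path`).
#' @export
run_prediction <- function(report_path, out_dir,
                           L_grid = seq(0, 150, by = 1),
                           N_grid = seq(0, 100, by = 1),
                           cfg_hash = "none") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rep <- jsonlite::fromJSON(report_path)
  if (is.null(rep$estimates)) stop("malformed fit report: no estimates")
  full <- c(unlist(rep$fixed), unlist(rep$estimates))
  if (rep$model_form == "multiplicative_basic")
    full <- c(mu_max = unname(full[["mu_0"]]), L0 = 0,
              K_L = unname(full[["K_L"]]), N0 = 0,
              K_N = unname(full[["K_N"]]))
  params <- monod_params(mu_max = full[["mu_max"]], L0 = full[["L0"]],
                         K_L = full[["K_L"]], N0 = full[["N0"]],
                         K_N = full[["K_N"]])
  map <- predict_map(params, L_grid, N_grid)
  path <- file.path(out_dir, "prediction_map.csv")
  write_map_csv(map, path)
  writeLines(provenance_lines("predict", NA, cfg_hash),
             file.path(out_dir, "provenance_predict.txt"))
  attr(map, "path") <- path
  invisible(map)
}

#' Run the full pipeline under one master seed
#'
#' simulate -> extract -> fit -> predict, with per-stage seeds derived
#' deterministically from the master seed so repeated runs are
#' byte-identical and individual stages can be rerun in isolation.
#'
#' @param pcfg A [read_pipeline_config()] result, or `NULL` for defaults.
#' @param out_dir Output directory.
#' @param seed Master seed (overrides the config's).
#' @param B Bootstrap runs (overrides the config's).
#' @return Invisibly, a list with the `colim_boot` fit and all artifact
#'   paths.
#' @export
run_pipeline <- function(pcfg = NULL, out_dir, seed = NULL, B = NULL) {
  if (is.null(pcfg)) {
    master <- seed %||% 1L
    sim_cfg <- simulation_config(seed = stage_seed(master, "simulate"))
    extraction <- list(n = 9, min_time_days = 1.3, k = 4, background = NULL)
    fitting <- list(form = "multiplicative_storage", acetate = TRUE,
                    B = B %||% 1000)
    hash <- "default"
  } else {
    master <- seed %||% pcfg$seed
    sim_cfg <- pcfg$sim_cfg
    sim_cfg$seed <- stage_seed(master, "simulate")
    extraction <- pcfg$extraction
    fitting <- pcfg$fitting
    if (!is.null(B)) fitting$B <- B
    hash <- pcfg$hash
  }
  sim <- run_simulation(sim_cfg, out_dir, cfg_hash = hash)
  ex <- run_extraction(sim$timeseries, sim$environment, out_dir,
                       n = extraction$n,
                       min_time_days = extraction$min_time_days,
                       k = extraction$k, background = extraction$background,
                       cfg_hash = hash)
  boot <- run_fitting(ex$matrix, out_dir, form = fitting$form,
                      acetate = fitting$acetate, B = fitting$B,
                      seed = stage_seed(master, "fit"), cfg_hash = hash)
  map <- run_prediction(attr(boot, "report"), out_dir, cfg_hash = hash)
  invisible(list(boot = boot, map = map, paths = c(sim, ex,
                 list(report = attr(boot, "report"),
                      map = attr(map, "path")))))
}
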