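#' Convert one habitat's intensity series to a log-growth curve
#'
#' Background-subtracted fluorescence is proportional to cell number, so
#' growth is measured as `ln((I_t - background) / (I_0 - background))`.
#' Habitats seeded empty (`n0_cells = 0`) or whose initial
#' background-subtracted intensity is non-positive carry no growth signal
#' and are excluded (return value `NULL`, with the reason attached as an
#' attribute). Later time points whose subtracted intensity is
#' non-positive are masked (`NA`) and flagged rather than dropped.
#'
#' @param series Data.frame for a single habitat and replicate with
#'   columns `time_h`, `intensity`, `n0_cells` (plus `replicate_id`,
#'   `row`, `col`).
#' @param background Scalar background intensity to subtract.
#' @return A `growth_curve` list (`habitat`, `replicate_id`, `times` in
#'   hours, `log_ratio`, `n_masked`), or a `growth_exclusion` object whose
#'   `reason` is one of `EMPTY`, `NONPOSITIVE_I0`.
#' @export
to_growth_curve <- function(series, background) {
  if (nrow(series) == 0) stop("empty series")
  series <- series[order(series$time_h), ]
  habitat <- c(row = series$row[1], col = series$col[1])
  rid <- series$replicate_id[1]
  if (series$n0_cells[1] == 0)
    return(structure(list(reason = "EMPTY"), class = "growth_exclusion"))
  sig <- series$intensity - background
  if (sig[1] <= 0)
    return(structure(list(reason = "NONPOSITIVE_I0"),
                     class = "growth_exclusion"))
  lr <- suppressWarnings(log(sig / sig[1]))
  masked <- !is.finite(lr)
  lr[masked] <- NA_real_
  structure(list(habitat = habitat, replicate_id = rid,
                 times = series$time_h, log_ratio = lr,
                 n_masked = sum(masked)),
            class = "growth_curve")
}

# OLS slope of y on x (per hour); vectorized over windows elsewhere.
ols_slope <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sum((x - mx)^2)
}

# Slopes (day^-1) and center times (h) of every length-n contiguous window.
# Windows containing masked points yield NA slopes.
window_slopes <- function(times, log_ratio, n) {
  n_win <- length(times) - n + 1L
  slopes <- numeric(n_win)
  centers <- numeric(n_win)
  for (w in seq_len(n_win)) {
    idx <- w:(w + n - 1L)
    y <- log_ratio[idx]
    centers[w] <- mean(times[idx])
    slopes[w] <- if (anyNA(y)) NA_real_ else ols_slope(times[idx], y) * 24
  }
  list(slopes = slopes, centers = centers)
}

#' Maximum specific growth rate by the sliding-window rule
#'
#' Fits every contiguous window of `n` points of `ln(N/N0)` versus time to
#' a straight line and returns the maximum slope (converted to day^-1)
#' among windows whose center time is at least `min_time_days`. The window
#' length `n = 9` suppresses point-to-point noise while leaving the
#' maximum essentially unchanged for n up to ~25; the 1.3-day threshold
#' skips the settling period after seeding. Ties return the earliest
#' window.
#'
#' @param curve A [to_growth_curve()] result.
#' @param n Window length in points (default 9, must be >= 2).
#' @param min_time_days Earliest admissible window-center time, in days
#'   (default 1.3).
#' @return A `growth_rate_record` list: `habitat`, `replicate_id`, `mu`
#'   (day^-1), `se` (`NA` until [se_around_max()] is applied),
#'   `window_center_time` (hours), `n_window`, and the index
#'   `window_index` of the maximizing window.
#' @export
sliding_window_rate <- function(curve, n = 9, min_time_days = 1.3) {
  stopifnot(inherits(curve, "growth_curve"))
  if (n < 2) stop("window length n must be >= 2")
  if (length(curve$times) < n)
    stop("TOO_SHORT: curve has ", length(curve$times),
         " points; window needs ", n)
  ws <- window_slopes(curve$times, curve$log_ratio, n)
  ok <- ws$centers >= min_time_days * 24 & !is.na(ws$slopes)
  if (!any(ok))
    stop("NO_WINDOW: no complete window with center time >= ",
         min_time_days, " days")
  cand <- which(ok)
  best <- cand[which.max(ws$slopes[cand])]  # which.max takes first on ties
  structure(list(habitat = curve$habitat, replicate_id = curve$replicate_id,
                 mu = ws$slopes[best], se = NA_real_,
                 window_center_time = ws$centers[best], n_window = n,
                 window_index = best, all_slopes = ws$slopes,
                 all_centers = ws$centers),
            class = "growth_rate_record")
}

#' Standard error around the maximum window slope
#'
#' Takes the `k` sliding-window slope values nearest the maximizing window
#' (the maximizer plus its closest neighbors: positions max-1 .. max+k-2
#' for the default k = 4, clamped at the ends of the window sequence) and
#' returns their standard error `sd / sqrt(k)`. These are the "points
#' around each maximum growth rate" whose reciprocal squared standard
#' error weights replicate selection in [bootstrap_fit()].
#'
#' @param curve The [to_growth_curve()] curve the record came from.
#' @param record The [sliding_window_rate()] record.
#' @param k Number of neighboring window slopes to use (default 4).
#' @return The record with `se` (day^-1) filled in.
#' @export
se_around_max <- function(curve, record, k = 4) {
  stopifnot(inherits(record, "growth_rate_record"))
  slopes <- record$all_slopes
  n_win <- length(slopes)
  if (n_win < k) {
    warning("only ", n_win, " windows available; using all for the SE")
    idx <- seq_len(n_win)
  } else {
    start <- record$window_index - floor((k - 1) / 2)
    start <- min(max(start, 1L), n_win - k + 1L)
    idx <- start:(start + k - 1L)
  }
  vals <- slopes[idx]
  vals <- vals[!is.na(vals)]
  record$se <- if (length(vals) >= 2) stats::sd(vals) / sqrt(length(vals)) else 0
  record
}

#' Extract a growth-rate matrix from array time series
#'
#' Runs [to_growth_curve()], [sliding_window_rate()] and [se_around_max()]
#' over every (replicate, habitat) series and joins the per-habitat
#' maximum growth rates to the environment grid, giving the matrix of
#' observations that the colimitation model is fitted to. Habitats that
#' cannot yield a rate are logged with a reason code rather than silently
#' dropped.
#'
#' @param ts An `array_timeseries` data.frame ([simulate_array()] or
#'   [read_timeseries_csv()]).
#' @param env The matching [environment_grid()].
#' @param background Scalar background intensity; if `NULL`, estimated by
#'   [estimate_background()].
#' @param n Sliding-window length (default 9 points).
#' @param min_time_days Window-center threshold (default 1.3 days).
#' @param k Window slopes used for the standard error (default 4).
#' @return A list with `matrix` (a `growth_rate_matrix` data.frame with
#'   columns `replicate_id, row, col, nitrogen_uM, par, mu_per_day,
#'   se_per_day, window_center_h`) and `exclusions` (data.frame
#'   `replicate_id, row, col, reason` with reason codes
#'   `EMPTY, NONPOSITIVE_I0, TOO_SHORT, NO_WINDOW`).
#' @export
extract_growth_rates <- function(ts, env, background = NULL, n = 9,
                                 min_time_days = 1.3, k = 4) {
  stopifnot(inherits(env, "environment_grid"))
  if (any(ts$row > env$n_rows) || any(ts$col > env$n_cols) ||
      any(ts$row < 1) || any(ts$col < 1))
    stop("habitat index outside the environment grid")
  if (is.null(background)) background <- estimate_background(ts)
  recs <- list(); excl <- list()
  key <- interaction(ts$replicate_id, ts$row, ts$col, drop = TRUE)
  for (g in split(seq_len(nrow(ts)), key)) {
    series <- ts[g, ]
    curve <- to_growth_curve(series, background)
    if (inherits(curve, "growth_exclusion")) {
      excl[[length(excl) + 1L]] <- data.frame(
        replicate_id = series$replicate_id[1], row = series$row[1],
        col = series$col[1], reason = curve$reason)
      next
    }
    rec <- tryCatch(
      se_around_max(curve, sliding_window_rate(curve, n, min_time_days), k),
      error = function(e) e)
    if (inherits(rec, "error")) {
      reason <- if (grepl("^TOO_SHORT", conditionMessage(rec))) "TOO_SHORT"
                else "NO_WINDOW"
      excl[[length(excl) + 1L]] <- data.frame(
        replicate_id = series$replicate_id[1], row = series$row[1],
        col = series$col[1], reason = reason)
      next
    }
    recs[[length(recs) + 1L]] <- data.frame(
      replicate_id = rec$replicate_id, row = rec$habitat[["row"]],
      col = rec$habitat[["col"]],
      nitrogen_uM = env$row_nitrogen[rec$habitat[["row"]]],
      par = env$col_par[rec$habitat[["col"]]],
      mu_per_day = rec$mu, se_per_day = rec$se,
      window_center_h = rec$window_center_time)
  }
  mat <- if (length(recs)) do.call(rbind, recs) else
    data.frame(replicate_id = character(), row = integer(), col = integer(),
               nitrogen_uM = numeric(), par = numeric(),
               mu_per_day = numeric(), se_per_day = numeric(),
               window_center_h = numeric())
  rownames(mat) <- NULL
  class(mat) <- c("growth_rate_matrix", "data.frame")
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(replicate_id = character(), row = integer(), col = integer(),
               reason = character())
  rownames(exclusions) <- NULL
  list(matrix = mat, exclusions = exclusions)
}

#' Estimate the fluorescence background from empty habitats
#'
#' Uses habitats seeded with zero cells, whose entire intensity trace is
#' background, taking the mean of their intensities. Errors if the data
#' contain no empty habitats — supply the background explicitly in that
#' case.
#'
#' @param ts An `array_timeseries` data.frame.
#' @return Scalar background intensity.
#' @export
estimate_background <- function(ts) {
  blank <- ts$intensity[ts$n0_cells == 0]
  if (!length(blank))
    stop("no empty habitats to estimate the background from; ",
         "supply `background` explicitly")
  mean(blank)
}

#' Write / read a growth-rate matrix CSV
#'
#' Exact columns: `replicate_id, row, col, nitrogen_uM, par, mu_per_day,
#' se_per_day, window_center_h`.
#'
#' @param mat A `growth_rate_matrix` data.frame.
#' @param path File path.
#' @return `read_rate_matrix_csv` returns the `growth_rate_matrix`.
#' @export
write_rate_matrix_csv <- function(mat, path) {
  cols <- c("replicate_id", "row", "col", "nitrogen_uM", "par",
            "mu_per_day", "se_per_day", "window_center_h")
  if (!all(cols %in% names(mat)))
    stop("growth-rate matrix must have columns: ", paste(cols, collapse = ", "))
  df <- as.data.frame(mat)[, cols]
  for (cc in c("nitrogen_uM", "par", "mu_per_day", "se_per_day",
               "window_center_h"))
    df[[cc]] <- format(df[[cc]], digits = 17, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rate_matrix_csv
#' @export
read_rate_matrix_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("replicate_id", "row", "col", "nitrogen_uM", "par",
            "mu_per_day", "se_per_day", "window_center_h")
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("rate-matrix CSV missing column(s): ", paste(missing, collapse = ", "))
  df <- df[, cols]
  class(df) <- c("growth_rate_matrix", "data.frame")
  df
}
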