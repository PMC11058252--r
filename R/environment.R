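#' Environment grid for an R x C microhabitat array
#'
#' Holds the per-row nitrogen concentrations and per-column light
#' intensities that define the 64 (by default) distinct resource
#' combinations of the array. Row 1 is the source-adjacent (high-nitrogen)
#' side; nitrogen is non-increasing with row index. Column light values are
#' non-decreasing with column index.
#'
#' @param row_nitrogen Numeric vector of nitrogen concentrations (uM), one
#'   per row, non-increasing.
#' @param col_par Numeric vector of light intensities (PAR,
#'   umol m^-2 s^-1), one per column, monotone.
#' @return An `environment_grid` list with `n_rows`, `n_cols`,
#'   `row_nitrogen`, `col_par`.
#' @examples
#' env <- environment_grid(row_nitrogen_profile(), col_light_profile())
#' env$row_nitrogen
#' @export
environment_grid <- function(row_nitrogen, col_par) {
  row_nitrogen <- as.numeric(row_nitrogen)
  col_par <- as.numeric(col_par)
  if (anyNA(row_nitrogen) || any(row_nitrogen < 0))
    stop("row_nitrogen must be non-negative")
  if (anyNA(col_par) || any(col_par < 0))
    stop("col_par must be non-negative")
  if (is.unsorted(rev(row_nitrogen), strictly = FALSE) &&
      is.unsorted(row_nitrogen, strictly = FALSE))
    stop("row_nitrogen must be monotone across rows")
  if (is.unsorted(col_par) && is.unsorted(rev(col_par)))
    stop("col_par must be monotone across columns")
  structure(list(n_rows = length(row_nitrogen), n_cols = length(col_par),
                 row_nitrogen = row_nitrogen, col_par = col_par),
            class = "environment_grid")
}

#' @export
print.environment_grid <- function(x, ...) {
  cat(sprintf("environment_grid: %d rows x %d cols\n", x$n_rows, x$n_cols))
  cat("  row nitrogen (uM): ", paste(signif(x$row_nitrogen, 4), collapse = ", "), "\n")
  cat("  col PAR:           ", paste(signif(x$col_par, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Default array geometry for the nitrogen gradient
#'
#' The source and sink perfusion channels are separated by a hydrogel gap
#' across which a steady linear diffusive gradient forms; each row of
#' habitats reads the concentration at its horizontal centerline. The
#' default gap of 2308 um with 8 centerlines spanning the sink-adjacent
#' position up to 75% of the gap reproduces a 5.3-27.8 uM row range from
#' 5.3/35.3 uM channel conditions and a slope of 1.3 uM per 100 um.
#'
#' @param channel_gap Gap between sink and source channel walls (um).
#' @param row_centerlines Row centerline positions (um) measured from the
#'   sink channel wall, ordered sink-side first.
#' @return A list with `channel_gap` and `row_centerlines`.
#' @export
default_geometry <- function(channel_gap = 2308,
                             row_centerlines = seq(0, 0.75 * channel_gap,
                                                   length.out = 8)) {
  list(channel_gap = channel_gap, row_centerlines = row_centerlines)
}

#' Per-row nitrogen concentrations from channel boundary conditions
#'
#' Linearly interpolates the steady diffusive gradient between the sink and
#' source channel concentrations at each row centerline. Rows are returned
#' source-side first (non-increasing concentrations), matching the
#' row-index convention of [environment_grid()].
#'
#' @param c_source Source-channel nitrogen concentration (uM), default
#'   35.3.
#' @param c_sink Sink-channel nitrogen concentration (uM), default 5.3.
#'   Must satisfy `c_source >= c_sink >= 0`.
#' @param n_rows Number of habitat rows (default 8). Must match the length
#'   of `geometry$row_centerlines`.
#' @param geometry List from [default_geometry()]: channel gap (um) and row
#'   centerline positions (um from the sink wall), strictly inside
#'   `[0, channel_gap]`.
#' @return Numeric vector of length `n_rows`: nitrogen (uM), source side
#'   (row 1) first.
#' @export
row_nitrogen_profile <- function(c_source = 35.3, c_sink = 5.3, n_rows = 8,
                                 geometry = default_geometry()) {
  if (is.na(c_source) || is.na(c_sink) || c_sink < 0 || c_source < c_sink)
    stop("need c_source >= c_sink >= 0")
  x <- geometry$row_centerlines
  gap <- geometry$channel_gap
  if (length(x) != n_rows)
    stop("geometry supplies ", length(x), " centerlines for n_rows = ", n_rows)
  if (any(x < 0) || any(x > gap))
    stop("row centerlines must lie within [0, channel_gap]")
  conc <- c_sink + (c_source - c_sink) * x / gap
  rev(sort(conc))  # source side (highest concentration) first
}

#' Per-column light intensities of a linear gradient
#'
#' Column values of an (approximately) linear light field across the array:
#' `n_cols` equally spaced PAR values from `par_min` to `par_max`,
#' ascending with column index.
#'
#' @param par_min,par_max Minimum and maximum PAR (umol m^-2 s^-1); defaults
#'   0.1 and 45. Require `0 <= par_min <= par_max`.
#' @param n_cols Number of habitat columns (default 8).
#' @return Numeric vector of length `n_cols`.
#' @export
col_light_profile <- function(par_min = 0.1, par_max = 45, n_cols = 8) {
  if (is.na(par_min) || is.na(par_max) || par_min < 0 || par_max < par_min)
    stop("need 0 <= par_min <= par_max")
  if (n_cols < 1) stop("n_cols must be >= 1")
  if (n_cols == 1) return((par_min + par_max) / 2)
  seq(par_min, par_max, length.out = n_cols)
}

#' Two-point linear calibration
#'
#' Maps a raw instrument signal (fluorescence grayscale, CCD grayscale) to
#' a physical value (uM, PAR) through the unique line defined by two anchor
#' points, as used to convert dye fluorescence to nitrogen concentration
#' and brightfield grayscale to PAR.
#'
#' @param x0,y0 First anchor: raw signal and its physical value.
#' @param x1,y1 Second anchor. `x0 != x1`.
#' @return A `linear_calibration` list.
#' @export
linear_calibration <- function(x0, y0, x1, y1) {
  if (any(is.na(c(x0, y0, x1, y1)))) stop("calibration anchors must be finite")
  if (x0 == x1) stop("calibration anchors must have distinct raw values")
  structure(list(x0 = x0, y0 = y0, x1 = x1, y1 = y1),
            class = "linear_calibration")
}

#' @rdname linear_calibration
#' @param raw Raw signal value(s) to convert.
#' @param cal A `linear_calibration`.
#' @export
apply_calibration <- function(raw, cal) {
  stopifnot(inherits(cal, "linear_calibration"))
  cal$y0 + (raw - cal$x0) * (cal$y1 - cal$y0) / (cal$x1 - cal$x0)
}

#' @rdname linear_calibration
#' @export
invert_calibration <- function(cal) {
  stopifnot(inherits(cal, "linear_calibration"))
  linear_calibration(cal$y0, cal$x0, cal$y1, cal$x1)
}

#' Read / write an environment grid as CSV
#'
#' Long CSV with columns `axis` (`row` or `col`), `index`, `value`,
#' `units`.
#'
#' @param env An [environment_grid()].
#' @param path File path.
#' @return `read_environment_csv` returns an [environment_grid()].
#' @export
write_environment_csv <- function(env, path) {
  stopifnot(inherits(env, "environment_grid"))
  df <- rbind(
    data.frame(axis = "row", index = seq_len(env$n_rows),
               value = env$row_nitrogen, units = "uM"),
    data.frame(axis = "col", index = seq_len(env$n_cols),
               value = env$col_par, units = "umol.m-2.s-1"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_environment_csv
#' @export
read_environment_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("axis", "index", "value", "units")
  if (!all(need %in% names(df)))
    stop("environment CSV must have columns: ", paste(need, collapse = ", "))
  rows <- df[df$axis == "row", ]
  cols <- df[df$axis == "col", ]
  environment_grid(rows$value[order(rows$index)], cols$value[order(cols$index)])
}
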