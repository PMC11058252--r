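as_rate_matrix <- function(x) {
  if (inherits(x, "growth_rate_matrix")) return(x)
  if (is.data.frame(x)) return(x)
  if (is.list(x)) {
    out <- do.call(rbind, lapply(x, as.data.frame))
    rownames(out) <- NULL
    class(out) <- c("growth_rate_matrix", "data.frame")
    return(out)
  }
  stop("expected a growth_rate_matrix or list of them")
}

default_init <- function(spec, mat) {
  mu_obs <- mat$mu_per_day
  init <- c(mu_max = max(mu_obs, 0.1), mu_0 = max(mu_obs, 0.1),
            L0 = 0.1 * max(mat$par), K_L = stats::median(mat$par),
            N0 = 0.1 * max(mat$nitrogen_uM),
            K_N = stats::median(mat$nitrogen_uM))
  pmax(init[spec$free_params], 1e-3)
}

default_bounds <- function(spec) {
  lower <- c(mu_max = 1e-6, mu_0 = 1e-6, L0 = 0, K_L = 1e-6, N0 = 0,
             K_N = 1e-6)
  list(lower = lower[spec$free_params],
       upper = rep(Inf, length(spec$free_params)))
}

#' Nonlinear least-squares fit of a colimitation model
#'
#' Minimizes the sum of squared deviations between observed per-habitat
#' growth rates and the model surface over the spec's free parameters,
#' using Levenberg-Marquardt with non-negativity bounds
#' (`minpack.lm::nls.lm`). The default protocol fixes `mu_max` at 2.4
#' day^-1 (the maximum rate previously observed in these microhabitats)
#' and `N0` at 0 uM (cells nitrogen-starved before seeding), leaving
#' `L0`, `K_L`, `K_N` free.
#'
#' To guard against local minima, the optimizer is restarted from
#' `n_starts` deterministically scaled versions of the initial guess and
#' the best-SSE solution is kept, so results are reproducible given the
#' same data and init.
#'
#' @param mat A `growth_rate_matrix` data.frame (columns `nitrogen_uM`,
#'   `par`, `mu_per_day`, ...) or a list of them (pooled).
#' @param spec A [model_spec()] (default: full multiplicative storage
#'   form with the standard fixed/free split).
#' @param init Optional named vector of starting values for the free
#'   parameters; sensible data-driven defaults otherwise.
#' @param bounds Optional list `lower`/`upper` named vectors; default
#'   constrains all free parameters to be non-negative, with
#'   half-saturation constants >= 1e-6 to keep denominators positive.
#' @param n_starts Number of multi-start restarts (default 5).
#' @return A `colim_fit` list: `spec`, `estimates` (free parameters),
#'   `params_full` (free + fixed), `sse` (day^-2), `r2`, `n_obs`,
#'   `converged`.
#' @export
nls_fit <- function(mat, spec = model_spec(), init = NULL, bounds = NULL,
                    n_starts = 5) {
  mat <- as_rate_matrix(mat)
  if (nrow(mat) == 0) stop("growth-rate matrix is empty")
  free <- spec$free_params
  if (nrow(mat) < length(free))
    stop("non-identifiable: ", nrow(mat), " observation(s) for ",
         length(free), " free parameter(s)")
  mu_obs <- mat$mu_per_day
  if (length(unique(mu_obs)) == 1L && length(free) > 0)
    stop("degenerate fitting surface: all observed rates identical")
  if (is.null(init)) init <- default_init(spec, mat)
  init <- init[free]
  if (anyNA(init)) stop("init must name every free parameter")
  b <- default_bounds(spec)
  if (!is.null(bounds)) {
    if (!is.null(bounds$lower)) b$lower[names(bounds$lower)] <- bounds$lower
    if (!is.null(bounds$upper)) b$upper[names(bounds$upper)] <- bounds$upper
  }
  resid_fun <- function(par) {
    names(par) <- free
    mu_obs - eval_model(spec, mat$par, mat$nitrogen_uM, par)
  }
  scale_table <- c(1, 0.3, 3, 0.1, 10)  # deterministic multi-start scales
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- pmin(pmax(init * scale_table[((s - 1) %% 5) + 1], b$lower),
                  ifelse(is.finite(b$upper), b$upper, init * 1e6))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = b$lower, upper = b$upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-15, ptol = 1e-15, maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse)
      best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) {
    return(structure(list(spec = spec, estimates = init,
                          params_full = NULL, sse = NA_real_, r2 = NA_real_,
                          n_obs = nrow(mat), converged = FALSE),
                     class = "colim_fit"))
  }
  est <- best$fit$par
  names(est) <- free
  full <- unlist(spec$fixed_params)
  full[free] <- est
  sst <- sum((mu_obs - mean(mu_obs))^2)
  converged <- best$fit$info %in% 1:4
  structure(list(spec = spec, estimates = est, params_full = full,
                 sse = best$sse, r2 = 1 - best$sse / sst,
                 n_obs = nrow(mat), converged = converged),
            class = "colim_fit")
}

#' @export
print.colim_fit <- function(x, ...) {
  cat(sprintf("colim_fit [%s]%s\n", x$spec$form,
              if (!x$converged) " (NOT CONVERGED)" else ""))
  cat("  free:  ", paste(sprintf("%s = %.4g", names(x$estimates),
                                 x$estimates), collapse = ", "), "\n")
  if (length(x$spec$fixed_params))
    cat("  fixed: ", paste(sprintf("%s = %.4g", names(x$spec$fixed_params),
                                   unlist(x$spec$fixed_params)),
                           collapse = ", "), "\n")
  cat(sprintf("  SSE = %.4g day^-2, R2 = %.4f, n = %d\n", x$sse, x$r2,
              x$n_obs))
  invisible(x)
}

# Per-condition replicate-selection weights proportional to 1/se^2.
# se = 0 takes the largest finite weight at that condition, or uniform
# weights if every replicate's se is 0.
condition_weights <- function(se) {
  w <- ifelse(se > 0, 1 / se^2, NA_real_)
  if (all(is.na(w))) return(rep(1 / length(se), length(se)))
  w[is.na(w)] <- max(w, na.rm = TRUE)
  w / sum(w)
}

# Shared machinery: index the rate records by condition and replicate and
# pre-compute selection weights.
index_conditions <- function(mat) {
  cond <- interaction(mat$row, mat$col, drop = TRUE)
  idx <- split(seq_len(nrow(mat)), cond)
  weights <- lapply(idx, function(i) condition_weights(mat$se_per_day[i]))
  list(idx = idx, weights = weights)
}

# One resampled matrix: for every condition draw one replicate's record
# with the precomputed weights.
draw_matrix <- function(mat, ci) {
  pick <- vapply(seq_along(ci$idx), function(j) {
    i <- ci$idx[[j]]
    if (length(i) == 1L) i else i[sample.int(length(i), 1L,
                                             prob = ci$weights[[j]])]
  }, integer(1))
  mat[pick, , drop = FALSE]
}

#' Weighted-bootstrap estimation of colimitation parameters
#'
#' Repeats `B` times: for each (row, col) condition of the array, draw one
#' replicate's growth-rate record with probability proportional to the
#' reciprocal of its squared standard error (so better-determined
#' replicates are chosen more often), then fit the model to the resampled
#' matrix by unweighted nonlinear least squares and record the free
#' parameters. The reported estimate of each parameter is the mean of its
#' `B` bootstrap values; the spread and pairwise correlations of the
#' bootstrap distributions quantify uncertainty.
#'
#' Per-run fits are warm-started from the pooled point fit (a single
#' start), which is where every resampled surface's optimum lies nearby.
#'
#' @param mats A `growth_rate_matrix` containing all replicates (keyed by
#'   `replicate_id`), or a list of per-replicate matrices sharing the
#'   environment grid.
#' @param spec A [model_spec()].
#' @param B Number of bootstrap runs (default 1000).
#' @param seed Integer RNG seed.
#' @param init,bounds Passed to [nls_fit()] (init defaults to the pooled
#'   point-fit estimates).
#' @return A `colim_boot` list: `samples` (B x p matrix of free-parameter
#'   values), `means`, `sds`, `correlations`, `B`, `seed`, `spec`,
#'   `point_fit`, `sse_mean`, `r2_mean`, `selection_counts` (draws per
#'   replicate id), `n_dropped_conditions`.
#' @export
bootstrap_fit <- function(mats, spec = model_spec(), B = 1000, seed = 1L,
                          init = NULL, bounds = NULL) {
  mat <- as_rate_matrix(mats)
  if (nrow(mat) == 0) stop("no growth-rate records to resample")
  point <- nls_fit(mat, spec, init = init, bounds = bounds)
  if (!point$converged) stop("pooled point fit did not converge")
  full_grid <- expand.grid(row = sort(unique(mat$row)),
                           col = sort(unique(mat$col)))
  present <- unique(mat[, c("row", "col")])
  n_dropped <- nrow(full_grid) - nrow(present)
  if (n_dropped > 0)
    warning(n_dropped, " grid condition(s) have no record in any replicate",
            " and are dropped")
  ci <- index_conditions(mat)
  set.seed(as.integer(seed))
  free <- spec$free_params
  samples <- matrix(NA_real_, nrow = B, ncol = length(free),
                    dimnames = list(NULL, free))
  sse <- r2 <- numeric(B)
  sel <- integer(0)
  for (b in seq_len(B)) {
    mb <- draw_matrix(mat, ci)
    tab <- table(mb$replicate_id)
    sel[names(tab)] <- ifelse(is.na(sel[names(tab)]), 0L,
                              sel[names(tab)]) + as.integer(tab)
    fit <- nls_fit(mb, spec, init = point$estimates, bounds = bounds,
                   n_starts = 1)
    samples[b, ] <- fit$estimates
    sse[b] <- fit$sse
    r2[b] <- fit$r2
  }
  sds <- apply(samples, 2, stats::sd)
  corr <- suppressWarnings(stats::cor(samples))
  corr[!is.finite(corr)] <- NA_real_
  diag(corr) <- 1
  structure(list(samples = samples, means = colMeans(samples), sds = sds,
                 correlations = corr, B = B, seed = as.integer(seed),
                 spec = spec, point_fit = point, sse_mean = mean(sse),
                 r2_mean = mean(r2), selection_counts = sel,
                 n_dropped_conditions = n_dropped),
            class = "colim_boot")
}

#' @export
print.colim_boot <- function(x, ...) {
  cat(sprintf("colim_boot [%s], B = %d, seed = %d\n", x$spec$form, x$B,
              x$seed))
  for (p in names(x$means))
    cat(sprintf("  %-6s = %.4g (sd %.3g)\n", p, x$means[[p]], x$sds[[p]]))
  cat(sprintf("  mean SSE = %.4g, mean R2 = %.4f\n", x$sse_mean, x$r2_mean))
  invisible(x)
}

#' Significance of a bootstrap parameter estimate
#'
#' Tests whether a fitted parameter differs from a null value, in two
#' ways: a two-sided normal approximation
#' `p = 2 * (1 - Phi(|mean - null| / sd))` on the bootstrap distribution,
#' and the (two-sided) bootstrap tail fraction
#' `2 * min(frac <= null, frac >= null)`.
#'
#' @param result A [bootstrap_fit()] result.
#' @param param Free-parameter name.
#' @param null_value Null value (default 0).
#' @return A list `p_wald`, `p_tail`.
#' @export
param_significance <- function(result, param, null_value = 0) {
  stopifnot(inherits(result, "colim_boot"))
  if (!param %in% colnames(result$samples))
    stop("'", param, "' is not a free parameter of this fit")
  s <- result$samples[, param]
  m <- mean(s); sd_ <- stats::sd(s)
  if (sd_ == 0) {
    warning("bootstrap distribution of ", param, " is degenerate (sd = 0)")
    p_wald <- if (m == null_value) 1 else 0
  } else {
    p_wald <- 2 * stats::pnorm(-abs(m - null_value) / sd_)
  }
  p_tail <- 2 * min(mean(s <= null_value), mean(s >= null_value))
  list(p_wald = p_wald, p_tail = min(p_tail, 1))
}

# Small-sample corrected AIC from a Gaussian error model with k free
# parameters (+1 for the error variance).
aicc_gaussian <- function(sse, n, k_free) {
  k <- k_free + 1
  aic <- n * log(sse / n) + 2 * k
  if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else Inf
}

#' Compare colimitation model forms on a shared bootstrap stream
#'
#' Fits each candidate model spec to the same sequence of resampled
#' growth-rate matrices (identical condition draws for every spec, so the
#' comparison is paired) and summarizes goodness of fit by mean SSE, mean
#' R-squared, and mean small-sample AIC, with rankings under each metric.
#' Specs failing to converge in more than 10% of runs are excluded with a
#' warning.
#'
#' @param mats A combined `growth_rate_matrix` or list of per-replicate
#'   matrices.
#' @param specs List of [model_spec()] objects (typically the
#'   multiplicative storage form against rivals).
#' @param B Number of shared bootstrap draws (default 200).
#' @param seed Integer RNG seed.
#' @return A `colim_compare` data.frame with one row per retained spec:
#'   `form, k_free, sse_mean, r2_mean, aicc_mean, n_fail, rank_sse,
#'   rank_r2, rank_aicc`.
#' @export
compare_models <- function(mats, specs, B = 200, seed = 1L) {
  if (!length(specs)) stop("need at least one model spec")
  mat <- as_rate_matrix(mats)
  ci <- index_conditions(mat)
  set.seed(as.integer(seed))
  draws <- lapply(seq_len(B), function(b) draw_matrix(mat, ci))
  rows <- list()
  for (spec in specs) {
    point <- tryCatch(nls_fit(mat, spec), error = function(e) NULL)
    sse <- r2 <- aicc <- rep(NA_real_, B)
    fails <- 0L
    for (b in seq_len(B)) {
      fit <- tryCatch(
        nls_fit(draws[[b]], spec,
                init = if (!is.null(point) && point$converged)
                  point$estimates else NULL,
                n_starts = 1),
        error = function(e) NULL)
      if (is.null(fit) || !fit$converged) { fails <- fails + 1L; next }
      sse[b] <- fit$sse; r2[b] <- fit$r2
      aicc[b] <- aicc_gaussian(fit$sse, fit$n_obs,
                               length(spec$free_params))
    }
    if (fails > 0.1 * B) {
      warning("model form '", spec$form, "' failed to converge in ", fails,
              "/", B, " runs; excluded from the comparison")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      form = spec$form, k_free = length(spec$free_params),
      sse_mean = mean(sse, na.rm = TRUE), r2_mean = mean(r2, na.rm = TRUE),
      aicc_mean = mean(aicc, na.rm = TRUE), n_fail = fails)
  }
  if (!length(rows)) stop("no model form survived the comparison")
  out <- do.call(rbind, rows)
  if (nrow(out) > 1) {
    out$rank_sse <- rank(out$sse_mean, ties.method = "min")
    out$rank_r2 <- rank(-out$r2_mean, ties.method = "min")
    out$rank_aicc <- rank(out$aicc_mean, ties.method = "min")
  }
  class(out) <- c("colim_compare", "data.frame")
  out
}

#' Growth-rate prediction map
#'
#' Evaluates the multiplicative colimitation model on a rectangular grid
#' of light and nitrogen values — the lookup map predicting growth rate
#' for any resource combination. Rows index nitrogen, columns light; the
#' surface is non-decreasing along both axes.
#'
#' @param params A [monod_params()] (e.g. bootstrap means).
#' @param L_grid Ascending vector of PAR values.
#' @param N_grid Ascending vector of nitrogen concentrations (uM).
#' @return Numeric matrix `length(N_grid) x length(L_grid)` of growth
#'   rates (day^-1) with `dimnames = list(N_grid, L_grid)`.
#' @export
predict_map <- function(params, L_grid, N_grid) {
  if (any(L_grid < 0) || any(N_grid < 0))
    stop("grids must be non-negative")
  if (is.unsorted(L_grid) || is.unsorted(N_grid))
    stop("grids must be ascending")
  out <- outer(N_grid, L_grid,
               function(N, L) growth_rate_multiplicative(L, N, params))
  dimnames(out) <- list(format(N_grid, trim = TRUE),
                        format(L_grid, trim = TRUE))
  out
}

#' Write a prediction map as CSV
#'
#' Grid CSV: first column holds the nitrogen values (uM), the header row
#' the light values (PAR), body cells the predicted rates.
#'
#' @param map A [predict_map()] matrix.
#' @param path File path.
#' @export
write_map_csv <- function(map, path) {
  df <- data.frame(nitrogen_uM = rownames(map), map, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Predicted versus observed growth rates
#'
#' Pairs each observed per-habitat rate with the model prediction at its
#' light/nitrogen condition and reports the coefficient of determination
#' `R2 = 1 - SSE / SST` of the pairing.
#'
#' @param mat A `growth_rate_matrix`.
#' @param params A [monod_params()].
#' @return Data.frame with columns `mu_pred`, `mu_obs` (plus the keys),
#'   and attribute `r2`.
#' @export
predicted_vs_observed <- function(mat, params) {
  mat <- as_rate_matrix(mat)
  pred <- growth_rate_multiplicative(mat$par, mat$nitrogen_uM, params)
  obs <- mat$mu_per_day
  out <- data.frame(replicate_id = mat$replicate_id, row = mat$row,
                    col = mat$col, mu_pred = pred, mu_obs = obs)
  attr(out, "r2") <- 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  out
}

#' Bootstrap fit report as JSON
#'
#' Serializes a [bootstrap_fit()] result (model form, fixed and free
#' parameters, estimates, sds, correlations, goodness of fit) to the flat
#' JSON report consumed by [run_prediction()].
#'
#' @param boot A `colim_boot`.
#' @param path Optional file path.
#' @return JSON string (invisibly when written to file).
#' @export
fit_report_json <- function(boot, path = NULL) {
  stopifnot(inherits(boot, "colim_boot"))
  obj <- list(model_form = boot$spec$form,
              fixed = boot$spec$fixed_params,
              free = names(boot$means),
              estimates = as.list(boot$means),
              sds = as.list(boot$sds),
              correlations = boot$correlations,
              B = boot$B, seed = boot$seed,
              sse_mean = boot$sse_mean, r2_mean = boot$r2_mean,
              aicc_mean = aicc_gaussian(boot$sse_mean,
                                        boot$point_fit$n_obs,
                                        length(boot$means)))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
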