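#' Monod colimitation parameter set
#'
#' Bundles the five parameters of the multiplicative light-nitrogen
#' colimitation model: the maximum specific growth rate, a light "storage"
#' offset representing acetate-derived energy available in the dark, the
#' light half-saturation constant, a stored-nitrogen offset, and the
#' nitrogen half-saturation constant.
#'
#' @param mu_max Maximum specific growth rate (day^-1). Must be >= 0.
#' @param L0 Light-equivalent storage term (umol m^-2 s^-1). Must be >= 0.
#' @param K_L Light half-saturation constant (umol m^-2 s^-1). Must be > 0.
#' @param N0 Stored-nitrogen term (uM). Must be >= 0.
#' @param K_N Nitrogen half-saturation constant (uM). Must be > 0.
#' @return An object of class `monod_params`: a named numeric vector with
#'   elements `mu_max`, `L0`, `K_L`, `N0`, `K_N`.
#' @examples
#' p <- monod_params(mu_max = 2.4, L0 = 50.8, K_L = 57.2, N0 = 0, K_N = 2.8)
#' growth_rate_multiplicative(41.4, 30.8, p)
#' @export
monod_params <- function(mu_max, L0 = 0, K_L, N0 = 0, K_N) {
  p <- c(mu_max = as.numeric(mu_max), L0 = as.numeric(L0),
         K_L = as.numeric(K_L), N0 = as.numeric(N0), K_N = as.numeric(K_N))
  validate_monod_params(p)
  structure(p, class = "monod_params")
}

validate_monod_params <- function(p) {
  nm <- c("mu_max", "L0", "K_L", "N0", "K_N")
  if (!all(nm %in% names(p)))
    stop("monod_params requires fields: ", paste(nm, collapse = ", "))
  if (anyNA(p[nm]) || any(p[nm] < 0))
    stop("all Monod parameters must be finite and >= 0")
  if (p[["K_L"]] <= 0 || p[["K_N"]] <= 0)
    stop("half-saturation constants K_L and K_N must be strictly positive")
  invisible(p)
}

#' @export
print.monod_params <- function(x, ...) {
  cat("Monod colimitation parameters:\n")
  cat(sprintf("  mu_max = %.4g day^-1\n", x[["mu_max"]]))
  cat(sprintf("  L0     = %.4g umol m^-2 s^-1\n", x[["L0"]]))
  cat(sprintf("  K_L    = %.4g umol m^-2 s^-1\n", x[["K_L"]]))
  cat(sprintf("  N0     = %.4g uM\n", x[["N0"]]))
  cat(sprintf("  K_N    = %.4g uM\n", x[["K_N"]]))
  invisible(x)
}

check_env_inputs <- function(L, N) {
  if (anyNA(L) || anyNA(N) || any(L < 0) || any(N < 0))
    stop("light and nitrogen inputs must be non-negative and non-missing")
}

monod_factor <- function(x, storage, half_sat) {
  (x + storage) / (half_sat + x + storage)
}

#' Multiplicative Monod colimitation growth rate
#'
#' Specific growth rate under simultaneous light and nitrogen limitation,
#' modelled as the product of two saturating Monod factors, each with a
#' storage offset:
#' \deqn{\mu(L, N) = \mu_{max}\frac{L + L_0}{K_L + L + L_0}
#'                            \frac{N + N_0}{K_N + N + N_0}}
#'
#' The result is 0 exactly when `L + L0 == 0` or `N + N0 == 0`, and
#' approaches `mu_max` as both resources saturate.
#'
#' @param L Photosynthetically active radiation (umol m^-2 s^-1), >= 0.
#'   Vectorized; recycled against `N`.
#' @param N Nitrogen concentration (uM), >= 0. Vectorized.
#' @param p A [monod_params()] object (or named vector with the same fields).
#' @return Growth rate(s) in day^-1, in `[0, mu_max)`.
#' @export
growth_rate_multiplicative <- function(L, N, p) {
  check_env_inputs(L, N)
  validate_monod_params(p)
  p[["mu_max"]] *
    monod_factor(L, p[["L0"]], p[["K_L"]]) *
    monod_factor(N, p[["N0"]], p[["K_N"]])
}

#' Law-of-minimum (Liebig) colimitation growth rate
#'
#' Alternative to the multiplicative form in which only the most limiting
#' resource sets the growth rate:
#' \deqn{\mu(L, N) = \mu_{max}\,\min\!\left(\frac{L + L_0}{K_L + L + L_0},
#'                                          \frac{N + N_0}{K_N + N + N_0}\right)}
#' The saturating factors are identical to those of
#' [growth_rate_multiplicative()], so the two forms are nested over the same
#' parameter vector and can be compared fairly.
#'
#' @inheritParams growth_rate_multiplicative
#' @return Growth rate(s) in day^-1.
#' @export
growth_rate_liebig <- function(L, N, p) {
  check_env_inputs(L, N)
  validate_monod_params(p)
  p[["mu_max"]] * pmin(monod_factor(L, p[["L0"]], p[["K_L"]]),
                       monod_factor(N, p[["N0"]], p[["K_N"]]))
}

#' Saturating-factor specification for the generalized product model
#'
#' @param value_name Label of the environmental factor (e.g. "light").
#' @param storage Storage offset in the factor's units, >= 0.
#' @param half_sat Half-saturation constant in the factor's units, > 0.
#' @return A `factor_spec` list.
#' @export
factor_spec <- function(value_name, storage = 0, half_sat) {
  if (!is.character(value_name) || length(value_name) != 1L)
    stop("value_name must be a single string")
  storage <- as.numeric(storage); half_sat <- as.numeric(half_sat)
  if (is.na(storage) || storage < 0) stop("storage must be >= 0")
  if (is.na(half_sat) || half_sat <= 0) stop("half_sat must be > 0")
  structure(list(value_name = value_name, storage = storage,
                 half_sat = half_sat), class = "factor_spec")
}

#' Generalized n-factor product colimitation growth rate
#'
#' Extension of the two-resource multiplicative model to any number of
#' independent, non-substitutable limiting factors:
#' \deqn{\mu = \mu_{max}\prod_i \frac{E_i + E_{i0}}{K_{E_i} + E_i + E_{i0}}}
#'
#' With factors light and nitrogen this reduces bit-for-bit to
#' [growth_rate_multiplicative()]; with an empty factor list it returns
#' `mu_max`.
#'
#' @param factors A list of `list(value = <numeric >= 0>, spec = <factor_spec>)`
#'   pairs, one per limiting factor. Values may be vectors of a common length.
#' @param mu_max Maximum growth rate at saturation (day^-1), >= 0.
#' @return Growth rate(s) in day^-1.
#' @export
growth_rate_product <- function(factors, mu_max) {
  if (is.na(mu_max) || mu_max < 0) stop("mu_max must be >= 0")
  out <- mu_max
  for (f in factors) {
    if (!inherits(f$spec, "factor_spec"))
      stop("each factor needs a 'spec' of class factor_spec")
    v <- f$value
    if (anyNA(v) || any(v < 0))
      stop("factor values must be non-negative (", f$spec$value_name, ")")
    out <- out * monod_factor(v, f$spec$storage, f$spec$half_sat)
  }
  out
}

#' Colimitation model specification
#'
#' Names a member of the model family and fixes the free/fixed split of its
#' parameters, as used by [nls_fit()] and [bootstrap_fit()].
#'
#' Forms:
#' \describe{
#'   \item{`multiplicative_storage`}{the full model with storage terms;
#'     default protocol fixes `mu_max = 2.4` day^-1 and `N0 = 0` uM (cells
#'     nitrogen-starved before seeding) and frees `L0`, `K_L`, `K_N`. With
#'     `acetate = FALSE`, `L0` is additionally fixed at 0 (no dark growth
#'     without acetate).}
#'   \item{`multiplicative_basic`}{reduced form
#'     `mu_0 * L/(K_L+L) * N/(K_N+N)` with free `mu_0`, `K_L`, `K_N` and
#'     both storages forced to 0.}
#'   \item{`liebig_min`}{law-of-minimum form over the same parameters as
#'     `multiplicative_storage`.}
#' }
#'
#' @param form One of `"multiplicative_storage"`, `"multiplicative_basic"`,
#'   `"liebig_min"`.
#' @param fixed Named list overriding the default fixed-parameter values.
#' @param free Character vector overriding the default free-parameter set.
#' @param acetate Logical; acetate present in the medium? Controls whether
#'   `L0` is free (TRUE, default) or fixed at 0 (FALSE). Only used by the
#'   storage and Liebig forms.
#' @return A `model_spec` list with elements `form`, `free_params`,
#'   `fixed_params`.
#' @export
model_spec <- function(form = c("multiplicative_storage",
                                "multiplicative_basic", "liebig_min"),
                       fixed = NULL, free = NULL, acetate = TRUE) {
  form <- match.arg(form)
  if (form == "multiplicative_basic") {
    all_par <- c("mu_0", "K_L", "K_N")
    def_free <- all_par
    def_fixed <- list()
  } else {
    all_par <- c("mu_max", "L0", "K_L", "N0", "K_N")
    if (acetate) {
      def_free <- c("L0", "K_L", "K_N")
      def_fixed <- list(mu_max = 2.4, N0 = 0)
    } else {
      def_free <- c("K_L", "K_N")
      def_fixed <- list(mu_max = 2.4, L0 = 0, N0 = 0)
    }
  }
  free_params <- if (is.null(free)) def_free else free
  fixed_params <- def_fixed
  if (!is.null(fixed)) fixed_params[names(fixed)] <- fixed
  fixed_params <- fixed_params[setdiff(names(fixed_params), free_params)]
  covered <- union(free_params, names(fixed_params))
  if (!setequal(covered, all_par))
    stop("free + fixed parameters must cover exactly {",
         paste(all_par, collapse = ", "), "}; got {",
         paste(sort(covered), collapse = ", "), "}")
  structure(list(form = form, free_params = free_params,
                 fixed_params = fixed_params), class = "model_spec")
}

#' Evaluate a model_spec at given parameter values
#'
#' @param spec A [model_spec()].
#' @param L,N Environmental values (vectorized).
#' @param par Named numeric vector supplying at least the spec's free
#'   parameters; fixed parameters are taken from the spec.
#' @return Growth rate(s) in day^-1.
#' @export
eval_model <- function(spec, L, N, par) {
  full <- unlist(spec$fixed_params)
  full[names(par)] <- par
  if (spec$form == "multiplicative_basic") {
    p <- c(mu_max = unname(full[["mu_0"]]), L0 = 0,
           K_L = unname(full[["K_L"]]), N0 = 0, K_N = unname(full[["K_N"]]))
    growth_rate_multiplicative(L, N, p)
  } else if (spec$form == "liebig_min") {
    growth_rate_liebig(L, N, full[c("mu_max", "L0", "K_L", "N0", "K_N")])
  } else {
    growth_rate_multiplicative(L, N, full[c("mu_max", "L0", "K_L", "N0", "K_N")])
  }
}

#' Serialize / deserialize Monod parameters as flat JSON
#'
#' Keys are `mu_max`, `L0`, `K_L`, `N0`, `K_N` and `form`; units are
#' day^-1, umol m^-2 s^-1 (light terms) and uM (nitrogen terms).
#'
#' @param p A [monod_params()] object.
#' @param form Model-form label stored alongside the values.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return `params_to_json`: JSON string (invisibly, if written to file).
#'   `params_from_json`: a list with `params` ([monod_params()]) and `form`.
#' @export
params_to_json <- function(p, form = "multiplicative_storage", path = NULL) {
  validate_monod_params(p)
  obj <- c(as.list(unclass(p)), list(form = form))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname params_to_json
#' @param json JSON string or file path to parse.
#' @export
params_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  p <- monod_params(mu_max = obj$mu_max, L0 = obj$L0, K_L = obj$K_L,
                    N0 = obj$N0, K_N = obj$K_N)
  list(params = p, form = if (is.null(obj$form)) "multiplicative_storage" else obj$form)
}
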