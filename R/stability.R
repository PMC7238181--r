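#' One accelerated-stability condition
#'
#' Observations of drug content at one temperature / relative-humidity
#' condition. Fitting is always done on the percent-degraded scale; data
#' recorded as percent remaining are converted at ingest via the
#' `convention` flag.
#'
#' @param temp_c Storage temperature (degrees C).
#' @param rh Relative humidity (%RH, in \[0, 100\]).
#' @param days Sampling days, non-negative and increasing.
#' @param percent Drug content at each day, as percent remaining
#'   (`convention = "remaining"`, default) or percent degraded.
#' @param convention Scale of `percent`.
#' @return Object of class `stability_condition` with fields `temp_k`, `rh`,
#'   `days`, `degraded` (percent degraded).
#' @export
stability_condition <- function(temp_c, rh, days, percent,
                                convention = c("remaining", "degraded")) {
  convention <- match.arg(convention)
  temp_k <- temp_c + 273.15
  if (temp_k <= 273) stop_domain("temperature must be above 273 K")
  if (rh < 0 || rh > 100) stop_domain("`rh` must lie in [0, 100]")
  if (length(days) != length(percent)) stop_domain("`days` and `percent` lengths differ")
  if (any(days < 0) || any(diff(days) <= 0)) {
    stop_domain("`days` must be non-negative and increasing")
  }
  degraded <- if (convention == "remaining") 100 - percent else percent
  structure(
    list(temp_k = temp_k, rh = rh, days = as.numeric(days),
         degraded = as.numeric(degraded), convention = convention),
    class = "stability_condition"
  )
}

degradation_models <- function() c("zero", "first", "second", "diffusion", "avrami")

# Forward degradation curve on the percent-degraded scale. d_inf is the
# asymptotic percent degraded (100 for complete loss).
degradation_curve <- function(model, k, t, d_inf = 100,
                              avrami_form = c("canonical", "printed")) {
  avrami_form <- match.arg(avrami_form)
  switch(model,
    zero = k * t,
    first = d_inf * (1 - exp(-k * t)),
    second = d_inf * k * t / (1 / d_inf + k * t),
    diffusion = k * sqrt(t),
    avrami = if (avrami_form == "canonical") {
      d_inf * (1 - exp(-k * t^2))
    } else {
      # literal printed form (remaining = d_inf - exp(-k t^2)), expressed on
      # the degraded scale; kept only for comparison, dimensionally unsound
      exp(-k * t^2)
    },
    stop_domain("unknown degradation model: ", model)
  )
}

# 1-D least-squares fit of k for a nonlinear single-parameter curve: coarse
# log-spaced grid bracketing, then golden-section refinement.
fit_k_1d <- function(degraded, days, curve_fn, log10_range = c(-8, 2)) {
  sse <- function(log10_k) {
    sum((degraded - curve_fn(10^log10_k, days))^2)
  }
  grid <- seq(log10_range[1], log10_range[2], by = 0.05)
  vals <- vapply(grid, sse, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(sse, interval = c(lo, hi), tol = 1e-10)
  10^opt$minimum
}

#' Fit degradation kinetic models to one stability condition
#'
#' Each requested model is fitted by least squares in its stated functional
#' form on the percent-degraded scale: zero order `D = k t` and diffusion
#' `D = k sqrt(t)` by linear regression through the origin; first order
#' `D = D_inf (1 - exp(-k t))`, second order
#' `D = D_inf k t / (1/D_inf + k t)` and Avrami (canonical form
#' `D = D_inf (1 - exp(-k t^2))`) by one-dimensional nonlinear least squares
#' over k. Fits are returned best R^2 first.
#'
#' @param condition A [stability_condition()] with >= 3 observations.
#' @param models Subset of `"zero"`, `"first"`, `"second"`, `"diffusion"`,
#'   `"avrami"`.
#' @param d_inf Asymptotic percent degraded (default 100).
#' @param avrami_form `"canonical"` (default) or `"printed"` (the literal
#'   published expression, kept for comparison only).
#' @return List of `degradation_fit` objects sorted by R^2 descending; each
#'   carries `model`, `k` (with a `unit` attribute), `r_squared`.
#' @export
fit_degradation <- function(condition, models = degradation_models(),
                            d_inf = 100,
                            avrami_form = c("canonical", "printed")) {
  stopifnot(inherits(condition, "stability_condition"))
  avrami_form <- match.arg(avrami_form)
  models <- match.arg(models, degradation_models(), several.ok = TRUE)
  t <- condition$days
  d <- condition$degraded
  if (length(t) < 3L) stop_domain("need at least 3 observations")
  flat <- sd(d) == 0
  if (flat) warning("degenerate (flat) degradation data; returning k = 0 fits")

  units <- c(zero = "%/day", first = "1/day", second = "1/(%*day)",
             diffusion = "%/day^(1/2)", avrami = "1/day^2")
  fits <- lapply(models, function(m) {
    k <- if (flat) {
      0
    } else if (m == "zero") {
      unname(coef(lm(d ~ t + 0))[1])
    } else if (m == "diffusion") {
      st <- sqrt(t)
      unname(coef(lm(d ~ st + 0))[1])
    } else {
      fit_k_1d(d, t, function(k, tt) degradation_curve(m, k, tt, d_inf, avrami_form))
    }
    pred <- degradation_curve(m, k, t, d_inf, avrami_form)
    structure(
      list(model = m, k = structure(max(k, 0), unit = units[[m]]),
           r_squared = as.numeric(r_squared(d, pred)),
           convention = "percent_degraded", d_inf = d_inf,
           avrami_form = if (m == "avrami") avrami_form else NA_character_),
      class = "degradation_fit"
    )
  })
  fits[order(-vapply(fits, function(f) f$r_squared, numeric(1)))]
}

#' @export
print.degradation_fit <- function(x, ...) {
  cat(sprintf("<degradation_fit> %s order: k = %.4g %s (R^2 = %.4f)\n",
              x$model, x$k, attr(x$k, "unit"), x$r_squared))
  invisible(x)
}

#' Humidity-corrected Arrhenius regression
#'
#' Ordinary least-squares fit of `ln k = ln A - Ea / (R T) + B * RH` over a
#' set of condition-wise degradation rate constants. The gas constant is
#' fixed at R = 0.00198 kcal/(K mol), so Ea is reported in kcal/mol.
#'
#' @param rates A data frame with columns `temp_k` (or `temp_c`), `rh` and
#'   `k` (one rate constant per condition, all > 0). Needs >= 3 conditions
#'   spanning >= 2 distinct temperatures and >= 2 distinct RH values.
#' @return Object of class `arrhenius_fit` with fields `ln_a`, `ea`
#'   (kcal/mol), `b` (per %RH), `r_squared`, `fit` (the underlying `lm`).
#' @export
fit_arrhenius <- function(rates) {
  rates <- as.data.frame(rates)
  if (!"temp_k" %in% names(rates)) {
    if (!"temp_c" %in% names(rates)) stop_domain("`rates` needs a `temp_k` or `temp_c` column")
    rates$temp_k <- rates$temp_c + 273.15
  }
  if (!all(c("rh", "k") %in% names(rates))) stop_domain("`rates` needs `rh` and `k` columns")
  if (nrow(rates) < 3L) stop_domain("need >= 3 conditions")
  if (length(unique(rates$temp_k)) < 2L) {
    stop_domain("rank-deficient design: need >= 2 distinct temperatures")
  }
  if (length(unique(rates$rh)) < 2L) {
    stop_domain("rank-deficient design: need >= 2 distinct relative humidities")
  }
  if (any(rates$k <= 0)) stop_domain("all rate constants must be > 0")
  inv_t <- 1 / rates$temp_k
  rh <- rates$rh
  ln_k <- log(rates$k)
  fit <- lm(ln_k ~ inv_t + rh)
  structure(
    list(
      ln_a = unname(coef(fit)[1]),
      ea = -unname(coef(fit)[2]) * R_GAS_KCAL,
      b = unname(coef(fit)[3]),
      r_squared = as.numeric(r_squared(ln_k, fitted(fit))),
      gas_constant = R_GAS_KCAL,
      fit = fit
    ),
    class = "arrhenius_fit"
  )
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf(
    "Humidity-corrected Arrhenius fit: ln A = %.3f, Ea = %.3f kcal/mol, B = %.4g per %%RH (R^2 = %.4f)\n",
    x$ln_a, x$ea, x$b, x$r_squared
  ))
  invisible(x)
}

#' Predicted degradation rate at given conditions
#'
#' @param af An [fit_arrhenius()] result.
#' @param temp_k Temperature (K).
#' @param rh Relative humidity (%RH).
#' @return Rate constant `exp(ln A - Ea/(R T) + B RH)`.
#' @export
predict_rate <- function(af, temp_k, rh) {
  stopifnot(inherits(af, "arrhenius_fit"))
  exp(af$ln_a - af$ea / (af$gas_constant * temp_k) + af$b * rh)
}

#' Shelf life at storage conditions
#'
#' Extrapolates the degradation rate constant to the storage condition via
#' the Arrhenius surface, then inverts the selected kinetic model to find
#' the time at which percent degraded reaches the specification limit.
#'
#' @param af An [fit_arrhenius()] result.
#' @param model Kinetic model governing degradation at storage (one of
#'   [degradation_models()]).
#' @param storage_temp_c Storage temperature (default 25 degrees C).
#' @param storage_rh Storage relative humidity (default 60 %RH).
#' @param limit Specification limit, percent degraded (default 10).
#' @param d_inf Asymptotic percent degraded (default 100).
#' @return Object of class `shelf_life` with `k_extrapolated`,
#'   `shelf_life_days`, `shelf_life_years` and the inputs.
#' @export
predict_shelf_life <- function(af, model = "zero",
                               storage_temp_c = 25, storage_rh = 60,
                               limit = 10, d_inf = 100) {
  model <- match.arg(model, degradation_models())
  if (limit <= 0 || limit >= 100) stop_domain("`limit` must lie in (0, 100)")
  temp_k <- storage_temp_c + 273.15
  k <- predict_rate(af, temp_k, storage_rh)
  if (!is.finite(k) || k <= 0) stop_domain("extrapolated rate constant is not positive")
  if (model %in% c("first", "avrami", "second") && limit >= d_inf) {
    stop_domain("limit must be below d_inf for saturating kinetic models")
  }
  days <- switch(model,
    zero = limit / k,
    diffusion = (limit / k)^2,
    first = -log(1 - limit / d_inf) / k,
    second = limit / (d_inf * k * (d_inf - limit)),
    avrami = sqrt(-log(1 - limit / d_inf) / k)
  )
  structure(
    list(storage_temp_k = temp_k, storage_rh = storage_rh,
         k_extrapolated = k, specification_limit = limit, model = model,
         d_inf = d_inf, shelf_life_days = days, shelf_life_years = days / 365),
    class = "shelf_life"
  )
}

#' @export
print.shelf_life <- function(x, ...) {
  cat(sprintf(
    "Shelf life (%s-order kinetics, %.0f%% limit at %.1f K / %.0f%%RH): %.0f days (%.2f years), k = %.4g\n",
    x$model, x$specification_limit, x$storage_temp_k, x$storage_rh,
    x$shelf_life_days, x$shelf_life_years, x$k_extrapolated
  ))
  invisible(x)
}
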