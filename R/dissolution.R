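#' Dissolution profile of a dosage form
#'
#' Cumulative drug released over time. Small negative increments from assay
#' noise are clipped to the running maximum (tolerance `clip_epsilon` as a
#' fraction of `q_inf`); larger decreases are an error.
#'
#' @param times Sampling times (h), strictly increasing, >= 0.
#' @param released Cumulative release at each time, in percent of `q_inf`
#'   (`unit = "percent"`) or in mg (`unit = "mg"`).
#' @param q_inf Total drug in the dosage form (mg).
#' @param unit Unit of `released`.
#' @param geometry One of `"cylinder"`, `"thin_film"`, `"sphere"`; controls
#'   the Korsmeyer-Peppas mechanism thresholds.
#' @param medium_switch_time Optional time (h) of a medium/pH change event,
#'   kept as metadata.
#' @param clip_epsilon Tolerated negative increment as a fraction of `q_inf`
#'   (default 0.005, i.e. 0.5%).
#' @return Object of class `dissolution_profile`; `released_mg` holds the
#'   clipped cumulative amounts in mg.
#' @export
dissolution_profile <- function(times, released, q_inf,
                                unit = c("percent", "mg"),
                                geometry = c("cylinder", "thin_film", "sphere"),
                                medium_switch_time = NULL,
                                clip_epsilon = 0.005) {
  unit <- match.arg(unit)
  geometry <- match.arg(geometry)
  check_positive_scalar(q_inf, "q_inf")
  if (length(times) != length(released)) stop_domain("`times` and `released` lengths differ")
  if (any(diff(times) <= 0) || any(times < 0)) {
    stop_domain("`times` must be non-negative and strictly increasing")
  }
  q <- if (unit == "percent") released / 100 * q_inf else released
  if (any(q < -clip_epsilon * q_inf) || any(q > 1.1 * q_inf)) {
    stop_domain("released amounts must lie within [0, 1.1 * q_inf] (after noise tolerance)")
  }
  drops <- -pmin(0, diff(q))
  if (any(drops > clip_epsilon * q_inf)) {
    stop_domain("cumulative release decreases by more than clip_epsilon * q_inf")
  }
  q <- cummax(pmax(q, 0))
  structure(
    list(times = as.numeric(times), released_mg = q, q_inf = q_inf,
         geometry = geometry, medium_switch_time = medium_switch_time),
    class = "dissolution_profile"
  )
}

release_model_info <- function() {
  # fixed model order used for tie-breaking in select_best_model()
  tibble::tibble(
    model = c("zero_order", "first_order", "hixson_crowell", "korsmeyer_peppas"),
    n_params = c(1L, 2L, 1L, 2L)
  )
}

#' Fit drug-release kinetic models to a dissolution profile
#'
#' Fits each requested model in its stated functional form: zero order
#' `Q_t = K0 t` (least squares through the origin), first order
#' `ln Q_t = ln Q0 + K1 t` (linear on the log scale), Hixson-Crowell
#' `Q_inf^(1/3) - (Q_inf - Q_t)^(1/3) = Ks t` (through the origin on the
#' cube-root scale) and Korsmeyer-Peppas `Q_t/Q_inf = K_KP t^n` (nonlinear
#' least squares on the fractional scale, restricted to points with
#' fractional release <= `kp_fraction_cap`). R^2 is computed on each model's
#' fitted scale and floored at zero. Models that fail (e.g. too few points
#' after the cap) are recorded in the `errors` attribute; the remaining fits
#' are returned sorted by R^2 descending.
#'
#' @param profile A [dissolution_profile()].
#' @param models Character vector of models to fit (default all four).
#' @param kp_fraction_cap Fractional-release cap for the Korsmeyer-Peppas fit
#'   (default 0.6, the conventional 60% rule; set to 1 to use the full
#'   profile).
#' @param kp_scale `"natural"` (default, nonlinear fit of the power law) or
#'   `"log"` (linearised log-log fit).
#' @return List of `release_fit` objects sorted by R^2, with attribute
#'   `errors` (named list of per-model failure messages).
#' @export
fit_release_models <- function(profile,
                               models = release_model_info()$model,
                               kp_fraction_cap = 0.6,
                               kp_scale = c("natural", "log")) {
  stopifnot(inherits(profile, "dissolution_profile"))
  kp_scale <- match.arg(kp_scale)
  models <- match.arg(models, release_model_info()$model, several.ok = TRUE)
  t <- profile$times
  q <- profile$released_mg
  q_inf <- profile$q_inf
  if (length(t) < 4L) stop_domain("need at least 4 usable points")

  fit_one <- function(model) {
    switch(model,
      zero_order = {
        fit <- lm(q ~ t + 0)
        list(params = list(k0 = unname(coef(fit)[1])),
             obs = q, fitted = fitted(fit), n = length(t))
      },
      first_order = {
        pos <- q > 0
        if (sum(pos) < 3L) stop_domain("first-order fit needs >= 3 positive points")
        fit <- lm(log(q[pos]) ~ t[pos])
        list(params = list(k1 = unname(coef(fit)[2]), q0 = exp(unname(coef(fit)[1]))),
             obs = log(q[pos]), fitted = fitted(fit), n = sum(pos))
      },
      hixson_crowell = {
        y <- q_inf^(1 / 3) - (pmax(q_inf - q, 0))^(1 / 3)
        fit <- lm(y ~ t + 0)
        list(params = list(ks = unname(coef(fit)[1])),
             obs = y, fitted = fitted(fit), n = length(t))
      },
      korsmeyer_peppas = {
        frac <- q / q_inf
        keep <- frac <= kp_fraction_cap
        tk <- t[keep]
        fk <- frac[keep]
        if (sum(keep & frac > 0 & t > 0) < 3L) {
          stop_domain("too few points below the fractional-release cap")
        }
        start_ok <- fk > 0 & tk > 0
        start_fit <- lm(log(fk[start_ok]) ~ log(tk[start_ok]))
        n0 <- max(min(unname(coef(start_fit)[2]), 3), 0.05)
        k0 <- exp(unname(coef(start_fit)[1]))
        if (kp_scale == "log") {
          params <- list(k_kp = k0, n = unname(coef(start_fit)[2]))
          obs <- log(fk[start_ok])
          fitted_vals <- fitted(start_fit)
        } else {
          nls_fit <- minpack.lm::nlsLM(
            fk ~ k * tk^n,
            start = list(k = k0, n = n0),
            lower = c(k = 1e-12, n = 1e-6),
            control = minpack.lm::nls.lm.control(maxiter = 200)
          )
          params <- as.list(coef(nls_fit))
          names(params) <- c("k_kp", "n")
          obs <- fk
          fitted_vals <- fitted(nls_fit)
        }
        list(params = params, obs = obs, fitted = fitted_vals, n = length(tk))
      }
    )
  }

  fits <- list()
  errors <- list()
  for (m in models) {
    res <- tryCatch(fit_one(m), error = function(e) e)
    if (inherits(res, "error")) {
      errors[[m]] <- conditionMessage(res)
      next
    }
    mech <- if (m == "korsmeyer_peppas") {
      classify_mechanism(res$params$n, profile$geometry)
    } else {
      NA_character_
    }
    fits[[m]] <- structure(
      list(model = m, params = res$params,
           r_squared = as.numeric(r_squared(res$obs, res$fitted)),
           n_points_used = res$n, mechanism = mech),
      class = "release_fit"
    )
  }
  if (length(fits)) {
    fits <- fits[order(-vapply(fits, function(f) f$r_squared, numeric(1)))]
  }
  attr(fits, "errors") <- errors
  fits
}

#' @export
print.release_fit <- function(x, ...) {
  p <- paste(sprintf("%s = %.4g", names(x$params), unlist(x$params)), collapse = ", ")
  cat(sprintf("<release_fit> %s: %s (R^2 = %.4f, n = %d%s)\n",
              x$model, p, x$r_squared, x$n_points_used,
              if (!is.na(x$mechanism)) paste0(", mechanism: ", x$mechanism) else ""))
  invisible(x)
}

#' Classify the release mechanism from the Korsmeyer-Peppas exponent
#'
#' The Fickian threshold depends on the dosage-form geometry: 0.5 for a thin
#' film, 0.45 for a cylinder, 0.43 for a sphere. Exponents between the
#' threshold and 1 indicate anomalous (non-Fickian) transport; `n >= 1`
#' corresponds to zero-order transport.
#'
#' @param n Release exponent, > 0.
#' @param geometry `"cylinder"`, `"thin_film"` or `"sphere"`.
#' @return One of `"fickian"`, `"anomalous"`, `"zero_order_transport"`.
#' @examples
#' classify_mechanism(0.439, "cylinder") # fickian
#' @export
classify_mechanism <- function(n, geometry = c("cylinder", "thin_film", "sphere")) {
  geometry <- match.arg(geometry)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0) {
    stop_domain("`n` must be a positive finite exponent")
  }
  thr <- c(cylinder = 0.45, thin_film = 0.5, sphere = 0.43)[[geometry]]
  if (n >= 1) "zero_order_transport" else if (n <= thr) "fickian" else "anomalous"
}

#' Select the best-fitting release model
#'
#' Maximum R^2; exact ties are broken in favour of the model with fewer
#' parameters, then by the fixed order zero order, first order,
#' Hixson-Crowell, Korsmeyer-Peppas.
#'
#' @param fits List of `release_fit` objects (as from [fit_release_models()]).
#' @return The selected `release_fit`.
#' @export
select_best_model <- function(fits) {
  fits <- Filter(function(f) inherits(f, "release_fit"), fits)
  if (length(fits) == 0L) stop_domain("no successful fits to select from")
  info <- release_model_info()
  r2 <- vapply(fits, function(f) f$r_squared, numeric(1))
  np <- info$n_params[match(vapply(fits, function(f) f$model, character(1)), info$model)]
  ord <- match(vapply(fits, function(f) f$model, character(1)), info$model)
  fits[[order(-r2, np, ord)[1]]]
}

#' Correct cumulative release for sample withdrawal
#'
#' Standard cumulative correction for dissolution sampling: each withdrawn
#' aliquot removes drug from the vessel, so the cumulative amount at time i
#' is `V_medium[i] * C[i] + sample_volume * sum(C[1:(i-1)])`.
#'
#' @param conc_mg_ml Measured concentrations at each sampling time (mg/mL).
#' @param medium_volume_ml Vessel volume at each sampling time (mL); scalar
#'   or vector (use a vector when the medium volume changes mid-run).
#' @param sample_volume_ml Withdrawn aliquot volume (mL, default 2).
#' @return Corrected cumulative amounts (mg).
#' @export
correct_sample_withdrawal <- function(conc_mg_ml, medium_volume_ml, sample_volume_ml = 2) {
  n <- length(conc_mg_ml)
  vm <- rep_len(medium_volume_ml, n)
  prior <- c(0, cumsum(conc_mg_ml)[-n])
  vm * conc_mg_ml + sample_volume_ml * prior
}
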