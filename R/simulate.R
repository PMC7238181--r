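noise_models <- function() c("none", "additive_gaussian", "multiplicative_lognormal")

# Apply the declared noise family to a vector of true values. `noise_scale`
# is a fractional scale in both families: additive Gaussian perturbations
# have standard deviation noise_scale * |value| (heteroscedastic, proportional
# to the signal as assay noise is), lognormal noise multiplies by
# exp(N(0, noise_scale^2)).
apply_noise <- function(x, noise, noise_scale) {
  noise <- match.arg(noise, noise_models())
  if (noise_scale < 0) stop_domain("`noise_scale` must be >= 0")
  switch(noise,
    none = x,
    additive_gaussian = x + stats::rnorm(length(x), 0, noise_scale * abs(x)),
    multiplicative_lognormal = x * exp(stats::rnorm(length(x), 0, noise_scale))
  )
}

#' Generate a drug-loading time course with known flux
#'
#' Cumulative uptake is linear (`jss_true * S * t`) up to `plateau_time`,
#' then approaches an asymptote exponentially with time constant
#' `plateau_tau`, emulating the sharp early uptake followed by a gradual
#' levelling-off seen in passive-diffusion loading. Noise is applied
#' independently per replicate.
#'
#' @param jss_true True steady-state flux (mg/cm^2/h), >= 0.
#' @param geometry A [filament_geometry()].
#' @param t_points Sampling times (h); default the study design
#'   `c(0, 2, 4, 8, 24)` — the origin belongs to every cumulative uptake
#'   record (nothing has diffused at immersion time zero).
#' @param plateau_time Time (h) at which uptake departs from linearity
#'   (default 4).
#' @param plateau_tau Time constant (h) of the exponential approach to the
#'   asymptote (default 2).
#' @param replicates Number of replicate series (default 3).
#' @param noise One of [noise_models()].
#' @param noise_scale Fractional noise scale.
#' @param seed RNG seed (required for reproducibility).
#' @return A [diffusion_timecourse()].
#' @export
gen_diffusion_timecourse <- function(jss_true, geometry = filament_geometry(),
                                     t_points = c(0, 2, 4, 8, 24),
                                     plateau_time = 4, plateau_tau = 2,
                                     replicates = 3,
                                     noise = "none", noise_scale = 0,
                                     seed = 1) {
  if (jss_true < 0) stop_domain("`jss_true` must be >= 0")
  s <- geometry$surface_area
  mean_mass <- ifelse(
    t_points <= plateau_time,
    jss_true * s * t_points,
    jss_true * s * plateau_time +
      jss_true * s * plateau_tau * (1 - exp(-(t_points - plateau_time) / plateau_tau))
  )
  mass <- with_seed(seed, {
    vapply(seq_len(replicates), function(r) apply_noise(mean_mass, noise, noise_scale),
           numeric(length(t_points)))
  })
  diffusion_timecourse(t_points, pmax(mass, 0), geometry = geometry)
}

#' Generate a dissolution profile from a known release model
#'
#' Forward-evaluates the chosen release model, clips to `[0, q_inf]` and
#' applies noise. Model parameterisations mirror [fit_release_models()]:
#' zero order `Q = k0 t`; first order `Q = q0 exp(k1 t)`; Hixson-Crowell
#' `Q = q_inf - (q_inf^(1/3) - ks t)^3`; Korsmeyer-Peppas
#' `Q = q_inf k_kp t^n`.
#'
#' @param model One of the models in [release_model_info()].
#' @param params Named list of parameters for the model (`k0`; `q0`, `k1`;
#'   `ks`; `k_kp`, `n`).
#' @param q_inf Total drug in the dosage form (mg).
#' @param t_points Sampling times (h); default the study sampling scheme.
#' @param geometry Dosage-form geometry class for the profile.
#' @inheritParams gen_diffusion_timecourse
#' @return A [dissolution_profile()]; the attribute `clipped` on the profile
#'   flags whether the noiseless curve exceeded `q_inf` before clipping.
#' @export
gen_dissolution_profile <- function(model, params, q_inf = 15,
                                    t_points = c(1 / 12, 1 / 6, 0.25, 1 / 3, 0.5, 1, 2, 3, 4, 6, 24),
                                    geometry = "cylinder",
                                    noise = "none", noise_scale = 0, seed = 1) {
  model <- match.arg(model, release_model_info()$model)
  t <- t_points
  q <- switch(model,
    zero_order = params$k0 * t,
    first_order = params$q0 * exp(params$k1 * t),
    hixson_crowell = q_inf - (pmax(q_inf^(1 / 3) - params$ks * t, 0))^3,
    korsmeyer_peppas = q_inf * params$k_kp * t^params$n
  )
  clipped <- any(q > q_inf)
  q <- pmin(pmax(q, 0), q_inf)
  q <- with_seed(seed, apply_noise(q, noise, noise_scale))
  q <- cummax(pmin(pmax(q, 0), q_inf)) # keep cumulative and within range
  prof <- dissolution_profile(t, q, q_inf = q_inf, unit = "mg", geometry = geometry)
  attr(prof, "clipped") <- clipped
  prof
}

#' Generate condition-wise degradation rate constants
#'
#' Rate constants at each condition follow the humidity-corrected Arrhenius
#' surface `ln k = ln_a - ea / (R T) + b * RH`; noise (conventionally
#' multiplicative lognormal) acts on k directly.
#'
#' @param ln_a Log collision factor.
#' @param ea Activation energy (kcal/mol).
#' @param b Humidity sensitivity (per %RH).
#' @param conditions Tibble with `temp_c` and `rh` columns
#'   (default [stability_conditions_default()]).
#' @inheritParams gen_diffusion_timecourse
#' @return Tibble with `temp_c`, `temp_k`, `rh`, `k`.
#' @export
gen_arrhenius_rates <- function(ln_a = 32.5, ea = 23.38, b = 0.008,
                                conditions = stability_conditions_default(),
                                noise = "none", noise_scale = 0, seed = 1) {
  temp_k <- conditions$temp_c + 273.15
  k_true <- exp(ln_a - ea / (R_GAS_KCAL * temp_k) + b * conditions$rh)
  k <- with_seed(seed, apply_noise(k_true, noise, noise_scale))
  tibble::tibble(temp_c = conditions$temp_c, temp_k = temp_k,
                 rh = conditions$rh, k = k)
}

#' Generate a full accelerated-stability study
#'
#' Per condition, the rate constant comes from the Arrhenius surface and the
#' percent-degraded curve from the chosen kinetic model at the stated
#' sampling days; noise is applied to the observations. The defaults place
#' the synthetic study at the scale of the case study (Ea = 23.38 kcal/mol,
#' B = 0.008 per %RH); ln A defaults to 32.5, which keeps the hottest
#' condition below ~40% degraded at day 48 so curves stay in a usable assay
#' range.
#'
#' @inheritParams gen_arrhenius_rates
#' @param model Degradation model (one of [degradation_models()]).
#' @param d_inf Asymptotic percent degraded.
#' @return List of [stability_condition()] objects with attributes
#'   `true_k` (per-condition rate constants) and `truth`
#'   (the generating parameters).
#' @export
gen_stability_study <- function(ln_a = 32.5, ea = 23.38, b = 0.008,
                                model = "zero",
                                conditions = stability_conditions_default(),
                                d_inf = 100,
                                noise = "none", noise_scale = 0, seed = 1) {
  model <- match.arg(model, degradation_models())
  temp_k <- conditions$temp_c + 273.15
  k <- exp(ln_a - ea / (R_GAS_KCAL * temp_k) + b * conditions$rh)
  study <- with_seed(seed, {
    lapply(seq_len(nrow(conditions)), function(i) {
      days <- conditions$days[[i]]
      degraded <- degradation_curve(model, k[i], days, d_inf)
      degraded <- pmin(pmax(apply_noise(degraded, noise, noise_scale), 0), d_inf)
      stability_condition(conditions$temp_c[i], conditions$rh[i], days,
                          degraded, convention = "degraded")
    })
  })
  attr(study, "true_k") <- k
  attr(study, "truth") <- list(ln_a = ln_a, ea = ea, b = b, model = model, d_inf = d_inf)
  study
}

#' Generate a roughness profile with exact target Rav
#'
#' Zero-mean random heights rescaled so the realised mean absolute deviation
#' equals `rav_target` exactly.
#'
#' @param rav_target Target arithmetic average roughness (um), > 0.
#' @param n_points Number of points along the 8 mm sampling length.
#' @param sampling_length_mm Trace length (default 8 mm).
#' @inheritParams gen_diffusion_timecourse
#' @return A [roughness_profile()].
#' @export
gen_roughness_profile <- function(rav_target, n_points = 800,
                                  sampling_length_mm = 8, seed = 1) {
  check_positive_scalar(rav_target, "rav_target")
  z <- with_seed(seed, stats::rnorm(n_points))
  z <- z - mean(z)
  z <- z * rav_target / mean(abs(z))
  roughness_profile(seq(0, sampling_length_mm, length.out = n_points), z)
}

#' Generate an elastic-then-yield force-travel curve
#'
#' Linear loading of the given modulus up to `yield_travel`, then a smooth
#' plateau that decays toward `end_fraction` of the peak force by the end of
#' travel, emulating a three-point-bend record.
#'
#' @param modulus Initial slope (N/mm), > 0.
#' @param yield_travel Travel at yield (mm).
#' @param total_travel Total travel (mm, default `3 * yield_travel`).
#' @param n_points Number of samples (default 200).
#' @param end_fraction Force at end of travel as a fraction of peak
#'   (default 0.8).
#' @inheritParams gen_diffusion_timecourse
#' @return A [force_curve()].
#' @export
gen_force_curve <- function(modulus, yield_travel, total_travel = 3 * yield_travel,
                            n_points = 200, end_fraction = 0.8,
                            noise = "none", noise_scale = 0, seed = 1) {
  check_positive_scalar(modulus, "modulus")
  check_positive_scalar(yield_travel, "yield_travel")
  x <- seq(0, total_travel, length.out = n_points)
  peak <- modulus * yield_travel
  decay_span <- max(total_travel - yield_travel, .Machine$double.eps)
  rate <- -log(end_fraction) / decay_span
  f <- ifelse(x <= yield_travel, modulus * x, peak * exp(-rate * (x - yield_travel)))
  f <- with_seed(seed, apply_noise(f, noise, noise_scale))
  force_curve(x, pmax(f, 0))
}
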