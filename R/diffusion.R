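#' Filament section geometry
#'
#' Closed-cylinder geometry of a filament section. The surface area is
#' `S = 2 pi r^2 + 2 pi r h` with `r = diameter / 2`.
#'
#' @param length Section length h (cm).
#' @param diameter Section diameter (cm).
#' @return Object of class `filament_geometry` with fields `length`,
#'   `diameter` and derived `surface_area` (cm^2).
#' @examples
#' filament_geometry(1.0, 0.175)$surface_area # 0.598 cm^2
#' @export
filament_geometry <- function(length = 1.0, diameter = 0.175) {
  check_positive_scalar(length, "length")
  check_positive_scalar(diameter, "diameter")
  structure(
    list(length = length, diameter = diameter,
         surface_area = filament_surface_area(length, diameter)),
    class = "filament_geometry"
  )
}

#' Surface area of a filament section
#'
#' @param length Section length (cm), > 0.
#' @param diameter Section diameter (cm), > 0.
#' @return Closed-cylinder area `2 pi r^2 + 2 pi r h` in cm^2.
#' @export
filament_surface_area <- function(length, diameter) {
  check_positive_scalar(length, "length")
  check_positive_scalar(diameter, "diameter")
  r <- diameter / 2
  2 * pi * r^2 + 2 * pi * r * length
}

#' Drug-loading time course for one solvent-filament pair
#'
#' Cumulative drug mass extracted from filament sections as a function of
#' immersion time, one series per replicate.
#'
#' @param times Sampling times (h), strictly increasing, >= 0, length >= 3.
#' @param cumulative_mass Numeric matrix (or vector for a single replicate)
#'   with one row per time point and one column per replicate (mg).
#' @param geometry A [filament_geometry()].
#' @param solvent,filament Optional names for bookkeeping.
#' @return Object of class `diffusion_timecourse`.
#' @export
diffusion_timecourse <- function(times, cumulative_mass,
                                 geometry = filament_geometry(),
                                 solvent = NA_character_, filament = NA_character_) {
  if (length(times) < 3L) stop_domain("need at least 3 time points")
  if (any(diff(times) <= 0) || any(times < 0)) {
    stop_domain("`times` must be non-negative and strictly increasing")
  }
  m <- as.matrix(cumulative_mass)
  if (nrow(m) != length(times)) stop_domain("`cumulative_mass` must have one row per time point")
  if (any(m < 0)) stop_domain("cumulative masses must be non-negative")
  structure(
    list(times = as.numeric(times), cumulative_mass = m, geometry = geometry,
         solvent = solvent, filament = filament),
    class = "diffusion_timecourse"
  )
}

#' Steady-state flux from a loading time course
#'
#' Replicates are averaged per time point, cumulative mass is normalised by
#' the nominal section surface area, and the steady-state flux Jss is the
#' ordinary least-squares slope of mass-per-area against time over the linear
#' loading window (free intercept).
#'
#' @param tc A [diffusion_timecourse()].
#' @param window Length-2 numeric `(t_start, t_end)` in hours delimiting the
#'   linear portion; default `c(0, 4)`, the early loading window.
#' @return Object of class `flux_estimate` with fields `jss` (mg/cm^2/h),
#'   `intercept` (mg/cm^2), `r_squared`, `window` and `n_points_used`.
#' @export
fit_steady_state_flux <- function(tc, window = c(0, 4)) {
  stopifnot(inherits(tc, "diffusion_timecourse"))
  if (length(window) != 2L || window[2] <= window[1]) {
    stop_domain("`window` must be (t_start, t_end) with t_end > t_start")
  }
  keep <- tc$times >= window[1] & tc$times <= window[2]
  if (sum(keep) < 2L) stop_domain("fewer than 2 time points inside the window")
  t_w <- tc$times[keep]
  if (sd(t_w) == 0) stop_domain("zero time variance inside the window")
  m_w <- rowMeans(tc$cumulative_mass[keep, , drop = FALSE]) / tc$geometry$surface_area
  fit <- lm(m_w ~ t_w)
  structure(
    list(
      jss = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      r_squared = as.numeric(r_squared(m_w, fitted(fit))),
      window = window, n_points_used = sum(keep)
    ),
    class = "flux_estimate"
  )
}

#' @export
print.flux_estimate <- function(x, ...) {
  cat(sprintf(
    "Steady-state flux: Jss = %.4g mg/cm^2/h (intercept %.4g mg/cm^2, R^2 = %.4f, %d points in [%g, %g] h)\n",
    x$jss, x$intercept, x$r_squared, x$n_points_used, x$window[1], x$window[2]
  ))
  invisible(x)
}

#' Permeability coefficient
#'
#' `P = Jss / Csat`, the steady-state flux normalised by the drug's
#' saturation solubility in the loading vehicle.
#'
#' @param jss Steady-state flux (mg/cm^2/h).
#' @param csat Saturation solubility (mg/cm^3), > 0.
#' @return Permeability in cm/h.
#' @examples
#' permeability(0.203, 31.6) # 6.424e-3 cm/h
#' @export
permeability <- function(jss, csat) {
  if (!is.numeric(csat) || any(!is.finite(csat)) || any(csat <= 0)) {
    stop_domain("`csat` must be positive and finite")
  }
  jss / csat
}

#' Enhancement ratio between two solvents
#'
#' Ratio of steady-state flux in the reference solvent (ethanol in the case
#' study) to that in the comparator solvent, for the same filament.
#'
#' @param jss_ethanol Flux in the reference solvent (mg/cm^2/h).
#' @param jss_other Flux in the comparator solvent (mg/cm^2/h), > 0.
#' @return Unrounded ratio.
#' @export
enhancement_ratio <- function(jss_ethanol, jss_other) {
  if (any(jss_other <= 0)) stop_domain("denominator flux must be > 0")
  jss_ethanol / jss_other
}

#' Volume of a flat cylindrical tablet
#'
#' @param diameter_mm,height_mm Tablet dimensions in mm.
#' @return Volume in cm^3.
#' @examples
#' cylinder_volume(12, 4) # 0.452 cm^3
#' @export
cylinder_volume <- function(diameter_mm, height_mm) {
  check_positive_scalar(diameter_mm, "diameter_mm")
  check_positive_scalar(height_mm, "height_mm")
  pi * (diameter_mm / 20)^2 * (height_mm / 10)
}

#' Tablet dose geometry
#'
#' Given a target dose, the drug loading achieved in the filament, the
#' filament density and a tablet diameter, compute the tablet mass, volume
#' and height of a flat cylindrical design printed at 100% infill.
#'
#' @param dose Target drug dose (mg).
#' @param loading_fraction Drug loading in the filament (w/w, in (0, 1]; the
#'   value 1 is the pure-drug limit).
#' @param density Filament density (g/cm^3).
#' @param diameter_mm Tablet diameter (mm).
#' @return List with `tablet_mass_mg`, `volume_cm3`, `height_mm`.
#' @examples
#' design_tablet(15, 0.027, 1.25, 12) # ~556 mg, ~3.93 mm tall
#' @export
design_tablet <- function(dose, loading_fraction, density, diameter_mm) {
  check_positive_scalar(dose, "dose")
  check_positive_scalar(density, "density")
  check_positive_scalar(diameter_mm, "diameter_mm")
  if (!is.numeric(loading_fraction) || length(loading_fraction) != 1L ||
      loading_fraction <= 0 || loading_fraction > 1) {
    stop_domain("`loading_fraction` must lie in (0, 1]")
  }
  mass_mg <- dose / loading_fraction
  volume_cm3 <- (mass_mg / 1000) / density
  r_cm <- diameter_mm / 20
  height_mm <- volume_cm3 / (pi * r_cm^2) * 10
  list(tablet_mass_mg = mass_mg, volume_cm3 = volume_cm3, height_mm = height_mm)
}
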