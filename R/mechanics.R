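#' Profilometry height trace
#'
#' @param positions Positions along the sampling length (mm), increasing.
#' @param heights Surface heights (um), >= 10 points.
#' @return Object of class `roughness_profile`.
#' @export
roughness_profile <- function(positions, heights) {
  if (length(positions) != length(heights)) stop_domain("lengths differ")
  if (length(heights) < 10L) stop_domain("need at least 10 points")
  if (any(diff(positions) <= 0)) stop_domain("`positions` must be increasing")
  structure(list(positions = as.numeric(positions), heights = as.numeric(heights)),
            class = "roughness_profile")
}

profile_heights <- function(p, min_points = 2L) {
  z <- if (inherits(p, "roughness_profile")) p$heights else as.numeric(p)
  if (length(z) < min_points) stop_domain("need at least ", min_points, " height points")
  z
}

#' Arithmetic average roughness Rav
#'
#' Mean absolute deviation of the heights from their mean, computed over the
#' whole sampling length.
#'
#' @param p A [roughness_profile()] or a numeric height vector (um).
#' @return Rav in um.
#' @examples
#' average_roughness(c(1, -1, 1, -1)) # 1
#' @export
average_roughness <- function(p) {
  z <- profile_heights(p)
  mean(abs(z - mean(z)))
}

#' Maximum height of the profile Rz
#'
#' Absolute vertical distance between the maximum peak height and the
#' maximum valley depth over the whole sampling length (not per
#' sub-lengths).
#'
#' @inheritParams average_roughness
#' @return Rz in um.
#' @export
max_height <- function(p) {
  z <- profile_heights(p)
  max(z) - min(z)
}

#' Three-point-bend force-travel curve
#'
#' @param travel Probe travel (mm), non-decreasing, starting at 0.
#' @param force Force at each travel point, in `unit`.
#' @param unit `"N"` (default) or `"mN"`; forces are normalised to N.
#' @return Object of class `force_curve` with forces in N.
#' @export
force_curve <- function(travel, force, unit = c("N", "mN")) {
  unit <- match.arg(unit)
  if (length(travel) != length(force)) stop_domain("lengths differ")
  if (travel[1] != 0) stop_domain("`travel` must start at 0")
  if (any(diff(travel) < 0)) stop_domain("`travel` must be non-decreasing")
  f <- if (unit == "mN") force / 1000 else force
  structure(list(travel = as.numeric(travel), force = as.numeric(f)),
            class = "force_curve")
}

#' Bending modulus from the initial linear region
#'
#' The bending modulus is the gradient of the initial linear section of the
#' force-travel curve. The linear region is delimited by greedy prefix
#' growth: starting from the shortest prefix covering at least
#' `linear_fraction` of the maximum travel (and >= 5 points), points are
#' added one at a time while the ordinary least-squares fit of the prefix
#' keeps R^2 >= `r2_threshold`; the slope of the last accepted prefix is
#' returned. If even the initial prefix fails the R^2 criterion, the slope
#' over that initial prefix is returned with a warning.
#'
#' @param fc A [force_curve()].
#' @param linear_fraction Minimum fraction of the travel range the linear
#'   region must cover (default 0.15).
#' @param r2_threshold R^2 guard for accepting a longer prefix. The default
#'   0.999 keeps the detected window from creeping past the yield point on
#'   smooth curves (a looser guard admits a systematic slice of post-yield
#'   points and biases the slope low); lower it for noisy records where an
#'   exact-linearity guard would reject everything.
#' @return Slope in N per mm (the N mm gradient convention of three-point
#'   bend reports), with attributes `window_end` (travel at the end of the
#'   detected region) and `n_points`.
#' @export
bending_modulus <- function(fc, linear_fraction = 0.15, r2_threshold = 0.999) {
  stopifnot(inherits(fc, "force_curve"))
  x <- fc$travel
  y <- fc$force
  n <- length(x)
  if (n < 5L) stop_domain("need at least 5 points")
  m0 <- max(5L, which(x >= linear_fraction * max(x))[1])
  if (is.na(m0) || m0 > n) m0 <- n
  prefix_r2 <- function(m) {
    fit <- lm(y[1:m] ~ x[1:m])
    as.numeric(r_squared(y[1:m], fitted(fit)))
  }
  if (prefix_r2(m0) < r2_threshold) {
    warning("no prefix meets the R^2 criterion; using the first linear_fraction of travel")
    m <- m0
  } else {
    m <- m0
    while (m < n && prefix_r2(m + 1L) >= r2_threshold) m <- m + 1L
  }
  fit <- lm(y[1:m] ~ x[1:m])
  structure(unname(coef(fit)[2]), window_end = x[m], n_points = m)
}

#' Toughness as the area under the force-travel curve
#'
#' Trapezoidal area under the full force-travel record.
#'
#' @param fc A [force_curve()].
#' @return Area in N mm.
#' @export
toughness <- function(fc) {
  stopifnot(inherits(fc, "force_curve"))
  pracma::trapz(fc$travel, fc$force)
}
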