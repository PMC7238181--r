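#' Material with a role in the loading system
#'
#' A material is a named drug, solvent or filament carrying its Hansen
#' parameters and, where relevant, saturation solubilities (drugs) or a
#' density (filaments).
#'
#' @param name Material identifier.
#' @param role One of `"drug"`, `"solvent"`, `"filament"`.
#' @param hsp A [hansen()] object (or numeric triple).
#' @param saturation_solubility Optional named numeric vector mapping solvent
#'   name to the drug's saturation solubility in that solvent (mg/cm^3).
#' @param density Optional density (g/cm^3), meaningful for filaments.
#' @return An object of class `material`.
#' @export
material <- function(name, role = c("drug", "solvent", "filament"), hsp,
                     saturation_solubility = NULL, density = NULL) {
  role <- match.arg(role)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_domain("`name` must be a non-empty string")
  }
  if (!is.null(saturation_solubility)) {
    if (is.null(names(saturation_solubility)) || any(saturation_solubility <= 0)) {
      stop_domain("`saturation_solubility` must be a named vector of positive values")
    }
  }
  if (!is.null(density)) check_positive_scalar(density, "density")
  structure(
    list(
      name = name, role = role, hsp = as_hansen(hsp),
      saturation_solubility = saturation_solubility, density = density
    ),
    class = "material"
  )
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s (%s)\n", x$name, x$role))
  print(x$hsp)
  invisible(x)
}

#' Reference HSP table for the nifedipine case study
#'
#' Bundled reference descriptors for the package's worked case study:
#' nifedipine (NFD), the two food-grade loading solvents (ethanol, ethyl
#' acetate) and four commercial FDM filaments (PVA, Hydrosupport HS, PLA,
#' TPU). Columns hold the tabulated partial parameters together with the
#' published total HSP and NFD-distance values for cross-checking; the
#' package always recomputes totals and distances from the partial
#' parameters.
#'
#' @return A tibble with columns `material`, `role`, `delta_d`, `delta_p`,
#'   `delta_h`, `total_published`, `ra_nfd_published` (MPa^1/2).
#' @export
nfd_reference_hsp <- function() {
  tibble::tibble(
    material = c("NFD", "ethanol", "ethyl acetate", "PVA", "HS", "PLA", "TPU"),
    role = c("drug", "solvent", "solvent", rep("filament", 4)),
    delta_d = c(16.6, 15.8, 15.8, 15.0, 15.1, 18.6, 18.1),
    delta_p = c(2.4, 8.8, 5.3, 17.2, 16.9, 9.9, 9.3),
    delta_h = c(7.4, 19.4, 7.2, 17.8, 18.1, 6.0, 4.5),
    total_published = c(18.3, 26.5, 18.1, 28.9, 29.0, 21.9, 20.8),
    ra_nfd_published = c(NA, 13.7, 3.3, 18.4, 18.3, 8.6, 8.1)
  )
}

#' Reference materials for the nifedipine case study
#'
#' The [nfd_reference_hsp()] rows as a named list of [material()] objects.
#' The drug carries its saturation solubilities (31.6 mg/cm^3 in ethanol,
#' 71.2 mg/cm^3 in ethyl acetate); filaments carry the nominal density
#' 1.25 g/cm^3.
#'
#' @return Named list of `material` objects.
#' @export
nfd_reference_materials <- function() {
  ref <- nfd_reference_hsp()
  out <- lapply(seq_len(nrow(ref)), function(i) {
    material(
      name = ref$material[i], role = ref$role[i],
      hsp = hansen(ref$delta_d[i], ref$delta_p[i], ref$delta_h[i]),
      saturation_solubility = if (ref$role[i] == "drug") {
        c("ethanol" = 31.6, "ethyl acetate" = 71.2)
      },
      density = if (ref$role[i] == "filament") 1.25
    )
  })
  setNames(out, ref$material)
}

#' Reference flux table for the nifedipine case study
#'
#' Published steady-state flux of NFD into each filament over the 0-4 h
#' loading window, by solvent, with the derived permeability and
#' ethanol/ethyl-acetate enhancement ratio.
#'
#' @return A tibble with columns `solvent`, `filament`, `jss` (mg/cm^2/h),
#'   `permeability_1e3` (10^-3 cm/h) and `er` (dimensionless; `NA` for the
#'   ethyl-acetate rows where the ratio is not applicable).
#' @export
nfd_flux_reference <- function() {
  tibble::tibble(
    solvent = rep(c("ethanol", "ethyl acetate"), each = 4),
    filament = rep(c("PVA", "PLA", "TPU", "HS"), 2),
    jss = c(0.278, 0.064, 0.203, 0.276, 0.115, 0.126, 0.126, 0.046),
    permeability_1e3 = c(8.794, 2.044, 6.424, 8.744, 1.615, 1.771, 1.771, 0.652),
    er = c(2.4, 0.5, 1.6, 5.9, NA, NA, NA, NA)
  )
}

#' Reference mechanical descriptors for the blank filaments
#'
#' Published surface roughness and three-point-bend descriptors of the four
#' commercial filaments as purchased (blank, before loading).
#'
#' @return A tibble with columns `filament`, `roughness_rav` (um), `rz` (um),
#'   `bending_modulus` (N mm) and `toughness` (N mm, area under the
#'   force-travel curve).
#' @export
nfd_mechanics_reference <- function() {
  tibble::tibble(
    filament = c("HS", "PVA", "PLA", "TPU"),
    roughness_rav = c(2.99, 1.84, 2.79, 2.24),
    rz = c(15.2, 13.05, 15.39, 14.58),
    bending_modulus = c(7.86, 7.11, 6.84, 0.72),
    toughness = c(141.80, 130.82, 157.50, 12.26)
  )
}

#' Default accelerated-stability study design
#'
#' The six temperature/relative-humidity conditions of the accelerated
#' stability study, each sampled at days 14, 28 and 48.
#'
#' @return A tibble with columns `temp_c`, `rh` and a list-column `days`.
#' @export
stability_conditions_default <- function() {
  tibble::tibble(
    temp_c = c(80, 80, 70, 70, 60, 50),
    rh = c(75, 10, 50, 10, 75, 50),
    days = rep(list(c(14, 28, 48)), 6)
  )
}
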