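#' Hansen solubility parameter triple
#'
#' Construct a Hansen solubility parameter (HSP) object holding the
#' dispersion (`delta_d`), polar (`delta_p`) and hydrogen-bonding (`delta_h`)
#' components, all in MPa^1/2. The total parameter `delta_t` is derived as the
#' Euclidean norm of the triple.
#'
#' @param delta_d,delta_p,delta_h Non-negative finite components (MPa^1/2).
#' @param source Either `"tabulated"` (taken from a reference compilation) or
#'   `"group_contribution"` (estimated by [estimate_hsp_from_groups()]).
#' @return An object of class `hansen`: a list with fields `delta_d`,
#'   `delta_p`, `delta_h`, `delta_t` and `source`.
#' @examples
#' hansen(16.6, 2.4, 7.4)$delta_t # 18.33
#' @export
hansen <- function(delta_d, delta_p, delta_h, source = c("tabulated", "group_contribution")) {
  source <- match.arg(source)
  structure(
    list(
      delta_d = delta_d, delta_p = delta_p, delta_h = delta_h,
      delta_t = total_hsp(delta_d, delta_p, delta_h),
      source = source
    ),
    class = "hansen"
  )
}

#' @export
print.hansen <- function(x, ...) {
  cat(sprintf(
    "Hansen parameters (MPa^1/2): delta_d = %.2f, delta_p = %.2f, delta_h = %.2f, delta_t = %.2f [%s]\n",
    x$delta_d, x$delta_p, x$delta_h, x$delta_t, x$source
  ))
  invisible(x)
}

as_hansen <- function(x) {
  if (inherits(x, "hansen")) return(x)
  if (is.numeric(x) && length(x) == 3L) return(hansen(x[[1]], x[[2]], x[[3]]))
  stop_domain("expected a `hansen` object or a numeric triple (delta_d, delta_p, delta_h)")
}

check_hsp_components <- function(...) {
  vals <- c(...)
  if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals < 0)) {
    stop_domain("HSP components must be finite and non-negative")
  }
  invisible(vals)
}

#' Total Hansen solubility parameter
#'
#' The total cohesive parameter is the Euclidean norm of the three partial
#' parameters: `delta_t = sqrt(delta_d^2 + delta_p^2 + delta_h^2)`.
#'
#' @inheritParams hansen
#' @return Total HSP in MPa^1/2.
#' @examples
#' total_hsp(3, 4, 0) # 5
#' @export
total_hsp <- function(delta_d, delta_p, delta_h) {
  check_hsp_components(delta_d, delta_p, delta_h)
  sqrt(delta_d^2 + delta_p^2 + delta_h^2)
}

#' HSP distance between two materials
#'
#' Scaled Euclidean distance in Hansen space,
#' `Ra = sqrt(4 (delta_d1 - delta_d2)^2 + (delta_p1 - delta_p2)^2 +
#' (delta_h1 - delta_h2)^2)`. The factor 4 on the dispersion term is the
#' standard Hansen convention. Smaller Ra predicts greater miscibility.
#'
#' @param hsp_1,hsp_2 `hansen` objects (or numeric triples).
#' @return Ra in MPa^1/2; symmetric in its arguments.
#' @examples
#' nfd <- hansen(16.6, 2.4, 7.4)
#' ethanol <- hansen(15.8, 8.8, 19.4)
#' ra_distance(nfd, ethanol) # 13.69
#' @export
ra_distance <- function(hsp_1, hsp_2) {
  a <- as_hansen(hsp_1)
  b <- as_hansen(hsp_2)
  sqrt(4 * (a$delta_d - b$delta_d)^2 +
    (a$delta_p - b$delta_p)^2 +
    (a$delta_h - b$delta_h)^2)
}

#' Bundled group-contribution table
#'
#' Functional-group molar attraction constants and molar-volume increments for
#' estimating HSP by the Hoftyzer-van Krevelen group-contribution scheme.
#' Columns: `group`, `f_d` (dispersion molar attraction, MPa^1/2 cm^3/mol),
#' `f_p` (polar molar attraction, MPa^1/2 cm^3/mol), `e_h` (hydrogen-bond
#' cohesive energy, J/mol) and `v` (molar volume increment, cm^3/mol; positive
#' Fedors-style additive increments).
#'
#' @return A tibble with one row per functional group.
#' @export
vk_group_table <- function() {
  path <- system.file("extdata", "van_krevelen_groups.tsv", package = "filadose")
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (anyDuplicated(tab$group)) stop_domain("group-contribution table has duplicate group names")
  if (any(tab$v <= 0)) stop_domain("group-contribution table has non-positive molar volume increments")
  tibble::as_tibble(tab)
}

#' Estimate HSP by group contribution
#'
#' Hoftyzer-van Krevelen estimation from functional-group counts:
#' `delta_d = sum(n F_d) / V`, `delta_p = sqrt(sum(n F_p^2)) / V`,
#' `delta_h = sqrt(sum(n E_h) / V)`, with `V = sum(n v)` unless overridden.
#'
#' @param groups Named numeric vector of group counts, e.g.
#'   `c(CH3 = 1, CH2 = 1, OH = 1)` for ethanol.
#' @param table Group-contribution table as returned by [vk_group_table()].
#' @param molar_volume Optional molar volume override (cm^3/mol); by default
#'   the additive sum of the group volume increments is used.
#' @return A `hansen` object with `source = "group_contribution"`.
#' @examples
#' estimate_hsp_from_groups(c(CH3 = 1, CH2 = 1, OH = 1))
#' @export
estimate_hsp_from_groups <- function(groups, table = vk_group_table(), molar_volume = NULL) {
  if (length(groups) == 0L || is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop_domain("`groups` must be a non-empty named vector of group counts")
  }
  if (any(groups < 0) || sum(groups) < 1) {
    stop_domain("group counts must be non-negative with total count >= 1")
  }
  unknown <- setdiff(names(groups), table$group)
  if (length(unknown) > 0L) {
    stop_domain("unknown group(s): ", paste(unknown, collapse = ", "))
  }
  idx <- match(names(groups), table$group)
  n <- as.numeric(groups)
  v <- if (is.null(molar_volume)) sum(n * table$v[idx]) else molar_volume
  if (!is.finite(v) || v <= 0) stop_domain("molar volume must be positive")
  delta_d <- sum(n * table$f_d[idx]) / v
  delta_p <- sqrt(sum(n * table$f_p[idx]^2)) / v
  delta_h <- sqrt(sum(n * table$e_h[idx]) / v)
  hansen(delta_d, delta_p, delta_h, source = "group_contribution")
}
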