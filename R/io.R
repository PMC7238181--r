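#' Read and validate a delimited table
#'
#' Strict CSV ingest: comma-separated, UTF-8, `.` decimal, mandatory header.
#' Columns named in `schema` must be present and parse to the declared type;
#' extra columns are accepted with a warning. Parse failures are reported
#' with row and column coordinates.
#'
#' @param path File path.
#' @param schema Named character vector mapping required column name to type
#'   (`"numeric"` or `"character"`).
#' @return Tibble with the schema columns coerced, extra columns untouched.
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(names(schema), names(raw))
  if (length(missing_cols)) {
    stop_domain("missing column(s) in ", basename(path), ": ",
                paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(raw), names(schema))
  if (length(extra)) {
    warning("ignoring extra column(s) in ", basename(path), ": ",
            paste(extra, collapse = ", "))
  }
  for (col in names(schema)) {
    if (schema[[col]] == "numeric") {
      parsed <- suppressWarnings(as.numeric(raw[[col]]))
      bad <- which(is.na(parsed) & nzchar(trimws(raw[[col]])))
      if (length(bad)) {
        stop_domain(sprintf("unparseable cell at row %d, column '%s' in %s: '%s'",
                            bad[1], col, basename(path), raw[[col]][bad[1]]))
      }
      raw[[col]] <- parsed
    }
  }
  tibble::as_tibble(raw)
}

#' Read a drug-loading time-course CSV
#'
#' Expected columns: `time_h`, `replicate`, `cumulative_mg`.
#'
#' @param path File path.
#' @param geometry A [filament_geometry()].
#' @param solvent,filament Optional names.
#' @return A [diffusion_timecourse()].
#' @export
read_timecourse_csv <- function(path, geometry = filament_geometry(),
                                solvent = NA_character_, filament = NA_character_) {
  tab <- read_table(path, c(time_h = "numeric", replicate = "character",
                            cumulative_mg = "numeric"))
  times <- sort(unique(tab$time_h))
  reps <- unique(tab$replicate)
  m <- matrix(NA_real_, length(times), length(reps),
              dimnames = list(NULL, reps))
  for (i in seq_len(nrow(tab))) {
    m[match(tab$time_h[i], times), tab$replicate[i]] <- tab$cumulative_mg[i]
  }
  if (anyNA(m)) stop_domain("time-course is not complete across replicates")
  diffusion_timecourse(times, m, geometry = geometry,
                       solvent = solvent, filament = filament)
}

#' Read a dissolution CSV
#'
#' Expected columns: `time_h`, `released_pct` (or `released_mg`).
#'
#' @param path File path.
#' @param q_inf Total drug in the dosage form (mg).
#' @inheritParams dissolution_profile
#' @return A [dissolution_profile()].
#' @export
read_dissolution_csv <- function(path, q_inf, geometry = "cylinder",
                                 medium_switch_time = NULL) {
  header <- names(read.csv(path, nrows = 1, check.names = FALSE))
  if ("released_pct" %in% header) {
    tab <- read_table(path, c(time_h = "numeric", released_pct = "numeric"))
    dissolution_profile(tab$time_h, tab$released_pct, q_inf, unit = "percent",
                        geometry = geometry, medium_switch_time = medium_switch_time)
  } else {
    tab <- read_table(path, c(time_h = "numeric", released_mg = "numeric"))
    dissolution_profile(tab$time_h, tab$released_mg, q_inf, unit = "mg",
                        geometry = geometry, medium_switch_time = medium_switch_time)
  }
}

#' Read a stability-study CSV
#'
#' Expected columns: `temp_c`, `rh_pct`, `day`, `percent_remaining`. Rows are
#' grouped into one [stability_condition()] per (temp_c, rh_pct).
#'
#' @param path File path.
#' @return List of `stability_condition` objects.
#' @export
read_stability_csv <- function(path) {
  tab <- read_table(path, c(temp_c = "numeric", rh_pct = "numeric",
                            day = "numeric", percent_remaining = "numeric"))
  keys <- unique(tab[, c("temp_c", "rh_pct")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- tab[tab$temp_c == keys$temp_c[i] & tab$rh_pct == keys$rh_pct[i], ]
    sub <- sub[order(sub$day), ]
    stability_condition(keys$temp_c[i], keys$rh_pct[i], sub$day,
                        sub$percent_remaining, convention = "remaining")
  })
}

#' Read profilometry and force-curve CSVs
#'
#' Profilometry columns: `position_mm`, `height_um`. Force columns:
#' `travel_mm`, `force_N`.
#'
#' @param path File path.
#' @return A [roughness_profile()] / [force_curve()].
#' @export
read_profilometry_csv <- function(path) {
  tab <- read_table(path, c(position_mm = "numeric", height_um = "numeric"))
  roughness_profile(tab$position_mm, tab$height_um)
}

#' @rdname read_profilometry_csv
#' @export
read_force_csv <- function(path) {
  tab <- read_table(path, c(travel_mm = "numeric", force_N = "numeric"))
  force_curve(tab$travel_mm, tab$force_N, unit = "N")
}

#' Write a run report as JSON
#'
#' @param report A [run_pipeline()] report (or any list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Run the full design pipeline
#'
#' Executes the enabled stages in dependency order: HSP screen, flux
#' estimation, mechanics, predictive model (which needs the first three),
#' with dissolution and stability as independent branches. A stage is
#' enabled by supplying its inputs in `config`; failure of one branch is
#' recorded and does not abort the others.
#'
#' @param config A list with any of:
#'   \describe{
#'     \item{materials}{named list of [material()] objects (with exactly one
#'       drug) enabling the screen stage; optional `thresholds` list with
#'       `t_high`, `t_mid`, `width`.}
#'     \item{timecourses}{list of lists with fields `tc` (a
#'       [diffusion_timecourse()]), `solvent`, `filament`, `csat`; optional
#'       `window`.}
#'     \item{mechanics}{list of lists with fields `filament`, `profile`
#'       (roughness profile), `force` (force curve).}
#'     \item{dissolution}{list of lists with fields `profile`
#'       (a [dissolution_profile()]) and optional `label`.}
#'     \item{stability}{list with `conditions` (list of
#'       [stability_condition()]), optional `storage_temp_c`, `storage_rh`,
#'       `limit`.}
#'     \item{model}{logical; fit the flux model from the screen + flux +
#'       mechanics outputs.}
#'     \item{seed}{seed recorded in provenance (default 1).}
#'   }
#' @return Object of class `run_report`: list with `stages`, `errors`,
#'   `provenance`.
#' @export
run_pipeline <- function(config) {
  stages <- list()
  errors <- list()
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[name]] <<- conditionMessage(res)
    } else {
      stages[[name]] <<- res
    }
  }

  if (!is.null(config$materials)) {
    run_stage("screen", {
      mats <- config$materials
      roles <- vapply(mats, function(m) m$role, character(1))
      drug <- mats[[which(roles == "drug")[1]]]
      th <- config$thresholds %||% list()
      screen_combinations(drug, mats[roles == "solvent"], mats[roles == "filament"],
                          t_high = th$t_high %||% 10, t_mid = th$t_mid %||% 10,
                          width = th$width %||% 3)
    })
  }
  if (!is.null(config$timecourses)) {
    run_stage("flux", {
      rows <- lapply(config$timecourses, function(item) {
        est <- fit_steady_state_flux(item$tc, window = item$window %||% c(0, 4))
        tibble::tibble(
          solvent = item$solvent, filament = item$filament,
          jss = est$jss, r_squared = est$r_squared,
          permeability = permeability(est$jss, item$csat),
          jss_unit = "mg/cm^2/h", permeability_unit = "cm/h"
        )
      })
      do.call(rbind, rows)
    })
  }
  if (!is.null(config$mechanics)) {
    run_stage("mechanics", {
      rows <- lapply(config$mechanics, function(item) {
        tibble::tibble(
          filament = item$filament,
          roughness_rav = average_roughness(item$profile),
          rz = max_height(item$profile),
          bending_modulus = as.numeric(bending_modulus(item$force)),
          toughness = toughness(item$force),
          roughness_unit = "um", modulus_unit = "N/mm", toughness_unit = "N mm"
        )
      })
      do.call(rbind, rows)
    })
  }
  if (!is.null(config$dissolution)) {
    run_stage("dissolution", {
      lapply(config$dissolution, function(item) {
        fits <- fit_release_models(item$profile)
        best <- select_best_model(fits)
        list(label = item$label %||% NA_character_, best = best, fits = fits)
      })
    })
  }
  if (!is.null(config$stability)) {
    run_stage("stability", {
      st <- config$stability
      per_cond <- lapply(st$conditions, function(cond) {
        best <- fit_degradation(cond)[[1]]
        list(temp_k = cond$temp_k, rh = cond$rh, fit = best)
      })
      models <- vapply(per_cond, function(p) p$fit$model, character(1))
      consensus <- names(sort(table(models), decreasing = TRUE))[1]
      rates <- do.call(rbind, lapply(st$conditions, function(cond) {
        fits <- fit_degradation(cond, models = consensus)
        data.frame(temp_k = cond$temp_k, rh = cond$rh, k = as.numeric(fits[[1]]$k))
      }))
      af <- fit_arrhenius(rates)
      shelf <- predict_shelf_life(
        af, model = consensus,
        storage_temp_c = st$storage_temp_c %||% 25,
        storage_rh = st$storage_rh %||% 60,
        limit = st$limit %||% 10
      )
      list(per_condition = per_cond, consensus_model = consensus,
           arrhenius = af, shelf_life = shelf)
    })
  }
  if (isTRUE(config$model)) {
    run_stage("model", {
      if (is.null(stages$screen) || is.null(stages$flux) || is.null(stages$mechanics)) {
        stop_domain("model stage needs screen, flux and mechanics outputs")
      }
      ft <- assemble_feature_table(stages$screen, stages$mechanics, stages$flux)
      list(feature_table = ft, pca = run_pca(ft), svm = fit_flux_model(ft, "svm_rbf"))
    })
  }

  structure(
    list(
      stages = stages, errors = errors,
      provenance = list(package = "filadose",
                        version = as.character(packageVersion("filadose")),
                        seed = config$seed %||% 1)
    ),
    class = "run_report"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> stages:", paste(names(x$stages), collapse = ", "), "\n")
  if (length(x$errors)) {
    cat("failed stages:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}
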