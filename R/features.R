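feature_columns <- function() {
  c("ra_solvent_filament", "roughness_rav", "bending_modulus", "toughness",
    "jss", "permeability")
}

descriptor_columns <- function() {
  c("ra_solvent_filament", "roughness_rav", "bending_modulus", "toughness")
}

#' Assemble the solvent-filament feature table
#'
#' Joins the HSP screen, the mechanical descriptors and the flux estimates
#' into one modelling table with a row per (solvent, filament) combination
#' and the six modelling variables: solvent-filament Ra, average roughness,
#' bending modulus, toughness (the stiffness input, taken as the area under
#' the force-travel curve), steady-state flux and permeability. Mechanical
#' descriptors are per blank filament and are shared by both solvents.
#'
#' @param screen Tibble from [screen_combinations()] (needs `solvent`,
#'   `filament`, `ra_solvent_filament`).
#' @param mechanics Tibble with columns `filament`, `roughness_rav`,
#'   `bending_modulus`, `toughness` (e.g. [nfd_mechanics_reference()]).
#' @param flux Tibble with columns `solvent`, `filament`, `jss` and either
#'   `permeability` (cm/h) or `permeability_1e3` (10^-3 cm/h).
#' @return Tibble keyed by (solvent, filament) with the six feature columns,
#'   sorted by (solvent, filament).
#' @export
assemble_feature_table <- function(screen, mechanics, flux) {
  flux <- tibble::as_tibble(flux)
  if (!"permeability" %in% names(flux)) {
    if (!"permeability_1e3" %in% names(flux)) {
      stop_domain("`flux` needs a `permeability` or `permeability_1e3` column")
    }
    flux$permeability <- flux$permeability_1e3 / 1000
  }
  out <- flux[, c("solvent", "filament", "jss", "permeability")]
  key <- function(s, f) paste(s, f, sep = "\r")
  si <- match(key(out$solvent, out$filament), key(screen$solvent, screen$filament))
  if (anyNA(si)) {
    bad <- paste(out$solvent[is.na(si)], out$filament[is.na(si)], sep = "/")
    stop_domain("combination(s) missing from screen results: ", paste(bad, collapse = ", "))
  }
  mi <- match(out$filament, mechanics$filament)
  if (anyNA(mi)) {
    stop_domain("filament(s) missing from mechanics table: ",
                paste(unique(out$filament[is.na(mi)]), collapse = ", "))
  }
  out$ra_solvent_filament <- screen$ra_solvent_filament[si]
  out$roughness_rav <- mechanics$roughness_rav[mi]
  out$bending_modulus <- mechanics$bending_modulus[mi]
  out$toughness <- mechanics$toughness[mi]
  out <- out[order(out$solvent, out$filament),
             c("solvent", "filament", feature_columns())]
  if (anyNA(out[feature_columns()])) stop_domain("feature table has missing cells")
  tibble::as_tibble(out)
}

#' Feature table for the nifedipine case study
#'
#' Convenience constructor of the eight-row (two solvents x four filaments)
#' feature table from the bundled reference descriptors, with
#' solvent-filament Ra recomputed from the tabulated Hansen parameters.
#'
#' @return Tibble as from [assemble_feature_table()].
#' @export
nfd_feature_table <- function() {
  mats <- nfd_reference_materials()
  screen <- screen_combinations(
    mats$NFD, mats[c("ethanol", "ethyl acetate")],
    mats[c("PVA", "HS", "PLA", "TPU")]
  )
  assemble_feature_table(screen, nfd_mechanics_reference(), nfd_flux_reference())
}

#' Principal component analysis with correlation loadings
#'
#' PCA on the (by default standardised) feature columns. Correlation
#' loadings are the Pearson correlations of each original variable with each
#' score vector and are the standard way to read variable-component
#' relationships on a unit circle.
#'
#' @param ft Feature table (tibble with the six feature columns, or any
#'   all-numeric table).
#' @param standardise Scale columns to unit variance (default TRUE).
#' @return Object of class `filadose_pca` with `scores`, `loadings`
#'   (orthonormal rotation), `correlation_loadings` and
#'   `explained_variance` (fractions, non-increasing).
#' @export
run_pca <- function(ft, standardise = TRUE) {
  x <- as.data.frame(ft)
  x <- x[, vapply(x, is.numeric, logical(1)), drop = FALSE]
  if (nrow(x) < 3L) stop_domain("need at least 3 rows")
  sds <- vapply(x, sd, numeric(1))
  if (any(sds == 0)) {
    stop_domain("zero-variance column(s): ", paste(names(sds)[sds == 0], collapse = ", "))
  }
  pc <- prcomp(x, center = TRUE, scale. = standardise)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(scores = pc$x, loadings = pc$rotation,
         correlation_loadings = cor(as.matrix(x), pc$x),
         explained_variance = ev),
    class = "filadose_pca"
  )
}

#' @export
print.filadose_pca <- function(x, ...) {
  cat("PCA:", length(x$explained_variance), "components; explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "), "\n")
  invisible(x)
}

loo_r2 <- function(x, y, fit_fn) {
  n <- length(y)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    m <- fit_fn(x[-i, , drop = FALSE], y[-i])
    pred[i] <- predict(m, x[i, , drop = FALSE])
  }
  ss_tot <- sum((y - mean(y))^2)
  1 - sum((y - pred)^2) / ss_tot
}

#' Default SVM tuning grid
#'
#' @return Data frame of (cost, gamma, epsilon) combinations searched by
#'   [fit_flux_model()].
#' @export
svm_tuning_grid <- function() {
  expand.grid(cost = c(0.1, 1, 10, 100),
              gamma = c(0.01, 0.1, 0.5, 1, 2),
              epsilon = c(0.001, 0.01, 0.05))
}

#' Fit a regression model of steady-state flux on material descriptors
#'
#' Regresses `jss` on the four material descriptors (solvent-filament Ra,
#' roughness, bending modulus, toughness). Three methods are available:
#' multiple linear regression (`"mlr"`), partial least squares (`"pls"`,
#' NIPALS via mixOmics) and epsilon-insensitive support vector regression
#' with a radial-basis kernel (`"svm_rbf"`). Features are standardised
#' before fitting.
#'
#' For `svm_rbf` the hyperparameters are chosen by exhaustive grid search
#' (see [svm_tuning_grid()]) maximising leave-one-out R^2, then the model is
#' refit on all rows. With only a handful of rows LOO R^2 is frequently
#' negative for every grid point (each held-out row is an extrapolation for
#' the remaining rows), in which case the grid point maximising training R^2
#' is used instead; the reported fit statistics are training-set values
#' either way, and `tuning_criterion` in the result records which rule
#' applied.
#'
#' @param ft Feature table (from [assemble_feature_table()]).
#' @param method `"svm_rbf"` (default), `"mlr"` or `"pls"`.
#' @param features Descriptor column names (default the four material
#'   descriptors).
#' @param target Target column (default `"jss"`).
#' @param grid Tuning grid for `svm_rbf` (default [svm_tuning_grid()]).
#' @param pls_ncomp Number of PLS components (default 2; must be < rows).
#' @return Object of class `flux_model` with `method`, `hyperparameters`,
#'   `r_squared` and `rmse` (training set), `predictions`, and the fitted
#'   model object.
#' @export
fit_flux_model <- function(ft, method = c("svm_rbf", "mlr", "pls"),
                           features = descriptor_columns(), target = "jss",
                           grid = svm_tuning_grid(), pls_ncomp = 2) {
  method <- match.arg(method)
  ft <- as.data.frame(ft)
  missing_cols <- setdiff(c(features, target), names(ft))
  if (length(missing_cols)) stop_domain("missing column(s): ", paste(missing_cols, collapse = ", "))
  x <- as.matrix(ft[, features, drop = FALSE])
  y <- ft[[target]]
  n <- nrow(x)
  if (n < 3L) stop_domain("need at least 3 rows")

  hyper <- list()
  tuning_criterion <- NA_character_
  if (sd(y) == 0) {
    # degenerate target: every sensible regressor predicts the constant
    return(structure(
      list(method = method, hyperparameters = hyper,
           tuning_criterion = "constant_target",
           r_squared = 1, rmse = 0,
           predictions = y, observed = y,
           features = features, target = target,
           model = list(constant = y[1]), pls_ncomp = NA_integer_),
      class = "flux_model"
    ))
  }
  if (method == "mlr") {
    dat <- data.frame(y = y, x)
    model <- lm(y ~ ., data = dat)
    preds <- unname(predict(model, dat))
  } else if (method == "pls") {
    if (pls_ncomp >= n) stop_domain("`pls_ncomp` must be smaller than the number of rows")
    model <- mixOmics::pls(x, y, ncomp = pls_ncomp, mode = "regression", scale = TRUE)
    preds <- as.numeric(predict(model, x)$predict[, 1, pls_ncomp])
    hyper <- list(ncomp = pls_ncomp)
  } else {
    fit_svm <- function(xx, yy, row) {
      e1071::svm(xx, yy, type = "eps-regression", kernel = "radial",
                 cost = row$cost, gamma = row$gamma, epsilon = row$epsilon,
                 scale = TRUE)
    }
    train_r2 <- function(row) {
      m <- fit_svm(x, y, row)
      as.numeric(r_squared(y, predict(m, x)))
    }
    loo_scores <- vapply(seq_len(nrow(grid)), function(i) {
      row <- grid[i, ]
      loo_r2(x, y, function(xx, yy) fit_svm(xx, yy, row))
    }, numeric(1))
    if (max(loo_scores) > 0) {
      best_i <- which.max(loo_scores)
      tuning_criterion <- "loo_r2"
    } else {
      train_scores <- vapply(seq_len(nrow(grid)), function(i) train_r2(grid[i, ]), numeric(1))
      best_i <- which.max(train_scores)
      tuning_criterion <- "training_r2_fallback"
    }
    hyper <- as.list(grid[best_i, ])
    hyper$loo_r2 <- loo_scores[best_i]
    model <- fit_svm(x, y, grid[best_i, ])
    preds <- unname(predict(model, x))
  }
  structure(
    list(
      method = method, hyperparameters = hyper,
      tuning_criterion = tuning_criterion,
      r_squared = as.numeric(r_squared(y, preds)),
      rmse = sqrt(mean((y - preds)^2)),
      predictions = preds, observed = y,
      features = features, target = target, model = model,
      pls_ncomp = if (method == "pls") pls_ncomp else NA_integer_
    ),
    class = "flux_model"
  )
}

#' @export
print.flux_model <- function(x, ...) {
  cat(sprintf("<flux_model> %s: training R^2 = %.4f, RMSE = %.4g", x$method,
              x$r_squared, x$rmse))
  if (x$method == "svm_rbf") {
    cat(sprintf(" (cost = %g, gamma = %g, epsilon = %g, tuned by %s)",
                x$hyperparameters$cost, x$hyperparameters$gamma,
                x$hyperparameters$epsilon, x$tuning_criterion))
  }
  cat("\n")
  invisible(x)
}

#' Predict steady-state flux for new descriptor rows
#'
#' @param model A [fit_flux_model()] result.
#' @param descriptors Data frame (or named list) containing the model's
#'   descriptor columns.
#' @return Predicted flux on the original scale (mg/cm^2/h).
#' @export
predict_jss <- function(model, descriptors) {
  stopifnot(inherits(model, "flux_model"))
  descriptors <- as.data.frame(descriptors)
  missing_cols <- setdiff(model$features, names(descriptors))
  if (length(missing_cols)) {
    stop_domain("descriptor(s) missing: ", paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(descriptors), c(model$features, model$target,
                                         "solvent", "filament", "permeability"))
  if (length(extra)) {
    stop_domain("unknown descriptor(s): ", paste(extra, collapse = ", "))
  }
  x <- as.matrix(descriptors[, model$features, drop = FALSE])
  if (identical(model$tuning_criterion, "constant_target")) {
    return(rep(model$model$constant, nrow(x)))
  }
  if (model$method == "mlr") {
    unname(predict(model$model, as.data.frame(x)))
  } else if (model$method == "pls") {
    as.numeric(predict(model$model, x)$predict[, 1, model$pls_ncomp])
  } else {
    unname(predict(model$model, x))
  }
}
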