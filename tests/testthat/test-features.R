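test_that("the case-study feature table has eight complete rows", {
  ft <- nfd_feature_table()
  expect_equal(nrow(ft), 8L)
  expect_true(all(c("ra_solvent_filament", "roughness_rav", "bending_modulus",
                    "toughness", "jss", "permeability") %in% names(ft)))
  expect_false(anyNA(ft))
  # single-solvent subset has four rows
  expect_equal(nrow(ft[ft$solvent == "ethanol", ]), 4L)
})

test_that("feature-table assembly is a deterministic join", {
  mats <- nfd_reference_materials()
  screen <- screen_combinations(mats$NFD, mats[c("ethanol", "ethyl acetate")],
                                mats[c("PVA", "HS", "PLA", "TPU")])
  mech <- nfd_mechanics_reference()
  flux <- nfd_flux_reference()
  set.seed(4)
  a <- assemble_feature_table(screen, mech, flux)
  b <- assemble_feature_table(screen[sample(nrow(screen)), ],
                              mech[rev(seq_len(nrow(mech))), ],
                              flux[sample(nrow(flux)), ])
  expect_identical(a, b)
  expect_error(assemble_feature_table(screen[screen$solvent == "ethanol", ], mech, flux),
               "missing from screen")
  expect_error(assemble_feature_table(screen, mech[mech$filament != "TPU", ], flux),
               "TPU")
})

test_that("PCA satisfies its algebraic invariants", {
  ft <- nfd_feature_table()
  p <- run_pca(ft)
  expect_true(all(abs(colMeans(p$scores)) < 1e-10))
  cv <- crossprod(p$scores) / (nrow(p$scores) - 1)
  expect_true(all(abs(cv[upper.tri(cv)]) < 1e-10))
  expect_true(all(diff(p$explained_variance) < 1e-12))
  expect_equal(sum(p$explained_variance), 1, tolerance = 1e-12)
  expect_true(all(abs(p$correlation_loadings) <= 1 + 1e-12))
  # loadings orthonormal
  expect_equal(crossprod(p$loadings), diag(ncol(p$loadings)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("correlation loadings agree with an independent eigendecomposition", {
  ft <- nfd_feature_table()
  x <- as.matrix(ft[, c("ra_solvent_filament", "roughness_rav", "bending_modulus",
                        "toughness", "jss", "permeability")])
  p <- run_pca(ft)
  eig <- eigen(cor(x), symmetric = TRUE)
  xs <- scale(x)
  for (j in 1:2) {
    scores_j <- xs %*% eig$vectors[, j]
    cl_oracle <- cor(x, scores_j)
    # sign of a principal axis is arbitrary
    agree <- min(max(abs(p$correlation_loadings[, j] - cl_oracle)),
                 max(abs(p$correlation_loadings[, j] + cl_oracle)))
    expect_lt(agree, 1e-8)
  }
})

test_that("flux and permeability load opposite to Ra, toughness and bending modulus", {
  p <- run_pca(nfd_feature_table())
  cl <- p$correlation_loadings[, 1]
  material_side <- cl[c("ra_solvent_filament", "toughness", "bending_modulus")]
  flux_side <- cl[c("jss", "permeability")]
  expect_true(all(sign(material_side) == -sign(flux_side[1])))
  expect_true(all(sign(flux_side) == sign(flux_side[1])))
})

test_that("degenerate PCA inputs are reported", {
  ft <- nfd_feature_table()
  ft$toughness <- 1
  expect_error(run_pca(ft), "toughness")
  # rank-1 pair: PC1 carries all the variance
  two <- tibble::tibble(a = c(1, 2, 3, 4), b = 2 * c(1, 2, 3, 4))
  p <- run_pca(two)
  expect_equal(p$explained_variance[1], 1, tolerance = 1e-12)
})

test_that("MLR fits an exactly linear target perfectly", {
  ft <- nfd_feature_table()
  ft$jss <- 0.1 * ft$ra_solvent_filament - 0.02 * ft$bending_modulus + 1
  m <- fit_flux_model(ft, method = "mlr")
  expect_equal(m$r_squared, 1, tolerance = 1e-9)
  expect_lt(m$rmse, 1e-9)
})

test_that("SVM predictions equal the explicit kernel expansion", {
  ft <- nfd_feature_table()
  m <- fit_flux_model(ft, method = "svm_rbf")
  sv <- m$model
  x <- as.matrix(ft[, m$features])
  xs <- scale(x, center = sv$x.scale$`scaled:center`, scale = sv$x.scale$`scaled:scale`)
  manual <- vapply(seq_len(nrow(xs)), function(i) {
    k <- exp(-sv$gamma * colSums((t(sv$SV) - xs[i, ])^2))
    sum(sv$coefs * k) - sv$rho
  }, numeric(1))
  manual <- manual * sv$y.scale$`scaled:scale` + sv$y.scale$`scaled:center`
  expect_equal(unname(m$predictions), manual, tolerance = 1e-8)
})

test_that("flux-model prediction respects the descriptor schema", {
  ft <- nfd_feature_table()
  m <- fit_flux_model(ft, method = "svm_rbf")
  preds <- predict_jss(m, ft)
  # interpolating model reproduces training targets within the epsilon tube
  tube <- m$hyperparameters$epsilon * sd(ft$jss) + 1e-6
  expect_true(all(abs(preds - ft$jss) <= tube + 0.1 * sd(ft$jss)))
  expect_error(predict_jss(m, ft[, c("solvent", "filament")]), "missing")
  bad <- ft; bad$mystery <- 1
  expect_error(predict_jss(m, bad), "unknown descriptor")
})

test_that("constant targets give constant predictions", {
  ft <- nfd_feature_table()
  ft$jss <- 0.2
  m <- suppressWarnings(fit_flux_model(ft, method = "svm_rbf",
                                       grid = data.frame(cost = 1, gamma = 0.5, epsilon = 0.01)))
  expect_true(all(abs(predict_jss(m, ft) - 0.2) < 1e-6))
})

test_that("predictions are invariant to affine rescaling of an input column", {
  ft <- nfd_feature_table()
  grid1 <- data.frame(cost = 10, gamma = 0.5, epsilon = 0.01)
  m1 <- fit_flux_model(ft, method = "svm_rbf", grid = grid1)
  ft2 <- ft
  ft2$toughness <- ft2$toughness * 1000
  m2 <- fit_flux_model(ft2, method = "svm_rbf", grid = grid1)
  expect_equal(unname(m1$predictions), unname(m2$predictions), tolerance = 1e-8)
})

test_that("the tuned SVM outperforms the linear baseline on the case-study table", {
  ft <- nfd_feature_table()
  svm <- fit_flux_model(ft, method = "svm_rbf")
  mlr <- fit_flux_model(ft, method = "mlr")
  expect_gte(svm$r_squared, mlr$r_squared)
  # linear models correlate poorly here, as the case study reports
  expect_lt(mlr$r_squared, 0.5)
})

test_that("PLS fits and predicts with a bounded component count", {
  ft <- nfd_feature_table()
  m <- fit_flux_model(ft, method = "pls", pls_ncomp = 2)
  expect_length(predict_jss(m, ft), nrow(ft))
  expect_true(is.finite(m$r_squared))
  expect_error(fit_flux_model(ft[1:3, ], method = "pls", pls_ncomp = 3), "smaller")
})
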