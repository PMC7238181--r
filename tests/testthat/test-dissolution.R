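test_that("exact zero-order data fits back to its constant with R^2 = 1", {
  prof <- gen_dissolution_profile("zero_order", list(k0 = 2), q_inf = 50,
                                  t_points = 1:6)
  fits <- fit_release_models(prof)
  zero <- fits[[which(vapply(fits, function(f) f$model, "") == "zero_order")]]
  expect_equal(zero$params$k0, 2, tolerance = 1e-10)
  expect_equal(zero$r_squared, 1, tolerance = 1e-12)
  expect_identical(select_best_model(fits)$model, "zero_order")
})

test_that("noiseless Korsmeyer-Peppas data returns its exponent", {
  prof <- gen_dissolution_profile("korsmeyer_peppas", list(k_kp = 0.08, n = 0.439),
                                  q_inf = 15)
  fits <- fit_release_models(prof)
  kp <- fits[[which(vapply(fits, function(f) f$model, "") == "korsmeyer_peppas")]]
  expect_equal(kp$params$n, 0.439, tolerance = 0.01)
  expect_equal(kp$params$k_kp, 0.08, tolerance = 0.01)
  expect_identical(kp$mechanism, "fickian")
})

test_that("the Korsmeyer-Peppas optimiser agrees with a dense grid search", {
  # Oracle: exhaustive SSE evaluation over a (k, n) grid on a small profile
  # with an off-grid optimum.
  t <- c(0.25, 0.5, 1, 2, 4, 8)
  frac <- 0.123 * t^0.517
  prof <- dissolution_profile(t, frac * 15, q_inf = 15, unit = "mg")
  fits <- fit_release_models(prof, models = "korsmeyer_peppas", kp_fraction_cap = 1)
  kp <- fits[[1]]
  ks <- seq(0.05, 0.25, by = 0.001)
  ns <- seq(0.3, 0.8, by = 0.001)
  sse <- outer(ks, ns, function(K, N) {
    vapply(seq_along(K), function(i) sum((frac - K[i] * t^N[i])^2), numeric(1))
  })
  best <- arrayInd(which.min(sse), dim(sse))
  expect_equal(kp$params$k_kp, ks[best[1]], tolerance = 0.002 / 0.123)
  expect_equal(kp$params$n, ns[best[2]], tolerance = 0.002 / 0.517)
})

test_that("Hixson-Crowell fitting recovers the cube-root constant exactly", {
  prof <- gen_dissolution_profile("hixson_crowell", list(ks = 0.15), q_inf = 15,
                                  t_points = c(0.5, 1, 2, 4, 8, 12))
  fits <- fit_release_models(prof, models = "hixson_crowell")
  expect_equal(fits[[1]]$params$ks, 0.15, tolerance = 1e-10)
  expect_equal(fits[[1]]$r_squared, 1, tolerance = 1e-12)
})

test_that("Korsmeyer-Peppas with n = 1 coincides with zero order on the fractional scale", {
  t <- 1:8
  q <- 1.2 * t # exact linear release, q_inf chosen so all points usable
  prof <- dissolution_profile(t, q, q_inf = 20, unit = "mg", clip_epsilon = 0)
  fits <- fit_release_models(prof, kp_fraction_cap = 1)
  models <- vapply(fits, function(f) f$model, "")
  k0 <- fits[[which(models == "zero_order")]]$params$k0
  kp <- fits[[which(models == "korsmeyer_peppas")]]
  expect_equal(kp$params$n, 1, tolerance = 1e-6)
  expect_equal(kp$params$k_kp, k0 / 20, tolerance = 1e-6)
})

test_that("fitted release predictions are non-negative over the fit range", {
  prof <- gen_dissolution_profile("first_order", list(q0 = 0.5, k1 = 0.12),
                                  q_inf = 15, noise = "additive_gaussian",
                                  noise_scale = 0.02, seed = 5)
  fits <- fit_release_models(prof, kp_fraction_cap = 1)
  t <- prof$times
  for (f in fits) {
    pred <- switch(f$model,
      zero_order = f$params$k0 * t,
      first_order = f$params$q0 * exp(f$params$k1 * t),
      hixson_crowell = prof$q_inf - pmax(prof$q_inf^(1 / 3) - f$params$ks * t, 0)^3,
      korsmeyer_peppas = prof$q_inf * f$params$k_kp * t^f$params$n
    )
    expect_true(all(pred >= 0), label = f$model)
  }
})

test_that("mechanism classification uses the geometry-specific thresholds", {
  expect_identical(classify_mechanism(0.439, "cylinder"), "fickian")
  expect_identical(classify_mechanism(0.7, "cylinder"), "anomalous")
  for (g in c("cylinder", "thin_film", "sphere")) {
    expect_identical(classify_mechanism(1.0, g), "zero_order_transport")
  }
  expect_identical(classify_mechanism(0.5, "thin_film"), "fickian")
  expect_identical(classify_mechanism(0.51, "thin_film"), "anomalous")
  expect_identical(classify_mechanism(0.43, "sphere"), "fickian")
  expect_identical(classify_mechanism(0.44, "sphere"), "anomalous")
  expect_error(classify_mechanism(0, "cylinder"), "positive")
})

test_that("model selection maximises R^2 with the documented tie-breaks", {
  mk <- function(model, r2) {
    structure(list(model = model, params = list(), r_squared = r2,
                   n_points_used = 5L, mechanism = NA_character_),
              class = "release_fit")
  }
  expect_identical(select_best_model(list(mk("zero_order", 0.90),
                                          mk("first_order", 0.99),
                                          mk("hixson_crowell", 0.95)))$model,
                   "first_order")
  # exact tie: zero order wins over Korsmeyer-Peppas on parameter count
  expect_identical(select_best_model(list(mk("korsmeyer_peppas", 0.97),
                                          mk("zero_order", 0.97)))$model,
                   "zero_order")
  expect_error(select_best_model(list()), "no successful fits")
})

test_that("model selection does not depend on the order models are requested", {
  prof <- gen_dissolution_profile("first_order", list(q0 = 0.5, k1 = 0.12),
                                  q_inf = 15, noise = "additive_gaussian",
                                  noise_scale = 0.02, seed = 3)
  all_models <- c("zero_order", "first_order", "hixson_crowell", "korsmeyer_peppas")
  best_fwd <- select_best_model(fit_release_models(prof, models = all_models))
  best_rev <- select_best_model(fit_release_models(prof, models = rev(all_models)))
  expect_identical(best_fwd$model, best_rev$model)
  expect_equal(best_fwd$r_squared, best_rev$r_squared)
})

test_that("dissolution profiles tolerate only small assay-noise decrements", {
  # a 0.3% dip is clipped to the running maximum
  prof <- dissolution_profile(1:5, c(10, 20, 19.96, 25, 30), q_inf = 15,
                              unit = "percent")
  expect_true(all(diff(prof$released_mg) >= 0))
  # a gross decrease is rejected
  expect_error(
    dissolution_profile(1:5, c(10, 20, 12, 25, 30), q_inf = 15, unit = "percent"),
    "decreases"
  )
})

test_that("sample-withdrawal correction matches hand arithmetic", {
  # three samples of 2 mL at concentrations 0.01, 0.02, 0.03 mg/mL in 500 mL
  conc <- c(0.01, 0.02, 0.03)
  got <- correct_sample_withdrawal(conc, medium_volume_ml = 500, sample_volume_ml = 2)
  expect_equal(got, c(500 * 0.01,
                      500 * 0.02 + 2 * 0.01,
                      500 * 0.03 + 2 * (0.01 + 0.02)))
})
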