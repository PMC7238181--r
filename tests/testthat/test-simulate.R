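test_that("generators are pure functions of their seed", {
  a <- gen_diffusion_timecourse(0.278, noise = "multiplicative_lognormal",
                                noise_scale = 0.05, seed = 17)
  b <- gen_diffusion_timecourse(0.278, noise = "multiplicative_lognormal",
                                noise_scale = 0.05, seed = 17)
  c <- gen_diffusion_timecourse(0.278, noise = "multiplicative_lognormal",
                                noise_scale = 0.05, seed = 18)
  expect_identical(a, b)
  expect_false(identical(a$cumulative_mass, c$cumulative_mass))
  # caller's RNG stream is untouched
  set.seed(123); before <- .Random.seed
  invisible(gen_roughness_profile(3, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("noiseless uptake curves invert to the generating flux", {
  tc <- gen_diffusion_timecourse(0.278, noise = "none")
  est <- fit_steady_state_flux(tc, window = c(0, 4))
  expect_equal(est$jss, 0.278, tolerance = 1e-10)
  zero <- gen_diffusion_timecourse(0, noise = "none")
  expect_true(all(zero$cumulative_mass == 0))
})

test_that("uptake saturates after the plateau time", {
  tc <- gen_diffusion_timecourse(0.278, t_points = c(2, 4, 8, 24), plateau_time = 4,
                                 noise = "none")
  m <- tc$cumulative_mass[, 1]
  s <- tc$geometry$surface_area
  expect_lt(m[3], 0.278 * s * 8)     # below linear extrapolation
  expect_gt(m[3], 0.278 * s * 4)     # still rising
  expect_lt(m[4] - m[3], m[2] - m[1]) # increments shrink
})

test_that("each dissolution generator inverts to its own model at zero noise", {
  cases <- list(
    zero_order = list(k0 = 1.5),
    first_order = list(q0 = 0.5, k1 = 0.12),
    hixson_crowell = list(ks = 0.12),
    korsmeyer_peppas = list(k_kp = 0.07, n = 0.6)
  )
  t_pts <- c(0.25, 0.5, 1, 2, 4, 6, 8)
  for (model in names(cases)) {
    prof <- gen_dissolution_profile(model, cases[[model]], q_inf = 20,
                                    t_points = t_pts)
    fits <- fit_release_models(prof, kp_fraction_cap = 1)
    best <- select_best_model(fits)
    expect_equal(best$r_squared, 1, tolerance = 1e-9, label = model)
    this <- fits[[which(vapply(fits, function(f) f$model, "") == model)]]
    for (p in names(cases[[model]])) {
      expect_equal(this$params[[p]], cases[[model]][[p]], tolerance = 1e-4,
                   label = paste(model, p))
    }
  }
})

test_that("Korsmeyer-Peppas with n = 1 generates zero-order output", {
  t_pts <- c(0.5, 1, 2, 4)
  a <- gen_dissolution_profile("korsmeyer_peppas", list(k_kp = 0.1, n = 1),
                               q_inf = 20, t_points = t_pts)
  b <- gen_dissolution_profile("zero_order", list(k0 = 2), q_inf = 20,
                               t_points = t_pts)
  expect_equal(a$released_mg, b$released_mg, tolerance = 1e-12)
})

test_that("stability generation with b = 0 ignores humidity", {
  conds <- tibble::tibble(temp_c = c(60, 60), rh = c(10, 75),
                          days = rep(list(c(14, 28, 48)), 2))
  study <- gen_stability_study(ln_a = 30, ea = 20, b = 0, conditions = conds,
                               noise = "none")
  expect_equal(study[[1]]$degraded, study[[2]]$degraded, tolerance = 1e-12)
})

test_that("a noise-free synthetic study round-trips to its analytic shelf life", {
  # zero-order truth with ln A fixed so that 10% is reached at day 1095;
  # tablet-scale Ea and B keep every accelerated curve inside the assay range
  ln_a <- log(10 / 1095) + 10.25 / (0.00198 * 298.15) - 0.022 * 60
  study <- gen_stability_study(ln_a = ln_a, ea = 10.25, b = 0.022,
                               model = "zero", noise = "none")
  rates <- data.frame(
    temp_k = vapply(study, function(cc) cc$temp_k, numeric(1)),
    rh = vapply(study, function(cc) cc$rh, numeric(1)),
    k = vapply(study, function(cc) {
      as.numeric(fit_degradation(cc, models = "zero")[[1]]$k)
    }, numeric(1))
  )
  sl <- predict_shelf_life(fit_arrhenius(rates), model = "zero")
  expect_equal(sl$shelf_life_days, 1095, tolerance = 1e-6)
})

test_that("generated roughness profiles hit their target Rav exactly", {
  p <- gen_roughness_profile(3.0, seed = 2)
  expect_equal(average_roughness(p), 3.0, tolerance = 1e-12)
  p2 <- gen_roughness_profile(0.5, n_points = 200, seed = 9)
  expect_equal(average_roughness(p2), 0.5, tolerance = 1e-12)
})

test_that("generated force curves are elastic then yielding", {
  fc <- gen_force_curve(modulus = 7.86, yield_travel = 1, noise = "none")
  pre <- fc$travel <= 1
  expect_equal(fc$force[pre], 7.86 * fc$travel[pre], tolerance = 1e-12)
  # peak sits at the yield point (up to the sampling grid)
  expect_lte(max(fc$force), 7.86)
  expect_gt(max(fc$force), 7.86 * 0.99)
  expect_lt(fc$force[length(fc$force)], max(fc$force))
})

test_that("noise families match their declared moments at large n", {
  x <- rep(10, 2e5)
  ln <- filadose:::with_seed(31, filadose:::apply_noise(x, "multiplicative_lognormal", 0.05))
  expect_equal(mean(log(ln / 10)), 0, tolerance = 5e-4)
  expect_equal(sd(log(ln / 10)), 0.05, tolerance = 1e-3)
  ag <- filadose:::with_seed(32, filadose:::apply_noise(x, "additive_gaussian", 0.05))
  expect_equal(mean(ag), 10, tolerance = 0.01)
  expect_equal(sd(ag), 0.5, tolerance = 0.01)
  expect_identical(filadose:::apply_noise(x, "none", 0), x)
})

test_that("mean recovered flux stays within 1% of truth at 5% noise", {
  jss <- vapply(1:500, function(s) {
    tc <- gen_diffusion_timecourse(0.278, noise = "multiplicative_lognormal",
                                   noise_scale = 0.05, seed = s)
    fit_steady_state_flux(tc, window = c(0, 4))$jss
  }, numeric(1))
  expect_equal(mean(jss), 0.278, tolerance = 0.01)
})
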