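poisson_spec <- function(random = list()) {
  model_spec("n_tones", "poisson-log", fixed = "humidity", random = random)
}
full_random <- list(
  list(group = "family_id", intercept = TRUE, slope = "humidity"),
  list(group = "area_id", intercept = TRUE, slope = "humidity"))

test_that("model specifications validate their structure", {
  expect_error(model_spec("y", "poisson-log", fixed = c("a", "a")),
               "duplicate")
  expect_error(model_spec("y", "poisson-log",
                          random = list(list(group = "g",
                                             intercept = FALSE))),
               "intercept, a slope")
  expect_error(model_spec("y", "poisson-log",
                          random = list(list(intercept = TRUE))), "group")
})

test_that("a random-free specification reduces to the ML Poisson GLM", {
  w <- tiny_world(11)
  f <- fit_mixed(w, poisson_spec())
  oracle <- glm(n_tones ~ scale(humidity), poisson, data = w)
  expect_equal(unname(f$coefficients$estimate), unname(coef(oracle)),
               tolerance = 1e-6)
  expect_equal(f$logLik, as.numeric(logLik(oracle)), tolerance = 1e-8)
  expect_true(f$converged)
})

test_that("with zero true variances the mixed fit agrees with the GLM", {
  w <- generate_world(world_config(seed = 31, beta_humidity_tone = 0.2,
                                   family_intercept_sd = 0,
                                   family_slope_sd = 0,
                                   area_intercept_sd = 0, area_slope_sd = 0))
  fm <- fit_mixed(w, poisson_spec(full_random))
  fg <- fit_mixed(w, poisson_spec())
  bm <- fm$coefficients[fm$coefficients$term == "humidity", ]
  bg <- fg$coefficients[fg$coefficients$term == "humidity", ]
  expect_lt(abs(bm$estimate - bg$estimate), 2 * bg$se)
})

test_that("fixed effects are invariant to relabeling grouping ids", {
  w <- tiny_world(13, borrowing_strength = 0.3)
  f1 <- fit_mixed(w, poisson_spec(full_random))
  w2 <- w
  w2$family_id <- paste0("grp", match(w$family_id, unique(w$family_id)))
  w2$area_id <- paste0("reg", match(w$area_id, unique(w$area_id)))
  f2 <- fit_mixed(w2, poisson_spec(full_random))
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-6)
})

test_that("likelihood-ratio machinery is exact and guarded", {
  w <- tiny_world(17)
  f0 <- fit_mixed(w, model_spec("n_tones", "poisson-log",
                                random = list(list(group = "family_id",
                                                   intercept = TRUE))))
  f1 <- fit_mixed(w, model_spec("n_tones", "poisson-log", fixed = "humidity",
                                random = list(list(group = "family_id",
                                                   intercept = TRUE))))
  out <- lrt(f0, f1)
  expect_equal(out$chi2, max(0, 2 * (f1$logLik - f0$logLik)),
               tolerance = 1e-12)
  expect_equal(out$df, 1)
  expect_gte(out$chi2, 0)

  same <- lrt(f0, f0)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)

  # a log-likelihood gap of 0.22 yields the chi-square 0.44-0.45 pattern
  fa <- f0; fb <- f0
  fb$logLik <- fa$logLik + 0.224
  fb$npar <- fa$npar + 1L
  fb$spec$fixed <- c(fb$spec$fixed, "humidity")
  gap <- lrt(fa, fb)
  expect_true(gap$chi2 >= 0.44 && gap$chi2 <= 0.46)

  # reversed nesting is refused
  expect_error(lrt(f1, f0), "nested|more parameters")
})

test_that("a planted strong fixed effect is detected", {
  w <- generate_world(world_config(seed = 23, beta_humidity_tone = 0.5,
                                   n_families = 30,
                                   languages_per_family = 10, n_areas = 9))
  ri <- list(list(group = "family_id", intercept = TRUE),
             list(group = "area_id", intercept = TRUE))
  f0 <- fit_mixed(w, model_spec("n_tones", "poisson-log", random = ri))
  f1 <- fit_mixed(w, model_spec("n_tones", "poisson-log",
                                fixed = "humidity", random = ri))
  expect_lt(lrt(f0, f1)$p, 0.001)
})

test_that("the ablation table has exactly the five declared structures", {
  w <- tiny_world(19)
  ab <- ablation_sweep(w)
  expect_equal(ab$model,
               c("Full model", "No family intercept", "No family slope",
                 "No area intercept", "No area slope"))
  expect_true(all(is.finite(ab$estimate)))
  expect_true(all(ab$se > 0))
})

test_that("without clustering all ablation rows agree within 2 SE", {
  w <- generate_world(world_config(seed = 29, beta_humidity_tone = 0.2,
                                   family_intercept_sd = 0,
                                   family_slope_sd = 0,
                                   area_intercept_sd = 0, area_slope_sd = 0))
  ab <- ablation_sweep(w)
  for (i in 2:5) {
    expect_lt(abs(ab$estimate[i] - ab$estimate[1]),
              2 * max(ab$se[i], ab$se[1]))
  }
})

test_that("vowel models detect planted effects and survive degeneracy", {
  w <- generate_world(world_config(seed = 37, beta_humidity_vowel = 0.4,
                                   n_families = 30,
                                   languages_per_family = 10, n_areas = 9))
  vm <- vowel_models(w)
  expect_lt(vm$ratio$humidity_lrt$p, 0.05)

  w$humidity <- 0.01
  vm2 <- vowel_models(w)
  expect_true(isTRUE(vm2$ratio$humidity_lrt$degenerate))

  w2 <- tiny_world(38)
  w2$hull_area <- runif(nrow(w2), 1e5, 5e5)
  vm3 <- vowel_models(w2)
  expect_false(is.null(vm3$area))
  expect_true(is.numeric(vm3$area$humidity_lrt$p))
})

test_that("estimation sweeps are structured and stable where convex", {
  w <- tiny_world(41)
  spec <- poisson_spec()
  sw <- estimation_sweep(w, spec, n_starts = 2, seed = 1)
  expect_equal(nrow(sw$runs), 3 * 2)
  expect_true(all(sw$max_deviation < 1e-4))

  # the same optimizer from the same start lands on the same optimum
  sw2 <- estimation_sweep(w, spec, optimizers = c("BFGS", "BFGS"),
                          n_starts = 1, seed = 2)
  expect_equal(unname(sw2$max_deviation), rep(0, 2), tolerance = 1e-12)

  spec_m <- poisson_spec(list(list(group = "family_id", intercept = TRUE)))
  swm <- estimation_sweep(w, spec_m, n_starts = 2, seed = 3)
  expect_equal(nrow(swm$runs), 6)
  expect_true(all(swm$max_deviation < 0.05))
  expect_error(estimation_sweep(w, spec, optimizers = "BFGS"), ">= 2")
})
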