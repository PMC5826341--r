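test_that("identical config and seed give bit-identical worlds", {
  a <- generate_world(world_config(seed = 7))
  b <- generate_world(world_config(seed = 7))
  expect_identical(a, b)
  c_ <- generate_world(world_config(seed = 8))
  expect_false(identical(a$n_tones, c_$n_tones))
})

test_that("config validation rejects bad parameters", {
  expect_error(world_config(family_intercept_sd = -1), ">= 0")
  expect_error(world_config(beta_humidity_tone = NaN), "finite")
  expect_error(world_config(humidity_range = c(0.02, 0.01)), "min < max")
  expect_error(world_config(suppress_complex_below = 1.5))
})

test_that("world invariants hold", {
  w <- generate_world(world_config(seed = 3, borrowing_strength = 0.5,
                                   beta_humidity_vowel = 0.2))
  expect_false(anyDuplicated(w$language_id) > 0)
  expect_true(all(w$n_vowels + w$n_consonants >= 2))
  expect_true(all(w$n_tones >= 0 & w$n_tones <= 10))
  expect_true(all(w$n_tones_alt >= 0))
  expect_identical(w$tone_class == "complex", w$n_tones >= 3)
  hr <- attr(w, "config")$humidity_range
  expect_true(all(w$humidity >= hr[1] & w$humidity <= hr[2]))
})

test_that("degenerate parameters give a single Poisson rate", {
  cfg <- world_config(seed = 5, n_families = 50, languages_per_family = 10,
                      beta_humidity_tone = 0, family_intercept_sd = 0,
                      family_slope_sd = 0, area_intercept_sd = 0,
                      area_slope_sd = 0, borrowing_strength = 0,
                      baseline_tones = 1.3)
  w <- generate_world(cfg)
  se <- sqrt(1.3 / nrow(w))
  expect_lt(abs(mean(w$n_tones) - 1.3), 3 * se)
})

test_that("marginal tone counts are Poisson under the degenerate config", {
  # chi-square goodness of fit against Poisson(1.3), upper tail binned
  pass <- vapply(1:100, function(s) {
    w <- generate_world(world_config(
      seed = 1000 + s, n_families = 50, languages_per_family = 8,
      beta_humidity_tone = 0, family_intercept_sd = 0, family_slope_sd = 0,
      area_intercept_sd = 0, area_slope_sd = 0, borrowing_strength = 0))
    obs <- tabulate(pmin(w$n_tones, 5) + 1L, nbins = 6)
    p <- c(dpois(0:4, 1.3), ppois(4, 1.3, lower.tail = FALSE))
    suppressWarnings(chisq.test(obs, p = p)$p.value) > 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("a maximum-likelihood Poisson fit recovers the humidity effect", {
  betas <- vapply(1:8, function(s) {
    w <- generate_world(world_config(
      seed = 40 + s, n_families = 80, languages_per_family = 10,
      beta_humidity_tone = 0.2, family_intercept_sd = 0, family_slope_sd = 0,
      area_intercept_sd = 0, area_slope_sd = 0, borrowing_strength = 0))
    unname(coef(glm(n_tones ~ scale(humidity), poisson, data = w))[2])
  }, numeric(1))
  expect_lt(abs(mean(betas) - 0.2), 0.05)
})

test_that("climate-tracking borrowing confounds the naive regression", {
  naive_sig <- vapply(1:10, function(s) {
    w <- confound_world(300 + s)
    summary(glm(n_tones ~ scale(humidity), poisson,
                data = w))$coefficients[2, 4] < 0.05
  }, logical(1))
  expect_gt(mean(naive_sig), 0.5)
})

test_that("corpus generator respects the null and the planted tone-3 shift", {
  tk0 <- generate_corpus(shift_tone3 = 0, n_tokens = 50000, seed = 9)
  by_cond <- tapply(tk0$count, list(tk0$condition, tk0$tone_category), sum)
  p3 <- by_cond[, "t3"] / rowSums(by_cond)
  n <- min(rowSums(by_cond))
  expect_lt(abs(p3[1] - p3[2]),
            2.58 * sqrt(2 * 0.21 * 0.79 / n))

  tk <- generate_corpus(shift_tone3 = 0.12, n_tokens = 1e5, seed = 2)
  tb <- tapply(tk$count[tk$condition == "trouble_source"],
               tk$tone_category[tk$condition == "trouble_source"], sum)
  expect_lt(abs(tb[["t3"]] / sum(tb) - 0.33), 0.01)

  expect_error(generate_corpus(shift_tone3 = 0.9), "outside")
})

test_that("monthly contour proportions are flat when the effect is zero", {
  tk <- generate_corpus(shift_tone3 = 0, monthly_contour_effect = 0,
                        n_tokens = 96000, seed = 4, n_months = 12)
  tk$contour <- tk$tone_category %in% attr(tk, "contour_categories")
  agg <- tapply(tk$count, list(tk$date, tk$contour), sum)
  prop <- agg[, "TRUE"] / rowSums(agg)
  p <- mean(prop)
  sd1 <- sqrt(p * (1 - p) / mean(rowSums(agg)))
  expect_lt(max(abs(prop - p)), 3.5 * sd1)
})

test_that("formant templates scale and degenerate correctly", {
  f0 <- generate_formants(c(L1 = 0), k_vowels = 4, jitter_sd = 0)
  expect_equal(vowel_space_table(f0)$hull_area, 0)
  f1 <- generate_formants(c(L1 = 1, L2 = 2), k_vowels = 5, jitter_sd = 0)
  areas <- vowel_space_table(f1)$hull_area
  expect_equal(areas[2] / areas[1], 4, tolerance = 1e-12)
  # shoelace of the template triangle (300,800),(800,1100),(300,2300)
  expect_equal(areas[1], 375000, tolerance = 1e-9)
  expect_error(generate_formants(1, k_vowels = 2), ">= 3")
})

test_that("language table round-trips through CSV", {
  w <- tiny_world()
  path <- tempfile(fileext = ".csv")
  write_language_table(w, path)
  back <- read_language_table(path)
  expect_equal(nrow(back), nrow(w))
  expect_equal(back$n_tones, w$n_tones)
  expect_equal(back$humidity, w$humidity, tolerance = 1e-12)
})
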