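test_that("independent sampling respects and exhausts the constraints", {
  # all distinct: everything is returned
  set.seed(1)
  ids <- sample_independent(family = letters[1:5], area = LETTERS[1:5])
  expect_setequal(ids, 1:5)

  # two records sharing a family: exactly one survives
  set.seed(2)
  ids <- sample_independent(family = c("f1", "f1"), area = c("a1", "a2"))
  expect_length(ids, 1)

  expect_error(sample_independent(character(), character()), "no records")
})

test_that("greedy sampling matches exhaustive enumeration on a fixture", {
  # 6 records, two family clashes and one area clash
  fam <- c("f1", "f1", "f2", "f2", "f3", "f4")
  area <- c("a1", "a2", "a3", "a4", "a5", "a5")
  # enumeration oracle: run the greedy rule over all 720 scan orders
  greedy_ref <- function(ord) {
    fs <- character(); as <- character(); keep <- integer()
    for (i in ord) {
      if (!(fam[i] %in% fs) && !(area[i] %in% as)) {
        fs <- c(fs, fam[i]); as <- c(as, area[i]); keep <- c(keep, i)
      }
    }
    sort(keep)
  }
  perms <- NULL
  for (p in combinat_perms(6)) perms <- c(perms, list(p))
  oracle_sets <- unique(lapply(perms, greedy_ref))
  oracle_sizes <- sort(unique(lengths(oracle_sets)))

  set.seed(99)
  seen_sizes <- integer()
  for (i in 1:2000) {
    ids <- sample_independent(fam, area)
    expect_false(anyDuplicated(fam[ids]) > 0)
    expect_false(anyDuplicated(area[ids]) > 0)
    # maximality: every skipped record clashes with a kept one
    for (j in setdiff(1:6, ids)) {
      expect_true(fam[j] %in% fam[ids] || area[j] %in% area[ids])
    }
    expect_true(list(sort(ids)) %in% oracle_sets)
    seen_sizes <- union(seen_sizes, length(ids))
  }
  expect_setequal(seen_sizes, oracle_sizes)
})

test_that("percentile matches the linear-interpolation definition", {
  expect_equal(percentile(c(1, 2, 3), 0.5), 2)
  expect_equal(percentile(c(10, 20, 30, 40), 0.25), 17.5)
  expect_error(percentile(numeric(), 0.5), "nonempty")

  set.seed(11)
  for (i in 1:200) {
    v <- rnorm(sample(2:40, 1))
    x <- runif(4)
    expect_equal(percentile(v, x),
                 unname(quantile(v, x, type = 7)), tolerance = 1e-12)
  }
})

test_that("percentile test handles ties, strata and relabeling", {
  w <- tiny_world(5)
  w$humidity <- 0.01  # all identical: every comparison ties, strict fails
  pt <- percentile_test(w, percentile_test_config(n_iterations = 50, seed = 1))
  expect_true(all(pt$proportions == 0))

  w2 <- tiny_world(5)
  w2$n_tones <- 0L  # no complex languages at all
  expect_error(percentile_test(w2), "complex")

  # bijective renaming of family and area ids leaves results unchanged
  w3 <- tiny_world(6)
  w4 <- w3
  w4$family_id <- paste0("X_", w3$family_id)
  w4$area_id <- paste0("Y_", w3$area_id)
  cfg <- percentile_test_config(n_iterations = 200, seed = 42)
  expect_equal(percentile_test(w3, cfg)$proportions,
               percentile_test(w4, cfg)$proportions)
})

test_that("percentile test groups are equalized within iterations", {
  w <- tiny_world(9)
  pt <- percentile_test(w, percentile_test_config(n_iterations = 100,
                                                  seed = 3))
  expect_true(all(pt$group_size >= 2))
  expect_equal(pt$n_iterations, 100)
  expect_true(all(pt$proportions >= 0 & pt$proportions <= 1))
})

test_that("power curve is degenerate, bounded and monotone", {
  cfg1 <- percentile_test_config(n_iterations = 1, seed = 5)
  pc1 <- power_curve(0.5, worlds_per_effect = 1, config = cfg1,
                     base_world = world_config(n_families = 20,
                                               languages_per_family = 8,
                                               n_areas = 9))
  expect_true(all(pc1$mean_proportion %in% c(0, 1)))

  cfg <- percentile_test_config(n_iterations = 200, seed = 5)
  base <- world_config(n_families = 40, languages_per_family = 8,
                       n_areas = 16, baseline_tones = 2)
  pc <- power_curve(c(0, 0.6, 1.5), worlds_per_effect = 4, config = cfg,
                    base_world = base)
  expect_true(all(pc$rejection_rate[pc$effect == 0] <= 0.10))
  # rejection rate and mean proportion nondecreasing in the effect
  for (px in unique(pc$percentile)) {
    sub <- pc[pc$percentile == px, ]
    sub <- sub[order(sub$effect), ]
    expect_true(all(diff(sub$rejection_rate) >= 0))
  }
  m0 <- mean(pc$mean_proportion[pc$effect == 0])
  m2 <- mean(pc$mean_proportion[pc$effect == 1.5])
  expect_gt(m2, m0)
})
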