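test_that("region counts respect hemisphere mode, midline pooling and starter exclusion", {
  b <- toy_brain(rbind(toy_cells("SNr", 2, "ipsi"),
                       toy_cells("SNr", 1, "contra"),
                       toy_cells("DR", 1, "midline")))
  combined <- count_by_region(b, CAT)
  expect_equal(unname(combined["SNr"]), 3L)
  expect_equal(unname(combined["DR"]), 1L)
  expect_equal(sum(combined), 4L)   # starter not counted
  sep <- count_by_region(b, CAT, "separate")
  expect_equal(unname(sep["SNr", c("ipsi", "contra", "midline")]),
               c(2L, 1L, 0L))
  expect_equal(unname(sep["DR", ]), c(0L, 0L, 1L))
})

test_that("fraction matrix normalizes per brain and is scale invariant", {
  b <- toy_brain(rbind(toy_cells("SNr", 30), toy_cells("DR", 70)))
  fr <- fraction_matrix(list(b), CAT)
  expect_equal(unname(fr[1, "SNr"]), 0.30)
  expect_equal(unname(fr[1, "DR"]), 0.70)
  # triplicate every cell: fractions unchanged
  b3 <- toy_brain(rbind(b$inputs, b$inputs, b$inputs))
  expect_equal(unclass(fraction_matrix(list(b3), CAT)), unclass(fr),
               ignore_attr = TRUE)
  coh <- cohort4()
  frc <- fraction_matrix(coh, CAT)
  expect_equal(unname(rowSums(frc)), rep(1, 4), tolerance = 1e-12)
  empty <- toy_brain(toy_cells("SNr", 0))
  expect_error(fraction_matrix(list(empty), CAT), "zero input")
})

test_that("cohort column means recover the generating composition", {
  coh <- cohort50()
  cfg <- attr(coh, "config")
  fr <- fraction_matrix(coh, CAT)
  mu <- colMeans(fr)
  se <- apply(unclass(fr), 2, stats::sd) / sqrt(nrow(fr))
  # within 3 SE for at least 95% of regions (archetype mixing keeps means
  # centred on the composition; a few 3-SE misses are expected by chance)
  inside <- abs(mu - cfg$composition[colnames(fr)]) <= 3 * se + 1e-12
  expect_gte(mean(inside), 0.9)
})

test_that("local/long split sums to 1 per brain and recovers local_fraction", {
  b <- toy_brain(toy_cells("SNr", 10))
  sp1 <- local_long_split(fraction_matrix(list(b), CAT), CAT)
  expect_equal(sp1$per_brain$local, 1.0)
  expect_equal(sp1$per_brain$long_range, 0.0)
  coh <- cohort50()
  sp <- local_long_split(fraction_matrix(coh, CAT), CAT)
  expect_equal(sp$per_brain$local + sp$per_brain$long_range,
               rep(1, length(coh)))
  expect_lt(abs(sp$mean_local - 0.46), 0.02)
  fr_long <- fraction_matrix(coh, CAT, denominator = "long_range_only")
  expect_error(local_long_split(fr_long, CAT), "all_inputs")
})

test_that("convergence index is long-range inputs per starter", {
  starters <- toy_cells("PBP", 1000, tc66t = TRUE, th = TRUE,
                        is_starter = TRUE)
  b <- brain_dataset("toy", starters, toy_cells("NAcLat", 8000))
  expect_equal(convergence_index(b, CAT), 8.0)
  b_local <- brain_dataset("toy", toy_cells("PBP", 500, tc66t = TRUE,
                                            is_starter = TRUE),
                           toy_cells("SNr", 100))
  expect_equal(convergence_index(b_local, CAT), 0.0)
  no_start <- brain_dataset("toy", starters[0, ], toy_cells("SNr", 5))
  expect_error(convergence_index(no_start, CAT), "zero starters")
})

test_that("per-10,000 normalization matches its arithmetic contract", {
  expect_equal(per_10k_normalization(188, 5000), 376)
  expect_equal(per_10k_normalization(0, 10000), 0)
  expect_equal(per_10k_normalization(10000, 10000), 10000)
  expect_error(per_10k_normalization(5, 0), "positive")
  expect_error(per_10k_normalization(11, 10), "exceed")
})

test_that("starter composition sums to 1 and recovers the subnucleus mix", {
  b <- toy_brain(toy_cells("SNr", 1),
                 starters = toy_cells("PBP", 10, tc66t = TRUE,
                                      is_starter = TRUE))
  comp <- starter_composition(b, CAT)
  expect_equal(unname(comp["PBP"]), 1.0)
  expect_equal(sum(comp), 1.0)
  coh <- cohort50()
  pbp <- vapply(coh, function(b) starter_composition(b, CAT)["PBP"],
                numeric(1))
  expect_lt(abs(mean(pbp) - 0.58), 0.03)
  expect_error(starter_composition(brain_dataset("x", b$starters[0, ],
                                                 b$inputs), CAT),
               "no starter")
})

test_that("starter ellipse uses coordinate means and sample SDs", {
  one <- toy_cells("PBP", 1, tc66t = TRUE, is_starter = TRUE,
                   x_ml = 100, y_dv = -4300)
  e1 <- starter_ellipse(one)
  expect_equal(e1$center_ml, 100)
  expect_equal(e1$center_dv, -4300)
  expect_equal(e1$radius_ml, 0)
  sym <- toy_cells("PBP", 4, tc66t = TRUE, is_starter = TRUE)
  sym$x_ml <- c(-200, 200, -200, 200)
  sym$y_dv <- c(-100, -100, 100, 100)
  e2 <- starter_ellipse(sym)
  expect_equal(e2$center_ml, 0)
  expect_equal(e2$center_dv, 0)
  # sample SD of (+/-a): sqrt(4 a^2 / 3)
  expect_equal(e2$radius_ml, sqrt(4 * 200^2 / 3))
  expect_equal(e2$radius_dv, sqrt(4 * 100^2 / 3))
  none <- toy_cells("PBP", 2, tc66t = TRUE, is_starter = TRUE)
  expect_error(starter_ellipse(none), "coordinates")
})

test_that("pooled t-test matches the closed-form oracle", {
  idn <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(idn$p, 1.0)
  expect_true(idn$ci[1] < 0 && idn$ci[2] > 0)
  a <- c(1, 2, 3, 4)
  b <- c(2, 3, 4, 5)
  res <- compare_groups(a, b)
  # independent closed-form pooled-variance computation
  sp2 <- (3 * stats::var(a) + 3 * stats::var(b)) / 6
  t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(res$t, t_oracle, tolerance = 1e-12)
  expect_equal(res$df, 6)
  expect_equal(res$p, 2 * stats::pt(t_oracle, 6), tolerance = 1e-12)
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})
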