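test_that("co-label rules validate and filter exactly the matching inputs", {
  expect_error(colabel_rule(require = "gad", exclude = "gad"), "disjoint")
  expect_error(colabel_rule(require = "nonsense"), "unknown marker")
  b <- toy_brain(rbind(
    toy_cells("SNr", 1, gad = TRUE),                 # GABA input
    toy_cells("SNr", 1, gad = TRUE, tc66t = TRUE),   # TC66T+ -> excluded
    toy_cells("SNr", 1),                             # GAD- -> excluded
    toy_cells("RRF", 1, th = TRUE)))                 # DA input
  g <- apply_colabel_rule(b, gaba_rule())
  expect_equal(nrow(g), 1L)
  expect_true(all(g$gad & !g$tc66t))
  d <- apply_colabel_rule(b, da_rule())
  expect_equal(nrow(d), 1L)
  expect_equal(d$region, "RRF")
  # starters never pass, whatever their markers
  b2 <- toy_brain(toy_cells("SNr", 1, gad = TRUE),
                  starters = toy_cells("PBP", 5, tc66t = FALSE, gad = TRUE,
                                       is_starter = TRUE))
  expect_equal(nrow(apply_colabel_rule(b2, gaba_rule())), 1L)
})

test_that("rule filtering is idempotent and order-independent", {
  b <- cohort4()[[1]]
  rule1 <- colabel_rule(require = c("gfp", "gad"), exclude = "tc66t")
  rule2 <- colabel_rule(require = c("gad", "gfp"), exclude = "tc66t")
  f1 <- apply_colabel_rule(b, rule1)
  f2 <- apply_colabel_rule(b, rule2)
  expect_equal(f1, f2)
  again <- apply_colabel_rule(brain_dataset(b$brain_id, b$starters, f1),
                              rule1)
  expect_equal(nrow(again), nrow(f1))
})

test_that("GABAergic composition sums to 1, finds SNr dominant, and recovers rates", {
  # fixture built to the published composition levels: shares scale with
  # count x GAD rate
  b <- toy_brain(rbind(toy_cells("SNr", 201, gad = TRUE),
                       toy_cells("PBP", 193, gad = TRUE),
                       toy_cells("SNc", 105, gad = TRUE),
                       toy_cells("PnO", 75, gad = TRUE),
                       toy_cells("SNr", 300)))  # GAD- cells don't count
  gtab <- gaba_composition(list(b), CAT)
  expect_equal(sum(gtab$mean_share), 1, tolerance = 1e-9)
  expect_equal(gtab$region[which.max(gtab$mean_share)], "SNr")
  expect_equal(gtab$mean_share[gtab$region == "SNr"], 201 / 574)
  # generator-level recovery at the defaults (printed share for SNr: 20.1%)
  coh <- cohort50()
  g50 <- gaba_composition(coh, CAT)
  expect_equal(sum(g50$mean_share), 1, tolerance = 1e-9)
  expect_equal(g50$region[which.max(g50$mean_share)], "SNr")
  expect_lt(abs(g50$mean_share[g50$region == "SNr"] * 100 - 20.1), 1.5)
  # hemisphere-separated heatmap: midline column only for midline regions
  heat <- gaba_composition(coh, CAT, hemispheres = "separate")
  expect_equal(sum(heat), 1, tolerance = 1e-9)
  non_mid <- setdiff(rownames(heat), c("DR", "RMg", "MnR"))
  expect_true(all(heat[non_mid, "midline"] == 0))
  empty <- toy_brain(toy_cells("SNr", 3))
  expect_error(gaba_composition(list(empty), CAT), "zero GABAergic")
})

test_that("TH+ fractions are computed outside the TVA sphere and recover 0.40", {
  cells <- rbind(
    toy_cells("PBP", 2, th = TRUE, x_ml = 300, y_dv = -4400, z_ap = -3000),
    toy_cells("PBP", 1, th = FALSE, x_ml = 300, y_dv = -4400, z_ap = -3000),
    # inside the default 500 um sphere: excluded from the denominator
    toy_cells("PBP", 5, th = FALSE, x_ml = 500, y_dv = -4400, z_ap = -3500))
  b <- toy_brain(cells)
  res <- da_colabel_fraction(list(b), CAT)
  expect_equal(res$mean_fraction[res$roi == "vta_anterior"], 2 / 3)
  expect_equal(res$mean_n_eligible[res$roi == "vta_anterior"], 3)
  # sphere filter is monotone in the radius
  r_small <- da_colabel_fraction(list(b), CAT, tva_radius = 100)
  r_large <- da_colabel_fraction(list(b), CAT, tva_radius = 2000)
  expect_true(all(r_large$mean_n_eligible <= r_small$mean_n_eligible))
  # missing coordinates error only when the sphere filter needs them
  nocoord <- toy_brain(toy_cells("RRF", 3, th = TRUE))
  expect_error(da_colabel_fraction(list(nocoord), CAT), "coordinates")
  # generator-level recovery of the 0.40 TH rate in all four ROIs
  res50 <- da_colabel_fraction(cohort50(), CAT)
  expect_true(all(abs(res50$mean_fraction - 0.40) < 0.05))
  expect_equal(res50$n_brains, rep(50L, 4))
})

test_that("regions with no eligible cells are missing, not zero", {
  b <- toy_brain(toy_cells("PBP", 3, th = TRUE, x_ml = 300, y_dv = -4400,
                           z_ap = -3000))
  res <- da_colabel_fraction(list(b), CAT)
  expect_true(is.na(res$mean_fraction[res$roi == "rrf"]))
  expect_equal(res$n_brains[res$roi == "rrf"], 0L)
})

test_that("DA total estimate multiplies share by TH fraction, in percent", {
  expect_equal(da_total_estimate(0.11, 0.40), 4.4)
  expect_equal(da_total_estimate(0, 0.9), 0)
  expect_equal(da_total_estimate(1, 1), 100)
  expect_error(da_total_estimate(1.2, 0.4), "\\[0, 1\\]")
})

test_that("serotonin summary reports per-region Tph2 fractions and per-10k counts", {
  inputs <- rbind(toy_cells("DR", 30, hemisphere = "midline", tph2 = TRUE),
                  toy_cells("DR", 70, hemisphere = "midline"),
                  toy_cells("SNr", 9900))
  b <- toy_brain(inputs)
  s <- serotonin_summary(list(b), CAT)
  dr <- s[s$region == "DR", ]
  expect_equal(nrow(dr), 1L)            # midline: no hemisphere split
  expect_equal(dr$hemisphere, "midline")
  expect_equal(dr$mean_fraction, 0.30)
  expect_equal(dr$mean_per_10k, 30)
  # absent region-hemisphere cells are missing, not zero
  expect_true(is.na(s$mean_fraction[s$region == "RMg"]))
  # generator-level recovery of the planted Tph2 rates (0.20-0.37)
  coh <- cohort50()
  cfg <- attr(coh, "config")
  s50 <- serotonin_summary(coh, CAT)
  for (i in seq_len(nrow(s50))) {
    planted <- cfg$colabel_rates$tph2[cfg$colabel_rates$region ==
                                        s50$region[i]]
    expect_lt(abs(s50$mean_fraction[i] - planted), 0.04)
  }
})
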