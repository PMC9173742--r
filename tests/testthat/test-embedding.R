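test_that("z-scoring standardizes regions across brains, flagging constant rows", {
  v <- c(1, 2, 3, 4) / c(11, 12, 13, 14)
  fr2 <- structure(cbind(SNr = v, DR = rep(0.5, 4)),
                   dimnames = list(paste0("b", 1:4), c("SNr", "DR")),
                   denominator = "all_inputs")
  expect_warning(z <- zscore_regions(fr2), "constant")
  expect_equal(unname(z["SNr", ]), (v - mean(v)) / stats::sd(v))
  expect_equal(rowMeans(z), c(SNr = 0, DR = 0), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, stats::sd)), c(1, 0), tolerance = 1e-12)
  expect_equal(attr(z, "constant_regions"), "DR")
  expect_error(zscore_regions(fr2[1, , drop = FALSE]), "at least 2")
})

test_that("z-scores of a simple integer profile match the hand computation", {
  x <- matrix(c(1, 2, 3, 4), nrow = 4, ncol = 1,
              dimnames = list(paste0("b", 1:4), "R"))
  z <- zscore_regions(structure(x, denominator = "all_inputs"))
  expect_equal(unname(z["R", ]), c(-1.161895, -0.3872983, 0.3872983,
                                   1.161895), tolerance = 1e-6)
})

test_that("embedding ensembles are seed-deterministic with one point set per seed", {
  set.seed(5)
  z <- matrix(rnorm(57 * 4), 57, 4,
              dimnames = list(paste0("r", 1:57), NULL))
  e <- embed_ensemble(z, n_embeddings = 3, seeds = c(0, 1, 2))
  expect_length(e, 3)
  expect_true(all(vapply(e, function(m) all(dim(m) == c(57, 2)), logical(1))))
  e2 <- embed_ensemble(z, n_embeddings = 1, seeds = 1)
  expect_identical(e[[2]], e2[[1]])
  expect_false(identical(e[[1]], e[[2]]))
  expect_error(embed_ensemble(z[1:5, ], n_embeddings = 1, seeds = 0),
               "fewer points")
  expect_error(embed_ensemble(z, n_embeddings = 2, seeds = c(1, 1)),
               "distinct")
})

test_that("normalized pairwise distances match a brute-force oracle", {
  two <- matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)
  d2 <- normalized_pairwise_distance(two)
  expect_equal(unname(d2), matrix(c(0, 1, 1, 0), 2, 2))
  coll <- cbind(c(0, 1, 2), 0)
  d3 <- normalized_pairwise_distance(coll)
  expect_equal(unname(d3[1, ]), c(0, 0.5, 1))
  set.seed(9)
  pts <- matrix(rnorm(57 * 2), 57, 2)
  fast <- normalized_pairwise_distance(pts)
  # O(n^2) reference: explicit double loop
  n <- nrow(pts)
  slow <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    slow[i, j] <- sqrt(sum((pts[i, ] - pts[j, ])^2))
  slow <- slow / max(slow)
  expect_equal(unname(fast), slow, tolerance = 1e-12)
  expect_equal(max(fast), 1)
  expect_true(all(diag(fast) == 0))
  expect_error(normalized_pairwise_distance(matrix(1, 3, 2)), "coincident")
})

test_that("aggregation is the element-wise mean and preserves distance invariants", {
  m <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"),
                                                       c("a", "b")))
  z0 <- m * 0
  expect_equal(unclass(aggregate_distances(list(m, m, m))), m,
               ignore_attr = TRUE)
  half <- aggregate_distances(list(z0, m))
  expect_equal(unclass(half), m / 2, ignore_attr = TRUE)
  expect_equal(attr(half, "n_embeddings"), 2L)
  expect_error(aggregate_distances(list(m, matrix(0, 3, 3))), "shape")
  set.seed(3)
  mats <- lapply(1:5, function(i)
    normalized_pairwise_distance(matrix(rnorm(20), 10, 2)))
  agg <- aggregate_distances(mats)
  expect_equal(unclass(agg), t(unclass(agg)), ignore_attr = TRUE)
  expect_true(all(agg >= 0 & agg <= 1))
  expect_true(all(diag(agg) == 0))
})

test_that("clustering recovers planted archetypes and honours fixed k", {
  coh <- generate_cohort(generator_config(n_brains = 6, noise_scale = 0.05,
                                          seed = 21))
  fr <- fraction_matrix(coh, CAT)
  agg <- aggregated_region_distance(fr, n_embeddings = 20)
  expect_true(all(abs(unclass(agg) - t(unclass(agg))) < 1e-12))
  cl <- cluster_regions(agg)
  expect_equal(cl$k, 3L)
  planted <- default_archetypes(CAT)$assignment
  ari <- mclust::adjustedRandIndex(cl$cluster[CAT$name],
                                   as.integer(planted[CAT$name]))
  expect_gte(ari, 0.9)
  one <- cluster_regions(agg, k = 1)
  expect_true(all(one$cluster == 1))
  expect_error(cluster_regions(agg, k = 100), "exceed")

  # stability: each pair's within/between-cluster relationship (clustering
  # each embedding separately at k = 3) is identical across all 20
  # embeddings for >= 90% of region pairs
  z <- zscore_regions(fr)
  embs <- embed_ensemble(z, 20)
  same_cluster <- sapply(embs, function(e) {
    d <- normalized_pairwise_distance(e)
    lab <- stats::cutree(stats::hclust(stats::as.dist(d), "average"), 3)
    outer(lab, lab, `==`)[upper.tri(d)]
  })
  consistent <- rowMeans(same_cluster) %in% c(0, 1)
  expect_gte(mean(consistent), 0.9)
})

test_that("mixing score is 1 for separated clouds, chance under label shuffling", {
  set.seed(4)
  cloud_a <- matrix(rnorm(40, mean = 0), 20, 2)
  cloud_b <- matrix(rnorm(40, mean = 50), 20, 2)
  pts <- rbind(cloud_a, cloud_b)
  labels <- rep(c("a", "b"), each = 20)
  ms <- mixing_score(pts, labels, k_nn = 5)
  expect_equal(ms$score, 1.0)
  expect_equal(ms$expected_chance, (20 / 40) * (19 / 39) * 2)
  # permutation oracle: shuffled labels over one cloud sit near chance
  one_cloud <- matrix(rnorm(200), 100, 2)
  perm_scores <- replicate(100, mixing_score(one_cloud,
                                             sample(rep(c("a", "b"), 50)),
                                             k_nn = 5)$score)
  expect_lt(abs(mean(perm_scores) - ms$expected_chance), 0.03)
  expect_error(mixing_score(pts, labels, k_nn = 25), "k_nn")
  expect_error(mixing_score(pts, rep("a", 40)), "two dataset")
})

test_that("dataset comparison mixes shared cohorts and segregates disjoint ones", {
  cfg <- generator_config(n_brains = 12, seed = 31)
  shared <- generate_two_dataset_scenario(TRUE, cfg)
  res_s <- compare_datasets(shared$a, shared$b, CAT,
                            region_subset = "local", n_embeddings = 5,
                            k_nn = 5, n_perm = 50)
  expect_lt(res_s$score - res_s$expected_chance, 0.15)
  expect_gt(res_s$p_value, 0.05)
  disjoint <- generate_two_dataset_scenario(FALSE, cfg)
  res_d <- compare_datasets(disjoint$a, disjoint$b, CAT,
                            region_subset = "local", n_embeddings = 5,
                            k_nn = 5, n_perm = 50)
  expect_gt(res_d$score, 0.8)
  expect_lt(res_d$p_value, 0.05)
  # identical cohorts are exchangeable: score near chance
  res_i <- compare_datasets(shared$a, shared$a, CAT,
                            region_subset = "long_range", n_embeddings = 3,
                            k_nn = 3, n_perm = 20)
  expect_lt(res_i$score - res_i$expected_chance, 0.2)
  expect_error(compare_datasets(shared$a, shared$b, CAT,
                                region_subset = character(0)), "empty")
})
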