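#' Z-score region fractions across brains
#'
#' Transposes the brains x regions fraction matrix so regions are the points,
#' then standardizes each region's fractional counts across brains (sample
#' SD). Z-scoring puts regions with very different count magnitudes on a
#' common variation scale, which is what the embedding clusters on. Constant
#' regions become all-zero rows, with a warning.
#'
#' @param fractions A `fraction_matrix` (brains x regions), >= 2 brains.
#' @return Regions x brains numeric matrix with a `constant_regions`
#'   attribute naming any zero-variance regions.
#' @export
zscore_regions <- function(fractions) {
  if (nrow(fractions) < 2L)
    stop("z-scoring requires at least 2 brains")
  z <- t(unclass(fractions))
  mu <- rowMeans(z)
  s <- apply(z, 1, stats::sd)
  const <- s == 0
  if (any(const)) {
    warning("constant region(s) z-scored to all zeros: ",
            paste(rownames(z)[const], collapse = ", "))
    s[const] <- 1
  }
  out <- (z - mu) / s
  attr(out, "constant_regions") <- rownames(z)[const]
  out
}

#' Ensemble of UMAP embeddings
#'
#' Runs the nonlinear neighborhood-preserving embedding (UMAP) once per seed
#' on the rows of `z` (regions as points, brains as features, in the default
#' orientation). Individual embeddings are stochastic in their initial
#' conditions; downstream aggregation over the ensemble is what makes region
#' associations reproducible.
#'
#' @param z Points x features numeric matrix (e.g. from [zscore_regions()]).
#' @param n_embeddings Number of embeddings (default 20).
#' @param seeds Integer seeds, one per embedding (default `0:(n-1)`).
#' @param n_neighbors,min_dist UMAP hyperparameters.
#' @return List of points x 2 coordinate matrices, with `seeds` attribute.
#' @export
embed_ensemble <- function(z, n_embeddings = 20,
                           seeds = seq_len(n_embeddings) - 1L,
                           n_neighbors = 10, min_dist = 0.1) {
  if (n_embeddings < 1L) stop("n_embeddings must be >= 1")
  if (length(seeds) != n_embeddings) stop("need one seed per embedding")
  if (anyDuplicated(seeds)) stop("seeds must be distinct")
  if (nrow(z) <= n_neighbors)
    stop("fewer points (", nrow(z), ") than the neighborhood size requires")
  out <- lapply(seeds, function(s) {
    set.seed(s)
    emb <- uwot::umap(z, n_neighbors = n_neighbors, min_dist = min_dist,
                      metric = "euclidean", n_threads = 1, n_sgd_threads = 0,
                      verbose = FALSE)
    rownames(emb) <- rownames(z)
    emb
  })
  attr(out, "seeds") <- as.integer(seeds)
  out
}

#' Max-normalized pairwise distances of an embedding
#'
#' Euclidean distances between embedded points divided by the maximum
#' pairwise distance, so every embedding is on a common [0, 1] scale
#' regardless of its arbitrary global geometry.
#'
#' @param points Points x 2 (or more) coordinate matrix, >= 2 points.
#' @return Symmetric points x points matrix with zero diagonal, max entry 1.
#' @export
normalized_pairwise_distance <- function(points) {
  if (nrow(points) < 2L) stop("need at least 2 points")
  d <- as.matrix(stats::dist(points))
  m <- max(d)
  if (m == 0) stop("all points coincident; normalized distance undefined")
  d / m
}

#' Aggregate distance matrices across an embedding ensemble
#'
#' Element-wise mean of the per-embedding max-normalized distance matrices.
#'
#' @param matrices List of equally shaped/ordered distance matrices.
#' @param seeds Optional seeds to record.
#' @return An `aggregated_distance` matrix with `n_embeddings` and `seeds`
#'   attributes.
#' @export
aggregate_distances <- function(matrices, seeds = NULL) {
  if (length(matrices) < 1L) stop("no matrices to aggregate")
  dims <- lapply(matrices, dim)
  if (length(unique(dims)) != 1L) stop("matrices differ in shape")
  nms <- lapply(matrices, rownames)
  if (length(unique(nms)) != 1L) stop("matrices differ in row ordering")
  agg <- Reduce(`+`, matrices) / length(matrices)
  structure(agg, n_embeddings = length(matrices), seeds = seeds,
            class = c("aggregated_distance", class(agg)))
}

#' Z-score, embed, and aggregate in one step
#'
#' @inheritParams embed_ensemble
#' @param fractions A `fraction_matrix`.
#' @return An `aggregated_distance` matrix over regions.
#' @export
aggregated_region_distance <- function(fractions, n_embeddings = 20,
                                       seeds = seq_len(n_embeddings) - 1L,
                                       n_neighbors = 10, min_dist = 0.1) {
  z <- zscore_regions(fractions)
  embs <- embed_ensemble(z, n_embeddings, seeds, n_neighbors, min_dist)
  aggregate_distances(lapply(embs, normalized_pairwise_distance),
                      seeds = attr(embs, "seeds"))
}

#' Hierarchical clustering of regions on aggregated distances
#'
#' Agglomerative clustering (average linkage by default) on the aggregated
#' distance matrix. If `k` is not given, it is selected from `k_range` by
#' maximizing the mean silhouette width computed on the aggregated
#' distances.
#'
#' @param agg An `aggregated_distance` (or any symmetric distance matrix).
#' @param k Number of clusters; `NULL` selects by silhouette.
#' @param k_range Candidate k values when selecting automatically.
#' @param linkage Linkage method for [stats::hclust()].
#' @return A `cluster_assignment` list: `cluster` (named integer vector),
#'   `k`, `linkage`, `silhouette` (mean width; `NA` for k = 1), `tree`.
#' @export
cluster_regions <- function(agg, k = NULL, k_range = 2:6,
                            linkage = "average") {
  n <- nrow(agg)
  d <- stats::as.dist(agg)
  tree <- stats::hclust(d, method = linkage)
  sil_of <- function(labels)
    mean(cluster::silhouette(labels, d)[, "sil_width"])
  if (is.null(k)) {
    k_range <- k_range[k_range <= n]
    sils <- vapply(k_range, function(kk)
      sil_of(stats::cutree(tree, kk)), numeric(1))
    k <- k_range[which.max(sils)]
    sil <- max(sils)
  } else {
    if (k > n) stop("k cannot exceed the number of regions")
    sil <- if (k >= 2) sil_of(stats::cutree(tree, k)) else NA_real_
  }
  labels <- stats::cutree(tree, k)
  structure(list(cluster = labels, k = k, linkage = linkage,
                 silhouette = sil, tree = tree),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> k = %d (%s linkage, mean silhouette %.3f)\n",
              x$k, x$linkage, x$silhouette))
  print(table(x$cluster))
  invisible(x)
}

#' Nearest-neighbor dataset mixing score
#'
#' For embedded points carrying one of two dataset labels: the mean over
#' points of the fraction of their `k_nn` nearest neighbors sharing their
#' label. Under random mixing the score sits near the expected same-label
#' fraction (returned as `expected_chance`); complete segregation gives 1.
#' This statistic formalizes the visual "do the datasets mix in embedding
#' space" judgment.
#'
#' @param points Points x d coordinate matrix.
#' @param labels Vector with exactly two distinct values, each group of size
#'   >= `k_nn + 1`.
#' @param k_nn Neighborhood size.
#' @return List with `score`, `expected_chance`, `k_nn`.
#' @export
mixing_score <- function(points, labels, k_nn = 5) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) != 2L)
    stop("mixing score needs exactly two dataset labels")
  if (any(tab < k_nn + 1))
    stop("each dataset needs at least k_nn + 1 points")
  nn <- FNN::get.knn(points, k = k_nn)$nn.index
  same <- matrix(labels[nn], nrow = nrow(nn)) == labels
  n <- length(labels)
  chance <- sum((tab / n) * ((tab - 1) / (n - 1)))
  list(score = mean(same), expected_chance = unname(chance), k_nn = k_nn)
}

#' Cross-dataset mixing diagnostic
#'
#' Tests whether two cohorts are statistically comparable over a region
#' subset: the cohorts' per-brain fractions over the subset are jointly
#' z-scored (points are brains, features are regions), embedded as an
#' ensemble, and scored with the nearest-neighbor mixing statistic averaged
#' over embeddings. A permutation null (labels shuffled over brains)
#' calibrates the score: a score near chance with a large p means the
#' datasets mix (are comparable); a score near 1 with small p means they
#' segregate.
#'
#' @param cohort_a,cohort_b `vta_cohort`s quantified over `catalog`.
#' @param catalog A `region_catalog`.
#' @param region_subset `"long_range"`, `"local"`, or a character vector of
#'   region names.
#' @param n_embeddings,seeds,n_neighbors,min_dist Ensemble parameters; the
#'   neighborhood is capped below the number of brains.
#' @param k_nn Mixing-score neighborhood.
#' @param n_perm Number of label permutations for the null.
#' @return List with `score`, `expected_chance`, `p_value`, `null_scores`.
#' @export
compare_datasets <- function(cohort_a, cohort_b, catalog,
                             region_subset = "long_range",
                             n_embeddings = 20,
                             seeds = seq_len(n_embeddings) - 1L,
                             n_neighbors = NULL, min_dist = 0.1,
                             k_nn = 5, n_perm = 100) {
  if (length(region_subset) == 1L &&
      region_subset %in% c("long_range", "local"))
    region_subset <- catalog$name[catalog$locality == region_subset]
  if (length(region_subset) == 0L) stop("empty region subset")
  fa <- fraction_matrix(cohort_a, catalog)
  fb <- fraction_matrix(cohort_b, catalog)
  X <- rbind(unclass(fa)[, region_subset, drop = FALSE],
             unclass(fb)[, region_subset, drop = FALSE])
  labels <- rep(c("a", "b"), c(nrow(fa), nrow(fb)))
  # joint z-score per region across all brains of both cohorts
  Xz <- scale(X)
  Xz[, attr(Xz, "scaled:scale") == 0] <- 0
  if (is.null(n_neighbors)) n_neighbors <- min(10, nrow(Xz) - 1L)
  embs <- embed_ensemble(Xz, n_embeddings, seeds, n_neighbors, min_dist)
  score_for <- function(lab)
    mean(vapply(embs, function(e) mixing_score(e, lab, k_nn)$score,
                numeric(1)))
  obs <- score_for(labels)
  chance <- mixing_score(embs[[1]], labels, k_nn)$expected_chance
  null_scores <- vapply(seq_len(n_perm), function(i)
    score_for(sample(labels)), numeric(1))
  p <- (1 + sum(null_scores >= obs)) / (n_perm + 1)
  list(score = obs, expected_chance = chance, p_value = p,
       null_scores = null_scores)
}
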