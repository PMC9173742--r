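#' Marker co-label rules
#'
#' A co-label rule selects input cells by marker flags: every marker in
#' `require` must be positive and every marker in `exclude` negative.
#' `tc66t` is the mCherry-fused mutant TVA, so "mCherry-negative" and
#' "TC66T-negative" are the same flag.
#'
#' Built-in rules:
#' * GABAergic input: GFP+, GAD+, TC66T- (`gaba_rule()`)
#' * DAergic input:   GFP+, TH+,  TC66T- (`da_rule()`)
#' * Serotonergic:    GFP+, Tph2+        (`serotonin_rule()`)
#'
#' @param require,exclude Character vectors of marker flag names (among
#'   `gfp`, `tc66t`, `gad`, `th`, `tph2`); must be disjoint.
#' @return A `colabel_rule` list.
#' @export
colabel_rule <- function(require = character(), exclude = character()) {
  markers <- c("gfp", "tc66t", "gad", "th", "tph2")
  unknown <- setdiff(c(require, exclude), markers)
  if (length(unknown) > 0L)
    stop("unknown marker(s): ", paste(unknown, collapse = ", "))
  if (length(intersect(require, exclude)) > 0L)
    stop("require and exclude sets must be disjoint")
  structure(list(require = require, exclude = exclude),
            class = "colabel_rule")
}

#' @rdname colabel_rule
#' @export
gaba_rule <- function() colabel_rule(require = c("gfp", "gad"),
                                     exclude = "tc66t")

#' @rdname colabel_rule
#' @export
da_rule <- function() colabel_rule(require = c("gfp", "th"),
                                   exclude = "tc66t")

#' @rdname colabel_rule
#' @export
serotonin_rule <- function() colabel_rule(require = c("gfp", "tph2"))

#' Filter a brain's input cells by a co-label rule
#'
#' Returns exactly the input cells satisfying the rule. Starter cells never
#' pass (they are not inputs, whatever their markers).
#'
#' @param brain A `vta_brain`.
#' @param rule A `colabel_rule`.
#' @return The filtered input-cell table.
#' @export
apply_colabel_rule <- function(brain, rule) {
  stopifnot(inherits(rule, "colabel_rule"))
  cells <- brain$inputs[!brain$inputs$is_starter, , drop = FALSE]
  keep <- rep(TRUE, nrow(cells))
  for (m in rule$require) keep <- keep & cells[[m]]
  for (m in rule$exclude) keep <- keep & !cells[[m]]
  cells[keep, , drop = FALSE]
}

.sem <- function(x) stats::sd(x) / sqrt(length(x))

#' GABAergic input composition
#'
#' Applies the GABA rule (GFP+, GAD+, TC66T-) to each brain and reports the
#' per-region share of GABAergic inputs over the chosen regions (default:
#' all local regions, matching the local-inhibition map). Combined mode
#' averages per-brain shares across brains (mean +/- SEM); separate mode
#' returns the region x hemisphere share table (heatmap form), with midline
#' regions in their own column.
#'
#' @param cohort A `vta_cohort`.
#' @param catalog A `region_catalog`.
#' @param hemispheres `"combined"` or `"separate"`.
#' @param regions Regions over which composition is computed (default local).
#' @return Combined: data frame region/mean_share/sem_share (shares sum to 1).
#'   Separate: regions x c(ipsi, contra, midline) matrix of mean shares.
#' @export
gaba_composition <- function(cohort, catalog,
                             hemispheres = c("combined", "separate"),
                             regions = catalog$name[catalog$locality == "local"]) {
  hemispheres <- match.arg(hemispheres)
  rule <- gaba_rule()
  filt <- lapply(cohort, function(b) {
    g <- apply_colabel_rule(b, rule)
    g <- g[g$region %in% regions, , drop = FALSE]
    if (nrow(g) == 0L)
      stop("brain ", b$brain_id, " has zero GABAergic inputs")
    brain_dataset(b$brain_id, b$starters[0, ], g, condition = b$condition)
  })
  if (hemispheres == "combined") {
    shares <- t(vapply(filt, function(b) {
      cts <- count_by_region(b, catalog)[regions]
      cts / sum(cts)
    }, numeric(length(regions))))
    return(data.frame(region = regions,
                      mean_share = colMeans(shares),
                      sem_share = apply(shares, 2, .sem),
                      row.names = NULL))
  }
  mats <- lapply(filt, function(b) {
    m <- count_by_region(b, catalog, "separate")[regions, , drop = FALSE]
    m / sum(m)
  })
  Reduce(`+`, mats) / length(mats)
}

#' TH+ fraction of eligible inputs per midbrain region of interest
#'
#' Among input cells that are GFP+ and TC66T(mCherry)- and lie outside the
#' sphere of TVA spread around the injection site, the fraction that costain
#' with TH, per region of interest. The default ROIs partition the
#' VTA/RRF by anterior-posterior and medial-lateral coordinate predicates:
#' anterior VTA, posterior-medial VTA, posterior-lateral VTA, and RRF.
#'
#' @param cohort A `vta_cohort`.
#' @param catalog A `region_catalog`.
#' @param rois Named list of predicate functions `f(cells) -> logical`.
#' @param tva_center Numeric (x_ml, y_dv, z_ap) of the injection site.
#' @param tva_radius Radius of TVA spread in micrometres (cells inside are
#'   excluded from the denominator); `NULL` disables the sphere filter.
#' @return Data frame roi/mean_fraction/sem_fraction/mean_n_eligible/
#'   n_brains; ROIs with no
#'   eligible cells in a brain are missing for that brain (not zero) and are
#'   excluded from that ROI's mean.
#' @export
da_colabel_fraction <- function(cohort, catalog,
                                rois = default_da_rois(catalog),
                                tva_center = c(x_ml = 500, y_dv = -4400,
                                               z_ap = -3500),
                                tva_radius = 500) {
  per_brain <- vapply(cohort, function(b) {
    cells <- b$inputs[!b$inputs$is_starter & b$inputs$gfp &
                        !b$inputs$tc66t, , drop = FALSE]
    if (!is.null(tva_radius)) {
      roi_hit <- Reduce(`|`, lapply(rois, function(f) f(cells)))
      need <- which(roi_hit)
      if (length(need) > 0 &&
          anyNA(cells$x_ml[need] + cells$y_dv[need] + cells$z_ap[need]))
        stop("sphere filtering requested but cells lack coordinates")
      d <- sqrt((cells$x_ml - tva_center[["x_ml"]])^2 +
                  (cells$y_dv - tva_center[["y_dv"]])^2 +
                  (cells$z_ap - tva_center[["z_ap"]])^2)
      cells <- cells[is.na(d) | d > tva_radius, , drop = FALSE]
    }
    vapply(rois, function(f) {
      hit <- f(cells)
      n_hit <- sum(hit, na.rm = TRUE)
      if (n_hit == 0L) return(c(NA_real_, 0))
      c(mean(cells$th[which(hit)]), n_hit)
    }, numeric(2))
  }, matrix(numeric(1), 2, length(rois)))
  frac <- matrix(per_brain[1, , ], nrow = length(rois),
                 dimnames = list(names(rois), NULL))
  nelig <- matrix(per_brain[2, , ], nrow = length(rois))
  data.frame(roi = rownames(frac),
             mean_fraction = apply(frac, 1, mean, na.rm = TRUE),
             sem_fraction = apply(frac, 1, function(x) .sem(x[!is.na(x)])),
             mean_n_eligible = rowMeans(nelig),
             n_brains = apply(frac, 1, function(x) sum(!is.na(x))),
             row.names = NULL)
}

#' Default DA-connectivity regions of interest
#'
#' Coordinate predicates on (anterior-posterior, medial-lateral) that carve
#' the VTA into anterior, posterior-medial and posterior-lateral sectors,
#' plus the RRF as its own region. The AP boundary (-3600 um from bregma)
#' and ML boundary (500 um from midline) are configuration, not anatomy.
#'
#' @param catalog A `region_catalog`.
#' @param ap_split,ml_split Sector boundaries in micrometres.
#' @return Named list of predicate functions over a cell table.
#' @export
default_da_rois <- function(catalog, ap_split = -3600, ml_split = 500) {
  vta <- catalog$name[catalog$vta_subnucleus]
  list(
    vta_anterior = function(cells)
      cells$region %in% vta & !is.na(cells$z_ap) & cells$z_ap > ap_split,
    vta_posterior_medial = function(cells)
      cells$region %in% vta & !is.na(cells$z_ap) & cells$z_ap <= ap_split &
        abs(cells$x_ml) < ml_split,
    vta_posterior_lateral = function(cells)
      cells$region %in% vta & !is.na(cells$z_ap) & cells$z_ap <= ap_split &
        abs(cells$x_ml) >= ml_split,
    rrf = function(cells) cells$region == "RRF")
}

#' Estimated DAergic share of total inputs
#'
#' The product of the VTA/RRF share of total inputs and the TH+ co-label
#' fraction, expressed as a percentage: the back-of-envelope estimate of how
#' much of the total input to VTA dopamine cells comes from other dopamine
#' cells.
#'
#' @param vta_rrf_input_share Share of all inputs in the VTA/RRF, in [0,1].
#' @param th_fraction TH+ fraction among eligible inputs there, in [0,1].
#' @return Percentage (e.g. `da_total_estimate(0.11, 0.40)` is 4.4).
#' @export
da_total_estimate <- function(vta_rrf_input_share, th_fraction) {
  if (vta_rrf_input_share < 0 || vta_rrf_input_share > 1 ||
      th_fraction < 0 || th_fraction > 1)
    stop("both arguments must be in [0, 1]")
  vta_rrf_input_share * th_fraction * 100
}

#' Serotonergic input summary
#'
#' For every serotonergic region (B-groups) and hemisphere (midline regions
#' DR/RMg/MnR are never split), the fraction of that region's inputs that
#' costain with Tph2 and the Tph2+ count per 10,000 total labeled inputs,
#' as mean +/- SEM across brains. Region-hemisphere cells with no inputs in
#' a brain are missing for that brain, not zero.
#'
#' @param cohort A `vta_cohort`.
#' @param catalog A `region_catalog`.
#' @return Data frame region/group/hemisphere/mean_fraction/sem_fraction/
#'   mean_per_10k/sem_per_10k/n_brains.
#' @export
serotonin_summary <- function(cohort, catalog) {
  sero <- serotonergic_regions(catalog)
  if (nrow(sero) == 0L) stop("catalog has no serotonergic regions")
  cells_keys <- do.call(rbind, lapply(seq_len(nrow(sero)), function(i) {
    sides <- if (sero$midline[i]) "midline" else c("ipsi", "contra")
    data.frame(region = sero$name[i], group = sero$serotonergic_group[i],
               hemisphere = sides, stringsAsFactors = FALSE)
  }))
  stats_per_brain <- lapply(cohort, function(b) {
    inputs <- b$inputs[!b$inputs$is_starter, , drop = FALSE]
    total <- nrow(inputs)
    res <- lapply(seq_len(nrow(cells_keys)), function(j) {
      k <- cells_keys[j, ]
      sel <- inputs$region == k$region &
        (k$hemisphere == "midline" | inputs$hemisphere == k$hemisphere)
      n <- sum(sel)
      if (n == 0L) return(c(frac = NA_real_, per10k = NA_real_))
      npos <- sum(inputs$tph2[sel])
      c(frac = npos / n, per10k = per_10k_normalization(npos, total))
    })
    do.call(rbind, res)
  })
  frac <- sapply(stats_per_brain, function(m) m[, "frac"])
  p10k <- sapply(stats_per_brain, function(m) m[, "per10k"])
  frac <- matrix(frac, nrow = nrow(cells_keys))
  p10k <- matrix(p10k, nrow = nrow(cells_keys))
  row_mean <- function(m) apply(m, 1, mean, na.rm = TRUE)
  row_sem <- function(m) apply(m, 1, function(x) .sem(x[!is.na(x)]))
  cbind(cells_keys,
        data.frame(mean_fraction = row_mean(frac),
                   sem_fraction = row_sem(frac),
                   mean_per_10k = row_mean(p10k),
                   sem_per_10k = row_sem(p10k),
                   n_brains = apply(frac, 1, function(x) sum(!is.na(x)))))
}
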