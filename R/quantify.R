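#' Count input cells by region
#'
#' Counts RABV-labeled input cells (never starters) per catalog region,
#' either with hemispheres combined or reported separately. Midline regions
#' (DR, RMg, MnR in the default catalog) are always reported as a single
#' midline column, since their left and right populations cannot be
#' separated.
#'
#' @param brain A `vta_brain`.
#' @param catalog A `region_catalog`.
#' @param hemispheres `"combined"` or `"separate"`.
#' @return Combined mode: named integer vector over catalog regions.
#'   Separate mode: regions x c(ipsi, contra, midline) integer matrix.
#' @export
count_by_region <- function(brain, catalog,
                            hemispheres = c("combined", "separate")) {
  hemispheres <- match.arg(hemispheres)
  inputs <- brain$inputs[!brain$inputs$is_starter, , drop = FALSE]
  region <- resolve_region(inputs$region, catalog)
  if (hemispheres == "combined") {
    counts <- integer(nrow(catalog))
    names(counts) <- catalog$name
    tab <- table(region)
    counts[names(tab)] <- as.integer(tab)
    return(counts)
  }
  sides <- c("ipsi", "contra", "midline")
  m <- matrix(0L, nrow(catalog), 3L, dimnames = list(catalog$name, sides))
  midline <- catalog$midline[match(region, catalog$name)]
  hemi <- ifelse(midline, "midline", inputs$hemisphere)
  if (any(hemi == "midline" & !midline))
    stop("non-midline region recorded with hemisphere 'midline'")
  tab <- table(region, factor(hemi, levels = sides))
  m[rownames(tab), colnames(tab)] <- as.integer(tab)
  m
}

#' Fractional input counts per brain
#'
#' The brains x regions matrix of input fractions: each brain's per-region
#' input count divided by its total input count over the chosen denominator
#' (all 57 regions, or the long-range regions only).
#'
#' @param cohort A `vta_cohort` or list of `vta_brain`.
#' @param catalog A `region_catalog`.
#' @param denominator `"all_inputs"` or `"long_range_only"`.
#' @return A `fraction_matrix`: brains x regions numeric matrix with a
#'   `denominator` attribute. Rows sum to 1.
#' @export
fraction_matrix <- function(cohort, catalog,
                            denominator = c("all_inputs", "long_range_only")) {
  denominator <- match.arg(denominator)
  counts <- t(vapply(cohort, count_by_region, integer(nrow(catalog)),
                     catalog = catalog))
  rownames(counts) <- vapply(cohort, function(b) b$brain_id, character(1))
  if (denominator == "long_range_only")
    counts <- counts[, catalog$locality == "long_range", drop = FALSE]
  totals <- rowSums(counts)
  if (any(totals == 0))
    stop("brain(s) with zero input cells in the chosen denominator: ",
         paste(rownames(counts)[totals == 0], collapse = ", "))
  f <- counts / totals
  structure(f, denominator = denominator, class = c("fraction_matrix",
                                                    class(f)))
}

#' Local vs long-range input shares
#'
#' Per-brain share of inputs in local vs long-range regions, plus the cohort
#' mean and standard error.
#'
#' @param fractions A `fraction_matrix` over all inputs.
#' @param catalog A `region_catalog`.
#' @return List with `per_brain` (data frame brain/local/long_range),
#'   `mean_local`, `sem_local`.
#' @export
local_long_split <- function(fractions, catalog) {
  if (!identical(attr(fractions, "denominator"), "all_inputs"))
    stop("local/long split requires denominator = 'all_inputs'")
  loc <- catalog$locality[match(colnames(fractions), catalog$name)] == "local"
  local_share <- rowSums(fractions[, loc, drop = FALSE])
  per_brain <- data.frame(brain_id = rownames(fractions),
                          local = local_share, long_range = 1 - local_share,
                          row.names = NULL)
  list(per_brain = per_brain,
       mean_local = mean(local_share),
       sem_local = stats::sd(local_share) / sqrt(length(local_share)))
}

#' Convergence index of a brain
#'
#' The ratio of long-range RABV-labeled input cells to starter cells. Only
#' long-range inputs enter the numerator, which makes the index comparable
#' across TVA variants with different local background.
#'
#' @param brain A `vta_brain` with at least one starter cell.
#' @param catalog A `region_catalog`.
#' @return A single nonnegative number.
#' @examples
#' # 8,000 long-range inputs over 1,000 starters gives 8
#' @export
convergence_index <- function(brain, catalog) {
  n_start <- nrow(brain$starters)
  if (n_start == 0L) stop("convergence index undefined with zero starters")
  counts <- count_by_region(brain, catalog)
  sum(counts[catalog$locality == "long_range"]) / n_start
}

#' Normalize a count per 10,000 labeled inputs
#'
#' @param count Input count(s) in a region.
#' @param total_inputs Total labeled inputs in the brain (> 0).
#' @return `count / total_inputs * 10000`.
#' @export
per_10k_normalization <- function(count, total_inputs) {
  if (any(total_inputs <= 0)) stop("total_inputs must be positive")
  if (any(count > total_inputs)) stop("count cannot exceed total_inputs")
  count / total_inputs * 10000
}

#' Starter-cell composition over VTA subnuclei
#'
#' Fraction of starter cells in each ventral-midbrain subnucleus (PBP, PN,
#' IF, SNc, Rli, other), summing to 1.
#'
#' @param brain A `vta_brain` with starter cells.
#' @param catalog A `region_catalog`.
#' @return Named numeric vector over c(PBP, PN, IF, SNc, Rli, other).
#' @export
starter_composition <- function(brain, catalog) {
  if (nrow(brain$starters) == 0L) stop("no starter cells")
  sub <- c("PBP", "PN", "IF", "SNc", "Rli")
  region <- resolve_region(brain$starters$region, catalog)
  grp <- ifelse(region %in% sub, region, "other")
  out <- numeric(length(sub) + 1L)
  names(out) <- c(sub, "other")
  tab <- table(grp) / length(grp)
  out[names(tab)] <- as.numeric(tab)
  out
}

#' Starter-cell ellipse summary
#'
#' Center of mass and per-axis spread of starter cells: the ellipse center is
#' the mean (x_ml, y_dv) coordinate and the radii are one sample standard
#' deviation along each axis, the convention used for starter-distribution
#' ovals.
#'
#' @param starters Starter-cell table with `x_ml`, `y_dv` columns.
#' @return List with `center_ml`, `center_dv`, `radius_ml`, `radius_dv`
#'   (micrometres). A single cell gives radii 0.
#' @export
starter_ellipse <- function(starters) {
  ok <- !is.na(starters$x_ml) & !is.na(starters$y_dv)
  if (!any(ok)) stop("no starter cells with coordinates")
  x <- starters$x_ml[ok]
  y <- starters$y_dv[ok]
  sdz <- function(v) if (length(v) < 2L) 0 else stats::sd(v)
  list(center_ml = mean(x), center_dv = mean(y),
       radius_ml = sdz(x), radius_dv = sdz(y))
}

#' Two-group comparison (unpaired t-test)
#'
#' Two-sided unpaired Student t-test with pooled variance (the convention
#' for equal-n group comparisons here); Welch's correction available via
#' `pooled = FALSE`.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param pooled Use the pooled-variance (Student) test; `FALSE` for Welch.
#' @return List with `t`, `df`, `p`, `ci` (95% CI of the mean difference).
#' @export
compare_groups <- function(values_a, values_b, pooled = TRUE) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs at least 2 observations")
  ht <- stats::t.test(values_a, values_b, var.equal = pooled)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, ci = unname(ht$conf.int))
}
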