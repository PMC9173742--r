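#' Run configuration for the end-to-end pipeline
#'
#' @param out_dir Output directory for stage CSVs and the YAML report.
#' @param cohort_dir Directory with an on-disk cohort ([read_cohort()]);
#'   `NULL` simulates a cohort from `generator` instead.
#' @param generator A `generator_config` used when simulating.
#' @param stages Character subset of
#'   `c("quantify", "colabel", "embed", "profile")`.
#' @param n_embeddings,embed_seeds,k,linkage Embedding/clustering settings
#'   (`k = NULL` selects by silhouette).
#' @param tva_radius TVA-spread sphere radius (micrometres) for the DA map.
#' @param hemispheres Hemisphere mode for composition tables.
#' @param profile_noise,profile_seed Synthetic-image settings for the
#'   profile stage.
#' @param seed Master seed; stage seeds derive from it.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir,
                       cohort_dir = NULL,
                       generator = generator_config(),
                       stages = c("quantify", "colabel", "embed", "profile"),
                       n_embeddings = 20,
                       embed_seeds = seq_len(n_embeddings) - 1L,
                       k = NULL, linkage = "average",
                       tva_radius = 500,
                       hemispheres = "combined",
                       profile_noise = 0.1,
                       profile_seed = 7L,
                       seed = 1L) {
  stages <- match.arg(stages, c("quantify", "colabel", "embed", "profile"),
                      several.ok = TRUE)
  if ("embed" %in% stages && length(embed_seeds) == 0L)
    stop("embedding enabled but no seeds given")
  if (!is.null(cohort_dir) && !dir.exists(cohort_dir))
    stop("cohort_dir does not exist: ", cohort_dir)
  structure(list(out_dir = out_dir, cohort_dir = cohort_dir,
                 generator = generator, stages = stages,
                 n_embeddings = n_embeddings, embed_seeds = embed_seeds,
                 k = k, linkage = linkage, tva_radius = tva_radius,
                 hemispheres = hemispheres, profile_noise = profile_noise,
                 profile_seed = as.integer(profile_seed),
                 seed = as.integer(seed)),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the pipeline end to end
#'
#' Executes generate (or load) -> quantify -> colabel -> embed/cluster ->
#' profile, writing tidy CSVs named after the figure each table mirrors
#' (`fig1i_fractions.csv`, `fig4g_composition.csv`, ...) plus a YAML report
#' with per-brain convergence indices, the local/long split, composition
#' summaries, cluster assignment and profile checks. Re-running with the
#' same config and seed reproduces the report exactly.
#'
#' @param config A `run_config`.
#' @param catalog A `region_catalog`.
#' @return The report list, invisibly; also written to
#'   `<out_dir>/report.yaml`.
#' @export
run_pipeline <- function(config, catalog = load_default_catalog()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed, stages = config$stages,
                 embed_seeds = as.integer(config$embed_seeds))

  cohort <- .stage("input", {
    if (!is.null(config$cohort_dir)) read_cohort(config$cohort_dir)
    else {
      gen <- config$generator
      gen$seed <- config$seed
      generate_cohort(gen)
    }
  })
  violations <- validate_cohort(cohort, catalog)
  report$n_brains <- length(cohort)
  report$validation_violations <- nrow(violations)

  if ("quantify" %in% config$stages) {
    .stage("quantify", {
      fr <- fraction_matrix(cohort, catalog)
      utils::write.csv(data.frame(region = colnames(fr),
                                  t(unclass(fr)), check.names = FALSE),
                       file.path(config$out_dir, "fig1i_fractions.csv"),
                       row.names = FALSE)
      split <- local_long_split(fr, catalog)
      utils::write.csv(split$per_brain,
                       file.path(config$out_dir, "fig1j_local_long.csv"),
                       row.names = FALSE)
      ci <- vapply(cohort, convergence_index, numeric(1), catalog = catalog)
      names(ci) <- vapply(cohort, function(b) b$brain_id, character(1))
      comp <- t(vapply(cohort, starter_composition, numeric(6),
                       catalog = catalog))
      utils::write.csv(data.frame(brain_id = names(ci),
                                  convergence_index = ci, comp,
                                  row.names = NULL),
                       file.path(config$out_dir, "fig1fh_starters.csv"),
                       row.names = FALSE)
      report$convergence_index <- as.list(round(ci, 4))
      report$mean_convergence_index <- mean(ci)
      report$local_share <- list(mean = split$mean_local,
                                  sem = split$sem_local)
      report$total_inputs <- sum(vapply(cohort, function(b)
        nrow(b$inputs), integer(1)))
      report$fraction_regions <- ncol(fr)
    })
  }

  if ("colabel" %in% config$stages) {
    .stage("colabel", {
      gc_tab <- gaba_composition(cohort, catalog,
                                 hemispheres = config$hemispheres)
      utils::write.csv(gc_tab,
                       file.path(config$out_dir, "fig4g_composition.csv"),
                       row.names = FALSE)
      heat <- gaba_composition(cohort, catalog, hemispheres = "separate")
      utils::write.csv(data.frame(region = rownames(heat), heat,
                                  row.names = NULL),
                       file.path(config$out_dir, "fig4f_heatmap.csv"),
                       row.names = FALSE)
      da <- da_colabel_fraction(cohort, catalog,
                                tva_radius = config$tva_radius)
      utils::write.csv(da,
                       file.path(config$out_dir, "fig5f_th_fractions.csv"),
                       row.names = FALSE)
      sero <- serotonin_summary(cohort, catalog)
      utils::write.csv(sero,
                       file.path(config$out_dir, "fig6cd_serotonin.csv"),
                       row.names = FALSE)
      top <- gc_tab$region[which.max(gc_tab$mean_share)]
      report$gaba_top_region <- top
      report$da_th_fraction <-
        stats::weighted.mean(da$mean_fraction, da$n_brains, na.rm = TRUE)
    })
  }

  if ("embed" %in% config$stages) {
    .stage("embed", {
      fr <- fraction_matrix(cohort, catalog)
      agg <- aggregated_region_distance(fr,
                                        n_embeddings = config$n_embeddings,
                                        seeds = config$embed_seeds)
      utils::write.csv(data.frame(region = rownames(agg), unclass(agg),
                                  check.names = FALSE, row.names = NULL),
                       file.path(config$out_dir, "fig2d_distances.csv"),
                       row.names = FALSE)
      cl <- cluster_regions(agg, k = config$k, linkage = config$linkage)
      utils::write.csv(data.frame(region = names(cl$cluster),
                                  cluster = unname(cl$cluster)),
                       file.path(config$out_dir, "fig2d_clusters.csv"),
                       row.names = FALSE)
      report$clusters <- list(k = cl$k, silhouette = cl$silhouette,
                               linkage = cl$linkage)
    })
  }

  if ("profile" %in% config$stages) {
    .stage("profile", {
      archetypes <- c("lateral", "uniform", "medial")
      profs <- lapply(archetypes, function(a) {
        imgs <- lapply(1:3, function(i)
          generate_axon_image(a, noise = config$profile_noise,
                              seed = config$profile_seed + i +
                                100L * match(a, archetypes)))
        line <- profile_line(c(60, 1), c(60, ncol(imgs[[1]])))
        average_profiles(lapply(imgs, image_profile, line = line),
                         level_out = "cluster")
      })
      names(profs) <- archetypes
      utils::write.csv(data.frame(bin = seq_along(profs[[1]]),
                                  lateral = as.numeric(profs$lateral),
                                  uniform = as.numeric(profs$uniform),
                                  medial = as.numeric(profs$medial)),
                       file.path(config$out_dir, "fig3e_profiles.csv"),
                       row.names = FALSE)
      report$profile_bins <- length(profs[[1]])
    })
  }

  yaml::write_yaml(report, file.path(config$out_dir, "report.yaml"))
  invisible(report)
}
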