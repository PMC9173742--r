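# Shared fixtures, built in code once per test run.

CAT <- load_default_catalog()

# Hand-built brain: explicit cells with known counts and markers.
toy_cells <- function(region, n = 1, hemisphere = "ipsi", gfp = TRUE,
                      tc66t = FALSE, gad = FALSE, th = FALSE, tph2 = FALSE,
                      is_starter = FALSE, x_ml = NA_real_, y_dv = NA_real_,
                      z_ap = NA_real_, brain_id = "toy") {
  region <- rep(region, n)
  m <- length(region)
  data.frame(brain_id = rep_len(brain_id, m), region = region,
             hemisphere = rep_len(hemisphere, m), x_ml = rep_len(x_ml, m),
             y_dv = rep_len(y_dv, m), z_ap = rep_len(z_ap, m),
             gfp = rep_len(gfp, m), tc66t = rep_len(tc66t, m),
             gad = rep_len(gad, m), th = rep_len(th, m),
             tph2 = rep_len(tph2, m), is_starter = rep_len(is_starter, m),
             stringsAsFactors = FALSE)
}

toy_brain <- function(inputs, starters = NULL, brain_id = "toy") {
  if (is.null(starters))
    starters <- toy_cells("PBP", 1, tc66t = TRUE, th = TRUE,
                          is_starter = TRUE, x_ml = 500, y_dv = -4400,
                          z_ap = -3500, brain_id = brain_id)
  brain_dataset(brain_id, starters, inputs)
}

# A 4-brain cohort at the default study conditions (memoized).
cohort4 <- local({
  coh <- NULL
  function() {
    if (is.null(coh)) coh <<- generate_cohort(generator_config(n_brains = 4,
                                                               seed = 42))
    coh
  }
})

# A 50-brain cohort for rate-recovery checks (memoized; shared across files).
cohort50 <- local({
  coh <- NULL
  function() {
    if (is.null(coh)) coh <<- generate_cohort(generator_config(n_brains = 50,
                                                               seed = 7))
    coh
  }
})
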