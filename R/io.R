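#' Write a cohort to disk
#'
#' One cells CSV per brain (starters and inputs in one table, distinguished
#' by `is_starter`) plus a YAML manifest listing the brains, their
#' conditions, and the file names.
#'
#' @param cohort A `vta_cohort` or list of `vta_brain`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(cohort, function(b) {
    file <- paste0(b$brain_id, "_cells.csv")
    cells <- rbind(b$starters, b$inputs)
    utils::write.csv(cells, file.path(dir, file), row.names = FALSE)
    list(brain_id = b$brain_id, condition = b$condition, cells = file)
  })
  manifest <- list(format = "vtatrace-cohort-1", brains = entries)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Read a cohort from disk
#'
#' @param dir Directory containing `manifest.yaml` and the cells CSVs
#'   written by [write_cohort()].
#' @return A `vta_cohort`.
#' @export
read_cohort <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  brains <- lapply(manifest$brains, function(e) {
    cells <- utils::read.csv(file.path(dir, e$cells),
                             stringsAsFactors = FALSE)
    for (col in c("gfp", "tc66t", "gad", "th", "tph2", "is_starter"))
      cells[[col]] <- as.logical(cells[[col]])
    brain_dataset(e$brain_id,
                  starters = cells[cells$is_starter, , drop = FALSE],
                  inputs = cells[!cells$is_starter, , drop = FALSE],
                  condition = e$condition)
  })
  structure(brains, class = "vta_cohort")
}

#' Validate a cohort against the schema and a catalog
#'
#' Checks (without aborting): required columns present, region names known
#' to the catalog, starter/input disjointness and flag consistency (starters
#' GFP+ and TC66T+; inputs GFP+ and TC66T-), marker-flag completeness, and
#' hemisphere values.
#'
#' @param cohort A `vta_cohort`.
#' @param catalog A `region_catalog`.
#' @return Data frame of violations (zero rows if clean) with columns
#'   `brain_id`, `check`, `detail`.
#' @export
validate_cohort <- function(cohort, catalog) {
  required <- c("brain_id", "region", "hemisphere", "gfp", "tc66t", "gad",
                "th", "tph2", "is_starter")
  out <- list()
  note <- function(brain_id, check, detail)
    out[[length(out) + 1L]] <<- data.frame(brain_id = brain_id,
                                           check = check, detail = detail)
  for (b in cohort) {
    cells <- rbind(b$starters, b$inputs)
    missing <- setdiff(required, names(cells))
    if (length(missing) > 0L) {
      note(b$brain_id, "schema",
           paste("missing columns:", paste(missing, collapse = ", ")))
      next
    }
    unknown <- tryCatch({resolve_region(cells$region, catalog); character(0)},
                        error = function(e) conditionMessage(e))
    if (length(unknown) > 0L && nzchar(unknown[1]))
      note(b$brain_id, "region", unknown)
    if (any(b$starters$is_starter == FALSE) || any(b$inputs$is_starter))
      note(b$brain_id, "disjoint", "starter/input tables mislabeled")
    st <- b$starters
    if (any(!st$gfp | !st$tc66t))
      note(b$brain_id, "starter_flags",
           "starter cells must be GFP+ and TC66T+")
    if (any(!b$inputs$gfp | b$inputs$tc66t))
      note(b$brain_id, "input_flags",
           "input cells must be GFP+ and TC66T-")
    for (col in c("gfp", "tc66t", "gad", "th", "tph2"))
      if (anyNA(cells[[col]]))
        note(b$brain_id, "marker_na", paste("NA in marker flag", col))
    badh <- setdiff(unique(cells$hemisphere), c("ipsi", "contra", "midline"))
    if (length(badh) > 0L)
      note(b$brain_id, "hemisphere",
           paste("unknown hemisphere:", paste(badh, collapse = ", ")))
  }
  if (length(out) == 0L)
    return(data.frame(brain_id = character(0), check = character(0),
                      detail = character(0)))
  do.call(rbind, out)
}
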