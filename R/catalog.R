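#' Region catalogs for VTA input quantification
#'
#' A region catalog is the fixed frame of reference for all counting stages:
#' an ordered table of quantified input regions, each classed as `long_range`
#' (forebrain and other sites more than ~1 mm from the injection site) or
#' `local` (ventral midbrain / hindbrain sites near the VTA, including
#' posterior sites kept local by convention), flagged as midline where left
#' and right populations cannot be separated, as a VTA subnucleus
#' (PBP/PN/IF/Rli), and annotated with the serotonergic cell-group (B3-B9)
#' it contains, if any.
#'
#' The default catalog has 57 regions: 22 long-range and 35 local. The
#' long-range membership is reconstructed from published input-mapping work
#' (the full list is not printed in any single table) and is shipped as a
#' versioned CSV so edits are configuration, not code.
#'
#' @param path Path to a catalog CSV with columns `name`, `full_name`,
#'   `locality`, `midline`, `vta_subnucleus`, `serotonergic_group`.
#' @return A `region_catalog`: a data frame with the columns above plus a
#'   `version` attribute. Row order is stable and defines matrix column order
#'   throughout the package.
#' @examples
#' cat57 <- load_default_catalog()
#' table(cat57$locality)
#' @export
load_default_catalog <- function() {
  path <- system.file("extdata", "region_catalog.csv", package = "vtatrace",
                      mustWork = TRUE)
  load_catalog(path, version = "default-1")
}

#' @rdname load_default_catalog
#' @param version Version string stored on the catalog.
#' @export
load_catalog <- function(path, version = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("name", "full_name", "locality", "midline",
                "vta_subnucleus", "serotonergic_group")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("catalog is missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(tolower(df$name)))
    stop("catalog region names must be unique (case-insensitive)")
  bad <- setdiff(unique(df$locality), c("long_range", "local"))
  if (length(bad) > 0L)
    stop("unknown locality class: ", paste(bad, collapse = ", "))
  df$midline <- as.logical(df$midline)
  df$vta_subnucleus <- as.logical(df$vta_subnucleus)
  attr(df, "version") <- version
  class(df) <- c("region_catalog", "data.frame")
  df
}

#' @export
print.region_catalog <- function(x, ...) {
  cat(sprintf("Region catalog '%s': %d regions (%d long-range, %d local)\n",
              attr(x, "version"), nrow(x),
              sum(x$locality == "long_range"), sum(x$locality == "local")))
  cat(sprintf("  midline: %s\n", paste(x$name[x$midline], collapse = ", ")))
  invisible(x)
}

# Alias table: figure legends use both "VTA PBP" and "PBP" style labels.
.region_aliases <- c(
  "vta pbp" = "PBP", "vta pn" = "PN", "vta if" = "IF", "vta rli" = "Rli",
  "sept" = "septum", "ctx" = "cortex", "nacmed shell" = "NAcMed",
  "naclat shell" = "NAcLat"
)

#' Resolve a region name against a catalog
#'
#' Matching is case-insensitive on the short label, with a small alias table
#' (e.g. "VTA PBP" resolves to "PBP").
#'
#' @param region_name Character vector of region labels.
#' @param catalog A `region_catalog`.
#' @return Canonical region names (character).
#' @export
resolve_region <- function(region_name, catalog) {
  key <- tolower(trimws(region_name))
  aliased <- .region_aliases[key]
  key <- ifelse(is.na(aliased), key, tolower(aliased))
  idx <- match(key, tolower(catalog$name))
  if (anyNA(idx)) {
    unknown <- unique(region_name[is.na(idx)])
    stop("unknown region name(s): ", paste(unknown, collapse = ", "))
  }
  catalog$name[idx]
}

#' Locality class of a region
#'
#' Returns `"long_range"` or `"local"`. "Local" follows the tracing
#' convention of sites within ~1 mm of the injection plus the posterior
#' ventral midbrain, so posterior sites beyond 1 mm still count as local.
#'
#' @inheritParams resolve_region
#' @return Character vector of locality classes.
#' @examples
#' cat57 <- load_default_catalog()
#' classify_locality(c("SNr", "NAcLat"), cat57)
#' @export
classify_locality <- function(region_name, catalog) {
  nm <- resolve_region(region_name, catalog)
  catalog$locality[match(nm, catalog$name)]
}

#' Regions containing serotonergic cell groups
#'
#' @param catalog A `region_catalog`.
#' @return The catalog rows with `serotonergic_group != "none"` (B3, B5, B6,
#'   B7, B8, B9 in the default catalog).
#' @export
serotonergic_regions <- function(catalog) {
  catalog[catalog$serotonergic_group != "none", , drop = FALSE]
}

#' Write a catalog back to CSV
#'
#' @param catalog A `region_catalog`.
#' @param path Output CSV path.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.csv(as.data.frame(catalog)[, c("name", "full_name", "locality",
                                              "midline", "vta_subnucleus",
                                              "serotonergic_group")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
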