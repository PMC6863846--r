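# IUCN cross-tabulation and the extent summary table.

#' Cross-tabulate species sets against IUCN categories
#'
#' Counts evaluated species per category for each extent, with percentages
#' relative to the first (country-total) column and two roll-up rows:
#' "Conservation concern" and "Total". By default conservation concern
#' includes NT (EX + EW + CR + EN + VU + NT); `concern_includes_nt = FALSE`
#' restricts the roll-up to EX-VU.
#'
#' @param species_sets named list of character vectors of accepted names,
#'   first element the country-total reference set.
#' @param redlist data.frame (`species`, `category`).
#' @param concern_includes_nt include NT in the roll-up (default TRUE).
#' @return a `crosstab_report` data.frame: one row per category plus
#'   roll-ups; per extent a count column and (except the reference) a pct
#'   column.
#' @export
iucn_crosstab <- function(species_sets, redlist,
                          concern_includes_nt = TRUE) {
  stopifnot(length(species_sets) >= 1, !is.null(names(species_sets)))
  bad <- setdiff(unique(redlist$category), iucn_categories)
  if (length(bad)) stop("unknown IUCN categories: ", paste(bad, collapse = ", "))
  concern_cats <- if (concern_includes_nt) c("EX", "EW", "CR", "EN", "VU", "NT")
                  else c("EX", "EW", "CR", "EN", "VU")
  counts <- vapply(species_sets, function(spp) {
    cat_of <- redlist$category[match(spp, redlist$species)]
    c(vapply(iucn_categories, function(cc) sum(cat_of == cc, na.rm = TRUE),
             integer(1)),
      concern = sum(cat_of %in% concern_cats),
      total = sum(!is.na(cat_of)))
  }, integer(length(iucn_categories) + 2))
  rows <- c(iucn_categories, "Conservation concern", "Total")
  out <- data.frame(category = rows, stringsAsFactors = FALSE)
  ref <- counts[, 1]
  for (j in seq_along(species_sets)) {
    nm <- names(species_sets)[j]
    out[[paste0(nm, "_taxa")]] <- counts[, j]
    if (j > 1)
      out[[paste0(nm, "_pct")]] <-
        ifelse(ref > 0, pct_of(counts[, j], pmax(ref, 1)), 0)
  }
  structure(out, concern_includes_nt = concern_includes_nt,
            class = c("crosstab_report", "data.frame"))
}

#' Extent summary table
#'
#' One column per extent (first = country total): area, record count, taxon
#' count, extent-endemic count and maximum 50 km-cell richness, each with
#' its percentage of the country-total column.
#'
#' @param extents named list; each element a list with fields `area_km2`,
#'   `n_records`, `n_taxa`, `n_endemics`, `max_cell_richness`.
#' @return a `summary_table` data.frame with a `parameter` column and per
#'   extent value/pct columns.
#' @export
summary_table <- function(extents) {
  stopifnot(length(extents) >= 1, !is.null(names(extents)))
  fields <- c(area_km2 = "Area, km2", n_records = "Number of records",
              n_taxa = "Number of taxa",
              n_endemics = "Number of endemic taxa",
              max_cell_richness = "Max 50 km cell richness")
  out <- data.frame(parameter = unname(fields), stringsAsFactors = FALSE)
  ref <- unlist(extents[[1]][names(fields)])
  for (j in seq_along(extents)) {
    v <- unlist(extents[[j]][names(fields)])
    out[[paste0(names(extents)[j], "_value")]] <- unname(v)
    if (j > 1)
      out[[paste0(names(extents)[j], "_pct")]] <- unname(pct_of(v, ref))
  }
  structure(out, class = c("summary_table", "data.frame"))
}

#' Published worked-example count tables
#'
#' The printed counts of the study's summary tables (extent summary,
#' backbone congruence, IUCN cross-tab), shipped as CSV fixtures so the
#' percentage arithmetic can be recomputed and machine-checked.
#'
#' @param which one of "extents", "backbones", "iucn".
#' @return data.frame of printed counts.
#' @export
published_counts <- function(which = c("extents", "backbones", "iucn")) {
  which <- match.arg(which)
  f <- c(extents = "published_extent_counts.csv",
         backbones = "published_backbone_counts.csv",
         iucn = "published_iucn_counts.csv")[[which]]
  utils::read.csv(system.file("extdata", f, package = "karstflora"),
                  stringsAsFactors = FALSE)
}
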