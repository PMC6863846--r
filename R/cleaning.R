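# Coordinate cleaning and taxonomic reconciliation.
#
# The coordinate filter applies a fixed sequence of standard occurrence
# tests (zero coordinates, out-of-range, lat == lon, country mismatch,
# off-land, country-centroid proximity); each step is individually
# switchable and the report names every step so the bookkeeping is
# auditable. Name matching is exact on the whitespace-normalized binomial;
# synonym chains are assumed pre-flattened to one hop.

clean_step_names <- c("zero_coordinates", "out_of_range", "lat_equals_lon",
                      "country_mismatch", "not_on_land", "centroid_proximity")

#' Options for the coordinate cleaner
#'
#' @param steps character vector of steps to run (default all six).
#' @param lon_range,lat_range valid coordinate ranges; the WGS84 defaults
#'   apply to degree data, planar landscapes pass their bounding box.
#' @param centroid_radius_km exclusion radius around country centroids.
#' @return a list of options.
#' @export
clean_options <- function(steps = clean_step_names,
                          lon_range = c(-180, 180), lat_range = c(-90, 90),
                          centroid_radius_km = 10) {
  bad <- setdiff(steps, clean_step_names)
  if (length(bad)) stop("unknown cleaning step(s): ", paste(bad, collapse = ", "))
  list(steps = steps, lon_range = lon_range, lat_range = lat_range,
       centroid_radius_km = centroid_radius_km)
}

#' Coordinate-validity filtering with per-step bookkeeping
#'
#' Applies, in fixed order: (1) drop records whose coordinates are missing
#' or both exactly zero; (2) drop out-of-range coordinates; (3) drop
#' lat == lon exactly; (4) drop records whose country attribute mismatches
#' the containing country polygon; (5) drop records not on land; (6) drop
#' records within `centroid_radius_km` of a country centroid.
#'
#' @param records occurrence data.frame (pipeline CSV dialect).
#' @param land_polygons `karst_extent` of land, or NULL to skip step 5.
#' @param country_polygons named list of `karst_extent`s keyed by country
#'   code, or NULL to skip steps 4 and 6.
#' @param options from [clean_options()].
#' @return list with `records` (retained rows) and `report` (a
#'   `clean_report` data.frame: step, removed, plus attributes `input`,
#'   `retained`, `pct_lost`).
#' @export
clean_coordinates <- function(records, land_polygons = NULL,
                              country_polygons = NULL,
                              options = clean_options()) {
  if (!is.null(land_polygons) && !inherits(land_polygons, "karst_extent"))
    stop("'land_polygons' must be a karst_extent")
  if (!is.null(country_polygons) &&
      (!is.list(country_polygons) || is.null(names(country_polygons)) ||
       !all(vapply(country_polygons, inherits, TRUE, "karst_extent"))))
    stop("'country_polygons' must be a named list of karst_extent objects")
  n_in <- nrow(records)
  removed <- setNames(integer(length(clean_step_names)), clean_step_names)
  keep <- records
  drop_by <- function(flag, step) {
    flag[is.na(flag)] <- TRUE
    removed[[step]] <<- sum(flag)
    keep <<- keep[!flag, , drop = FALSE]
  }
  lon <- function() keep$decimal_longitude
  lat <- function() keep$decimal_latitude
  run <- function(s) s %in% options$steps && nrow(keep) > 0

  if (run("zero_coordinates"))
    drop_by(is.na(lon()) | is.na(lat()) | (lon() == 0 & lat() == 0),
            "zero_coordinates")
  if (run("out_of_range"))
    drop_by(lon() < options$lon_range[1] | lon() > options$lon_range[2] |
              lat() < options$lat_range[1] | lat() > options$lat_range[2],
            "out_of_range")
  if (run("lat_equals_lon"))
    drop_by(lon() == lat(), "lat_equals_lon")
  if (run("country_mismatch") && !is.null(country_polygons)) {
    inside_own <- rep(FALSE, nrow(keep))
    for (cc in names(country_polygons)) {
      sel <- keep$country == cc
      if (any(sel))
        inside_own[sel] <- point_in_extent(lon()[sel], lat()[sel],
                                           country_polygons[[cc]])
    }
    drop_by(!inside_own, "country_mismatch")
  }
  if (run("not_on_land") && !is.null(land_polygons))
    drop_by(!point_in_extent(lon(), lat(), land_polygons), "not_on_land")
  if (run("centroid_proximity") && !is.null(country_polygons)) {
    centroids <- t(vapply(country_polygons, function(e) {
      xy <- do.call(rbind, e$polygons)
      c(mean(range(xy[, 1])), mean(range(xy[, 2])))
    }, numeric(2)))
    near <- rep(FALSE, nrow(keep))
    for (i in seq_len(nrow(centroids)))
      near <- near | sqrt((lon() - centroids[i, 1])^2 +
                            (lat() - centroids[i, 2])^2) <
        options$centroid_radius_km
    drop_by(near, "centroid_proximity")
  }

  report <- structure(
    data.frame(step = clean_step_names, removed = as.integer(removed),
               stringsAsFactors = FALSE),
    input = n_in, retained = nrow(keep),
    pct_lost = if (n_in > 0) round_half_up(100 * (n_in - nrow(keep)) / n_in, 1) else 0,
    class = c("clean_report", "data.frame"))
  stopifnot(n_in == nrow(keep) + sum(removed))
  list(records = keep, report = report)
}

#' @export
print.clean_report <- function(x, ...) {
  cat(sprintf("Coordinate cleaning: %d in, %d retained (%.1f%% lost)\n",
              attr(x, "input"), attr(x, "retained"), attr(x, "pct_lost")))
  print.data.frame(x)
  invisible(x)
}

norm_name <- function(x) gsub("\\s+", " ", trimws(x))

#' Resolve verbatim names against a backbone
#'
#' Accepted names map to themselves, synonyms to their accepted name in one
#' hop, and names absent from the backbone (or flagged not found) are routed
#' to an unresolved list, excluded from analysis but preserved.
#'
#' @param records occurrence data.frame with `verbatim_name`.
#' @param backbone a `name_backbone`.
#' @return list with `records` (retained rows plus `accepted_name`) and
#'   `unresolved` (rows whose names could not be resolved).
#' @export
resolve_names <- function(records, backbone) {
  vn <- norm_name(records$verbatim_name)
  idx <- match(vn, norm_name(backbone$name))
  status <- backbone$status[idx]
  acc <- ifelse(is.na(idx) | status == "not_found", NA_character_,
                ifelse(status == "accepted", backbone$name[idx],
                       backbone$accepted_name[idx]))
  ok <- !is.na(acc)
  out <- records[ok, , drop = FALSE]
  out$accepted_name <- acc[ok]
  list(records = out, unresolved = records[!ok, , drop = FALSE])
}

#' Backbone congruence accounting
#'
#' Classifies each name as shared (accepted as-is), synonymous (surplus
#' name) or not found against a backbone, with percentages to one decimal.
#'
#' @param names character vector of names (deduplicated internally).
#' @param backbone a `name_backbone`.
#' @return a `congruence_report` data.frame (status, count, pct) with
#'   attribute `total`.
#' @export
backbone_congruence <- function(names, backbone) {
  names <- unique(norm_name(names))
  if (!length(names)) stop("empty name list")
  idx <- match(names, norm_name(backbone$name))
  status <- backbone$status[idx]
  status[is.na(idx)] <- "not_found"
  status[status == "accepted"] <- "shared"
  status[status == "synonym"] <- "synonymous"
  counts <- vapply(c("shared", "synonymous", "not_found"),
                   function(s) sum(status == s), integer(1))
  structure(
    data.frame(status = names(counts), count = as.integer(counts),
               pct = pct_of(as.integer(counts), length(names)),
               stringsAsFactors = FALSE, row.names = NULL),
    total = length(names),
    class = c("congruence_report", "data.frame"))
}
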