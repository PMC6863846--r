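# Karst-map validation from collection-label metadata: keyword filtering of
# habitat notes, proximity rules for ambiguous terms, overlay congruence.
#
# Keyword classes: carbonate terms (calcario, limestone, dolomite, karst,
# ...) are unconditional evidence; doline terms require a polygon check
# (the manual review of the original protocol, automated here and flagged
# AUTO); cave terms require proximity (within 1 km of a carbonate record or
# of mapped karst), because caves also occur in sandstone and other rocks.

#' Keyword filter over habitat notes
#'
#' Case-insensitive whole-token match after Unicode accent folding, so
#' 'calcário' and 'calcario' both match either spelling. A record matching
#' several keywords is tagged with all of them and classed by the strongest
#' evidence it carries: carbonate > doline > cave.
#'
#' @param records data.frame with `habitat_notes`.
#' @param rules keyword rule table (`keyword`, `class`), default
#'   [default_keyword_rules()].
#' @return the matching records with added columns `keywords`
#'   (comma-separated) and `keyword_class`.
#' @export
keyword_filter <- function(records, rules = default_keyword_rules()) {
  stopifnot(all(c("keyword", "class") %in% names(rules)))
  notes <- tolower(fold_accents(records$habitat_notes))
  toks <- strsplit(notes, "[^a-z0-9]+")
  kw <- tolower(fold_accents(rules$keyword))
  hits <- lapply(toks, function(t) which(kw %in% t))
  nhit <- lengths(hits)
  out <- records[nhit > 0, , drop = FALSE]
  hits <- hits[nhit > 0]
  out$keywords <- vapply(hits, function(h)
    paste(unique(rules$keyword[h]), collapse = ","), character(1))
  rank <- c(carbonate = 1, doline = 2, cave = 3)
  out$keyword_class <- vapply(hits, function(h) {
    cls <- unique(rules$class[h])
    cls[which.min(rank[cls])]
  }, character(1))
  out
}

#' Proximity and polygon rules for conditional keyword classes
#'
#' Carbonate-class records are always retained. Cave-class records are
#' retained iff within `anchor_radius_km` (projected distance) of a
#' carbonate-class record or of mapped karst. Doline-class records are
#' retained iff inside a mapped karst polygon (AUTO stand-in for the manual
#' substrate check). The anchor set is computed before the conditional
#' rules, so the filter is order-independent.
#'
#' @param tagged output of [keyword_filter()] with projected coordinate
#'   columns `x`, `y`.
#' @param karst a `karst_extent`, or NULL when no map is available.
#' @param anchor_radius_km radius for the cave rule, km.
#' @return list with `retained`, `excluded` (each carrying an
#'   `exclusion_rule` column on the excluded side) and `report`
#'   (per-class matched / retained / excluded counts).
#' @export
proximity_filter <- function(tagged, karst = NULL, anchor_radius_km = 1) {
  stopifnot(all(c("x", "y", "keyword_class") %in% names(tagged)))
  carb <- tagged$keyword_class == "carbonate"
  if (!any(carb) && is.null(karst))
    warning("no carbonate anchors and no karst polygons: ",
            "all conditional records will be excluded")
  keep <- rep(TRUE, nrow(tagged))
  rule <- rep(NA_character_, nrow(tagged))

  near_anchor <- function(x, y) {
    ok <- rep(FALSE, length(x))
    if (any(carb)) {
      ax <- tagged$x[carb]; ay <- tagged$y[carb]
      for (i in seq_along(x))
        ok[i] <- any((ax - x[i])^2 + (ay - y[i])^2 <= anchor_radius_km^2)
    }
    if (!is.null(karst))
      ok <- ok | dist_to_extent(x, y, karst) <= anchor_radius_km
    ok
  }

  cave <- which(tagged$keyword_class == "cave")
  if (length(cave)) {
    ok <- near_anchor(tagged$x[cave], tagged$y[cave])
    keep[cave[!ok]] <- FALSE
    rule[cave[!ok]] <- "cave_beyond_1km_of_carbonate_or_karst"
  }
  dol <- which(tagged$keyword_class == "doline")
  if (length(dol)) {
    ok <- if (is.null(karst)) rep(FALSE, length(dol))
          else point_in_extent(tagged$x[dol], tagged$y[dol], karst)
    keep[dol[!ok]] <- FALSE
    rule[dol[!ok]] <- "doline_outside_karst_polygon [AUTO]"
  }

  excluded <- tagged[!keep, , drop = FALSE]
  excluded$exclusion_rule <- rule[!keep]
  report <- do.call(rbind, lapply(c("carbonate", "doline", "cave"), function(cl) {
    sel <- tagged$keyword_class == cl
    data.frame(class = cl, matched = sum(sel), retained = sum(sel & keep),
               excluded = sum(sel & !keep), stringsAsFactors = FALSE)
  }))
  list(retained = tagged[keep, , drop = FALSE], excluded = excluded,
       report = report)
}

#' Overlay congruence of retained keyword records with the karst map
#'
#' @param retained records with projected `x`, `y` (from
#'   [proximity_filter()]).
#' @param karst a `karst_extent`.
#' @param distance_threshold_km records farther than this from any mapped
#'   karst are listed as candidate undocumented outcrops.
#' @return list (`n`, `fraction_inside`, `fraction_within_threshold`,
#'   `candidates`).
#' @export
overlay_congruence <- function(retained, karst, distance_threshold_km = 5) {
  if (!nrow(retained)) stop("empty retained record set")
  d <- dist_to_extent(retained$x, retained$y, karst)
  list(n = nrow(retained),
       fraction_inside = mean(d == 0),
       fraction_within_threshold = mean(d <= distance_threshold_km),
       candidates = retained[d > distance_threshold_km, , drop = FALSE])
}
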