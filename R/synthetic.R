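# Synthetic landscape generator.
#
# Emulates the statistical structure of the study inputs: a species pool
# with a reversed-J range-size distribution, spatially biased collection
# effort, half of the records carrying 5 km coordinate error, karst polygons
# covering a stated fraction of the landscape, taxonomic backbones with a
# stated synonym fraction, and habitat notes seeded with karst keywords.
# All randomness flows from one integer seed through a derived stream per
# sub-generator, so each stage can be regenerated independently.

#' Specification of a synthetic landscape
#'
#' Defaults mirror the study conditions: about half of the records carry a
#' 5 km coordinate error, karst covers ~5% of the landscape (the reported
#' 3.7-6.3% band), 16.6% of names are synonyms in the stricter backbone and
#' 29% of species are confined to a single 50 km cell, at a desk-scale
#' species pool and record count.
#'
#' @param width_km,height_km landscape dimensions, km (>= 100).
#' @param n_species,n_records pool and record sizes.
#' @param single_cell_fraction target share of species whose true range fits
#'   one 50 km cell.
#' @param karst_fraction fraction of the landscape covered by karst,
#'   in (0, 0.5].
#' @param effort_bias strength of spatial sampling bias (0 = uniform).
#' @param coord_error_fraction share of records given 5,000 m uncertainty.
#' @param synonym_fraction share of names treated as synonyms by the second
#'   backbone.
#' @param seed master integer seed.
#' @return an object of class `landscape_spec`.
#' @export
landscape_spec <- function(width_km = 600, height_km = 600,
                           n_species = 400, n_records = 18000,
                           single_cell_fraction = 0.29,
                           karst_fraction = 0.05,
                           effort_bias = 1,
                           coord_error_fraction = 0.5,
                           synonym_fraction = 0.166,
                           seed = 1L) {
  chk <- function(ok, field, msg)
    if (!isTRUE(ok)) stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
  chk(is.numeric(width_km) && width_km >= 100, "width_km", "must be >= 100 km")
  chk(is.numeric(height_km) && height_km >= 100, "height_km", "must be >= 100 km")
  chk(is.numeric(n_species) && n_species >= 1, "n_species", "must be a positive integer")
  chk(is.numeric(n_records) && n_records >= 0, "n_records", "must be a non-negative integer")
  chk(is.numeric(single_cell_fraction) && single_cell_fraction >= 0 &&
        single_cell_fraction <= 1, "single_cell_fraction", "must be in [0,1]")
  chk(is.numeric(karst_fraction) && karst_fraction > 0 && karst_fraction <= 0.5,
      "karst_fraction", "must be in (0, 0.5]")
  chk(is.numeric(effort_bias) && effort_bias >= 0, "effort_bias", "must be >= 0")
  chk(is.numeric(coord_error_fraction) && coord_error_fraction >= 0 &&
        coord_error_fraction <= 1, "coord_error_fraction", "must be in [0,1]")
  chk(is.numeric(synonym_fraction) && synonym_fraction >= 0 &&
        synonym_fraction <= 1, "synonym_fraction", "must be in [0,1]")
  chk(is.numeric(seed) && length(seed) == 1 && is.finite(seed), "seed",
      "must be a single integer")
  structure(list(width_km = width_km, height_km = height_km,
                 n_species = as.integer(n_species),
                 n_records = as.integer(n_records),
                 single_cell_fraction = single_cell_fraction,
                 karst_fraction = karst_fraction,
                 effort_bias = effort_bias,
                 coord_error_fraction = coord_error_fraction,
                 synonym_fraction = synonym_fraction,
                 seed = as.integer(seed)),
            class = "landscape_spec")
}

species_names <- function(n)
  sprintf("Genus species%04d", seq_len(n))

#' Generate a species pool
#'
#' Species ranges are discs. A `single_cell_fraction` share of the pool gets
#' a small radius and a centre placed so the whole disc fits inside one
#' 50 km cell (grid anchored at the origin); the rest get radii >= 25 km
#' with a heavy right tail, so their ranges necessarily straddle cells and
#' the realized cell-count distribution is reversed-J. Relative abundances
#' are lognormal (few common, many rare) and sum to 1.
#'
#' @param spec a `landscape_spec`.
#' @return data.frame of class `species_pool` with columns `species`, `cx`,
#'   `cy`, `radius_km`, `abundance`, `karst_endemic`.
#' @export
gen_species_pool <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  n <- spec$n_species
  karst <- gen_karst_polygons(spec)
  with_seed(derive_seed(spec$seed, "species_pool"), {
    n_small <- round(spec$single_cell_fraction * n)
    small <- c(rep(TRUE, n_small), rep(FALSE, n - n_small))
    radius <- numeric(n)
    cx <- numeric(n); cy <- numeric(n)
    s <- 50
    for (i in seq_len(n)) {
      if (small[i]) {
        radius[i] <- runif(1, 1, 20)
        # pick a cell fully inside the landscape, then a centre keeping the
        # disc off the cell boundary
        ncx <- floor(spec$width_km / s); ncy <- floor(spec$height_km / s)
        cell <- c(sample.int(ncx, 1) - 1, sample.int(ncy, 1) - 1)
        cx[i] <- cell[1] * s + runif(1, radius[i], s - radius[i])
        cy[i] <- cell[2] * s + runif(1, radius[i], s - radius[i])
      } else {
        radius[i] <- 25 + rexp(1, rate = 1 / 40)
        cx[i] <- runif(1, 0, spec$width_km)
        cy[i] <- runif(1, 0, spec$height_km)
      }
    }
    ab <- exp(rnorm(n, 0, 1.2))
    ab <- ab / sum(ab)
    endemic <- point_in_extent(cx, cy, karst) & radius <= 20
    structure(data.frame(species = species_names(n), cx = cx, cy = cy,
                         radius_km = radius, abundance = ab,
                         karst_endemic = endemic,
                         stringsAsFactors = FALSE),
              class = c("species_pool", "data.frame"))
  })
}

#' Realized fraction of single-cell species in a pool
#'
#' A species is single-cell when its whole range disc fits inside one grid
#' cell of side `cell_km` anchored at multiples of the cell size.
#'
#' @param pool a `species_pool`.
#' @param cell_km grid cell side, km.
#' @return proportion in [0, 1].
#' @export
realized_single_cell_fraction <- function(pool, cell_km = 50) {
  eps <- 1e-9
  fits <- function(c0, r)
    floor((c0 - r) / cell_km) == floor((c0 + r - eps) / cell_km)
  mean(fits(pool$cx, pool$radius_km) & fits(pool$cy, pool$radius_km))
}

#' The karst keyword list used for habitat-note seeding and filtering
#'
#' @return data.frame with columns `keyword` and `class`
#'   (carbonate / doline / cave).
#' @export
default_keyword_rules <- function() {
  path <- system.file("extdata", "karst_keywords.csv", package = "karstflora")
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

neutral_notes <- c("floresta de terra firme", "beira de estrada",
                   "campo sujo", "mata ciliar", "cerrado sensu stricto",
                   "pastagem abandonada", "margem de rio")

#' Generate occurrence records
#'
#' Records are placed within species ranges, thinned by a spatial effort
#' surface (a mixture of Gaussian bumps at random "herbarium towns" whose
#' height scales with `effort_bias`). Exactly
#' `round(coord_error_fraction * n)` records carry 5,000 m uncertainty and a
#' coordinate jitter of at most 5 km. Records whose true position falls
#' inside karst receive, with probability 0.5, one keyword from the karst
#' keyword list in their habitat notes; all other notes are neutral text.
#'
#' @param pool a `species_pool`.
#' @param spec the `landscape_spec` the pool was generated from.
#' @return data.frame of occurrence records; columns `record_id`,
#'   `verbatim_name`, `decimal_longitude`, `decimal_latitude`,
#'   `coordinate_uncertainty_m`, `country`, `habitat_notes`, `source`, plus
#'   bookkeeping columns `x_true`, `y_true` (pre-jitter positions, not
#'   written to CSV).
#' @export
gen_occurrences <- function(pool, spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  if (!nrow(pool)) stop("empty species pool")
  n <- spec$n_records
  if (n == 0) return(empty_occurrences())
  karst <- gen_karst_polygons(spec)
  keywords <- default_keyword_rules()$keyword
  with_seed(derive_seed(spec$seed, "occurrences"), {
    # effort surface
    n_towns <- 15
    towns <- cbind(runif(n_towns, 0, spec$width_km),
                   runif(n_towns, 0, spec$height_km))
    sigma <- 40
    effort <- function(x, y) {
      f <- rep(1, length(x))
      if (spec$effort_bias > 0)
        for (t in seq_len(n_towns))
          f <- f + spec$effort_bias *
            exp(-((x - towns[t, 1])^2 + (y - towns[t, 2])^2) / (2 * sigma^2))
      f
    }
    f_max <- max(effort(towns[, 1], towns[, 2]), 1)

    sp_idx <- integer(0); xs <- numeric(0); ys <- numeric(0)
    while (length(sp_idx) < n) {
      m <- max(2L * (n - length(sp_idx)), 1000L)
      cand_sp <- sample.int(nrow(pool), m, replace = TRUE, prob = pool$abundance)
      u <- sqrt(runif(m)); th <- runif(m, 0, 2 * pi)
      cx <- pool$cx[cand_sp] + pool$radius_km[cand_sp] * u * cos(th)
      cy <- pool$cy[cand_sp] + pool$radius_km[cand_sp] * u * sin(th)
      keep <- cx >= 0 & cx <= spec$width_km & cy >= 0 & cy <= spec$height_km &
        runif(m) < effort(cx, cy) / f_max
      sp_idx <- c(sp_idx, cand_sp[keep])
      xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep])
    }
    sp_idx <- sp_idx[seq_len(n)]; xs <- xs[seq_len(n)]; ys <- ys[seq_len(n)]

    unc <- rep(0, n)
    x_obs <- xs; y_obs <- ys
    k <- round(spec$coord_error_fraction * n)
    if (k > 0) {
      jit <- sample.int(n, k)
      unc[jit] <- 5000
      r <- 5 * sqrt(runif(k)); a <- runif(k, 0, 2 * pi)
      x_obs[jit] <- xs[jit] + r * cos(a)
      y_obs[jit] <- ys[jit] + r * sin(a)
    }

    in_karst <- point_in_extent(xs, ys, karst)
    notes <- sample(neutral_notes, n, replace = TRUE)
    seeded <- in_karst & runif(n) < 0.5
    if (any(seeded))
      notes[seeded] <- paste("solo com afloramento de",
                             sample(keywords, sum(seeded), replace = TRUE))

    data.frame(
      record_id = sprintf("rec%06d", seq_len(n)),
      verbatim_name = pool$species[sp_idx],
      decimal_longitude = x_obs,
      decimal_latitude = y_obs,
      coordinate_uncertainty_m = unc,
      country = "BR",
      habitat_notes = notes,
      source = sample(c("herbarium-A", "herbarium-B", "survey-C"), n, TRUE),
      x_true = xs, y_true = ys,
      stringsAsFactors = FALSE)
  })
}

empty_occurrences <- function() {
  data.frame(record_id = character(0), verbatim_name = character(0),
             decimal_longitude = numeric(0), decimal_latitude = numeric(0),
             coordinate_uncertainty_m = numeric(0), country = character(0),
             habitat_notes = character(0), source = character(0),
             x_true = numeric(0), y_true = numeric(0),
             stringsAsFactors = FALSE)
}

# one random convex blob of roughly the requested mean radius
random_blob <- function(cx, cy, r) {
  nv <- 14
  ang <- sort(runif(nv, 0, 2 * pi))
  rad <- r * runif(nv, 0.75, 1.25)
  pts <- cbind(cx + rad * cos(ang), cy + rad * sin(ang))
  pts[rev(grDevices::chull(pts)), , drop = FALSE]
}

#' Generate karst polygons
#'
#' A set of disjoint random convex blobs whose total area equals
#' `karst_fraction` of the landscape (the last blob is rescaled to hit the
#' target, so the realized fraction is within +/- 0.02 by construction).
#'
#' @param spec a `landscape_spec`.
#' @return a `karst_extent` labelled "NBZ".
#' @export
gen_karst_polygons <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  with_seed(derive_seed(spec$seed, "karst_polygons"), {
    W <- spec$width_km; H <- spec$height_km
    target <- spec$karst_fraction * W * H
    blobs <- list(); centres <- NULL; radii <- numeric(0)
    total <- 0; attempts <- 0
    while (total < target * 0.999) {
      attempts <- attempts + 1
      if (attempts > 1000)
        stop("could not reach target karst fraction in 1,000 placement attempts")
      r <- runif(1, 0.04, 0.09) * min(W, H)
      # rescale the closing blob to land exactly on the target area
      approx_area <- pi * r^2
      if (total + approx_area > target)
        r <- r * sqrt((target - total) / approx_area)
      if (r < 1) r <- 1
      cx <- runif(1, r + 1, W - r - 1)
      cy <- runif(1, r + 1, H - r - 1)
      if (!is.null(centres)) {
        d <- sqrt((centres[, 1] - cx)^2 + (centres[, 2] - cy)^2)
        if (any(d < radii * 1.3 + r * 1.3 + 2)) next
      }
      b <- random_blob(cx, cy, r)
      a <- polygon_area(b)
      if (total + a > target) {
        b <- cbind(cx + (b[, 1] - cx) * sqrt((target - total) / a),
                   cy + (b[, 2] - cy) * sqrt((target - total) / a))
        a <- polygon_area(b)
      }
      blobs[[length(blobs) + 1L]] <- b
      centres <- rbind(centres, c(cx, cy)); radii <- c(radii, r)
      total <- total + a
    }
    karst_extent(blobs, "NBZ", 0)
  })
}

#' Generate two taxonomic backbones
#'
#' Backbone A accepts every generated name. Backbone B treats a random
#' `synonym_fraction` of the names as synonyms of other accepted names and a
#' further 5% as not found, mirroring the structure of a stricter checklist.
#'
#' @param pool a `species_pool`.
#' @param spec the `landscape_spec`.
#' @return list with elements `A` and `B`, each a `name_backbone`
#'   data.frame (`name`, `status`, `accepted_name`).
#' @export
gen_backbones <- function(pool, spec) {
  nm <- pool$species
  if (!length(nm))
    return(list(A = empty_backbone(), B = empty_backbone()))
  with_seed(derive_seed(spec$seed, "backbones"), {
    a <- data.frame(name = nm, status = "accepted", accepted_name = nm,
                    stringsAsFactors = FALSE)
    n <- length(nm)
    n_syn <- round(spec$synonym_fraction * n)
    n_nf <- round(0.05 * n)
    reshuffle <- sample.int(n)
    syn_i <- reshuffle[seq_len(n_syn)]
    nf_i <- reshuffle[n_syn + seq_len(n_nf)]
    status <- rep("accepted", n)
    status[syn_i] <- "synonym"
    status[nf_i] <- "not_found"
    acc <- nm
    acc[nf_i] <- NA_character_
    keep <- which(status == "accepted")
    if (length(keep) == 0) keep <- seq_len(n) # degenerate spec
    acc[syn_i] <- nm[sample(keep, n_syn, replace = TRUE)]
    b <- data.frame(name = nm, status = status, accepted_name = acc,
                    stringsAsFactors = FALSE)
    list(A = as_backbone(a), B = as_backbone(b))
  })
}

empty_backbone <- function() {
  as_backbone(data.frame(name = character(0), status = character(0),
                         accepted_name = character(0), stringsAsFactors = FALSE))
}

as_backbone <- function(df) {
  stopifnot(all(c("name", "status", "accepted_name") %in% names(df)))
  structure(df, class = c("name_backbone", "data.frame"))
}

iucn_categories <- c("EX", "EW", "CR", "EN", "VU", "NT", "LC")

#' Generate a red-list table
#'
#' Each species is independently assigned an IUCN category according to
#' `category_probs`; the remaining probability mass is "not evaluated" and
#' those species are absent from the table.
#'
#' @param pool a `species_pool`.
#' @param category_probs named numeric vector over a subset of
#'   EX, EW, CR, EN, VU, NT, LC; must sum to <= 1.
#' @param seed integer seed.
#' @return data.frame (`species`, `category`), one row per evaluated species.
#' @export
gen_redlist <- function(pool, category_probs, seed = 1L) {
  if (!length(category_probs)) category_probs <- numeric(0)
  if (any(!names(category_probs) %in% iucn_categories))
    stop("unknown IUCN category in 'category_probs'")
  if (any(category_probs < 0) || sum(category_probs) > 1 + 1e-12)
    stop("'category_probs' must be non-negative and sum to <= 1")
  if (!nrow(pool) || sum(category_probs) == 0)
    return(data.frame(species = character(0), category = character(0),
                      stringsAsFactors = FALSE))
  with_seed(derive_seed(seed, "redlist"), {
    cats <- c(names(category_probs), "__NE__")
    probs <- c(unname(category_probs), 1 - sum(category_probs))
    draw <- sample(cats, nrow(pool), replace = TRUE, prob = probs)
    keep <- draw != "__NE__"
    data.frame(species = pool$species[keep], category = draw[keep],
               stringsAsFactors = FALSE)
  })
}

# ---- CSV dialect -----------------------------------------------------------

occurrence_csv_cols <- c("record_id", "verbatim_name", "decimal_longitude",
                         "decimal_latitude", "coordinate_uncertainty_m",
                         "country", "habitat_notes", "source")

#' Write occurrences in the pipeline CSV dialect
#' @param records occurrence data.frame.
#' @param path output CSV.
#' @export
write_occurrences_csv <- function(records, path) {
  utils::write.csv(records[, intersect(occurrence_csv_cols, names(records))],
                   path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read occurrences from the pipeline CSV dialect
#' @param path CSV file.
#' @return occurrence data.frame.
#' @export
read_occurrences_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(occurrence_csv_cols, names(df))
  if (length(missing))
    stop("occurrence CSV missing column(s): ", paste(missing, collapse = ", "))
  df
}

#' Write / read a name backbone as CSV
#' @param backbone a `name_backbone`.
#' @param path CSV file.
#' @export
write_backbone_csv <- function(backbone, path) {
  utils::write.csv(backbone, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_backbone_csv
#' @export
read_backbone_csv <- function(path) {
  as_backbone(utils::read.csv(path, stringsAsFactors = FALSE,
                              fileEncoding = "UTF-8"))
}
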