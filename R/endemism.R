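# Range sizes, weighted endemism, randomization significance, small-range
# statistics, extent endemics and the log-log endemics-vs-area comparison.

#' Cell-based range sizes
#'
#' Range size r is the number of distinct 50 km grid cells occupied by each
#' species within the records supplied (which should already be restricted
#' to the extent of interest); an Area-of-Occupancy-like measure.
#'
#' @param records data.frame with `accepted_name` and `cell`.
#' @param extent_label label recorded with the table.
#' @return a `range_size_table`: data.frame (`species`, `r`) with attribute
#'   `extent`.
#' @export
range_sizes <- function(records, extent_label = "custom") {
  pair <- !duplicated(paste(records$accepted_name, records$cell))
  r <- table(records$accepted_name[pair])
  structure(data.frame(species = names(r), r = as.integer(r),
                       stringsAsFactors = FALSE, row.names = NULL),
            extent = extent_label,
            class = c("range_size_table", "data.frame"))
}

#' Weighted and corrected weighted endemism per cell
#'
#' WE(cell) = sum over species present of 1/r; CWE = WE / richness. Summed
#' over all cells, WE equals the total number of species exactly when the
#' range table is computed from the same records.
#'
#' @param records data.frame with `accepted_name` and `cell`.
#' @param ranges a `range_size_table` covering every species in `records`.
#' @return data.frame (`cell`, `richness`, `WE`, `CWE`).
#' @export
weighted_endemism <- function(records, ranges) {
  pair <- !duplicated(paste(records$accepted_name, records$cell))
  sp <- records$accepted_name[pair]
  cell <- records$cell[pair]
  ri <- ranges$r[match(sp, ranges$species)]
  if (anyNA(ri))
    stop("species missing from range table: ",
         paste(unique(sp[is.na(ri)]), collapse = ", "))
  we <- tapply(1 / ri, cell, sum)
  s <- tapply(sp, cell, length)
  cells <- names(we)
  data.frame(cell = cells, richness = as.integer(s[cells]),
             WE = as.numeric(we), CWE = as.numeric(we) / as.numeric(s[cells]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Randomization significance of weighted endemism
#'
#' For each cell, draws its observed richness S species from the overall
#' pool (without replacement within a draw) `n_draws` times, computes the
#' null WE each time, and flags the observed WE against the two-tailed
#' empirical quantiles at level `alpha`: strictly above the upper quantile
#' -> "higher", strictly below the lower -> "lower", otherwise "ns".
#'
#' @param cells data.frame with `cell`, `richness`, `WE` (from
#'   [weighted_endemism()]).
#' @param ranges a `range_size_table` for the overall pool.
#' @param n_draws number of random draws per cell.
#' @param alpha two-tailed significance level.
#' @param seed integer seed.
#' @return `cells` with added columns `null_lower`, `null_upper`,
#'   `significance`.
#' @export
we_randomization <- function(cells, ranges, n_draws = 2000, alpha = 0.05,
                             seed = 1L) {
  w <- 1 / ranges$r
  P <- length(w)
  if (any(cells$richness > P))
    stop("cell richness exceeds pool size")
  lo <- numeric(nrow(cells)); hi <- numeric(nrow(cells))
  with_seed(seed, {
    for (i in seq_len(nrow(cells))) {
      S <- cells$richness[i]
      nulls <- vapply(seq_len(n_draws),
                      function(b) sum(w[sample.int(P, S)]), numeric(1))
      q <- stats::quantile(nulls, c(alpha / 2, 1 - alpha / 2), type = 7,
                           names = FALSE)
      lo[i] <- q[1]; hi[i] <- q[2]
    }
  })
  cells$null_lower <- lo
  cells$null_upper <- hi
  cells$significance <- ifelse(cells$WE > hi, "higher",
                               ifelse(cells$WE < lo, "lower", "ns"))
  cells
}

#' Small-range species count and proportion
#'
#' Small-range species are those restricted to a single grid cell (r = 1).
#'
#' @param ranges a `range_size_table`.
#' @return list (`count`, `total`, `proportion`).
#' @export
small_range_stats <- function(ranges) {
  if (!nrow(ranges)) stop("empty range table")
  n1 <- sum(ranges$r == 1)
  list(count = n1, total = nrow(ranges), proportion = n1 / nrow(ranges))
}

#' Species endemic to an extent
#'
#' A species is an extent endemic when every one of its records lies inside
#' the extent.
#'
#' @param records data.frame with `accepted_name` and a logical column
#'   `inside` flagging records inside the extent.
#' @return character vector of endemic species names.
#' @export
extent_endemics <- function(records) {
  stopifnot(all(c("accepted_name", "inside") %in% names(records)))
  if (!nrow(records)) return(character(0))
  any_out <- tapply(!records$inside, records$accepted_name, any)
  has_in <- tapply(records$inside, records$accepted_name, any)
  names(any_out)[!any_out & has_in]
}

#' Log-log endemics-versus-area comparison
#'
#' Base-10 logs of endemic counts against surface areas, with a simple OLS
#' line and per-point residuals for outlier flagging. Points with zero
#' endemics are skipped with a warning.
#'
#' @param area_km2 surface areas (> 0).
#' @param endemics endemic species counts.
#' @param labels optional point labels.
#' @return list with `points` (data.frame: label, area_km2, endemics,
#'   log10_area, log10_endemics, residual) and, when >= 2 points, `slope`
#'   and `intercept` of the OLS line.
#' @export
log_area_endemics <- function(area_km2, endemics, labels = NULL) {
  if (any(area_km2 <= 0)) stop("areas must be positive")
  labels <- labels %||% paste0("site", seq_along(area_km2))
  zero <- endemics <= 0
  if (any(zero)) {
    warning("skipping point(s) with zero endemics: ",
            paste(labels[zero], collapse = ", "))
    area_km2 <- area_km2[!zero]; endemics <- endemics[!zero]
    labels <- labels[!zero]
  }
  pts <- data.frame(label = labels, area_km2 = area_km2, endemics = endemics,
                    log10_area = log10(area_km2),
                    log10_endemics = log10(endemics),
                    residual = NA_real_, stringsAsFactors = FALSE)
  out <- list(points = pts)
  if (nrow(pts) >= 2) {
    fit <- stats::lm(log10_endemics ~ log10_area, data = pts)
    out$slope <- unname(stats::coef(fit)[2])
    out$intercept <- unname(stats::coef(fit)[1])
    out$points$residual <- unname(stats::resid(fit))
  }
  out
}
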