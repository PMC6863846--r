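# Per-cell richness, sampling-effort regression, accumulation curves,
# Arrhenius species-area fitting, the bootstrap richness null with quantile
# outlier classification, and the resampling comparison of karst against
# the study area.

#' Per-cell record counts and species richness
#'
#' @param records data.frame with `accepted_name` and a `cell` column
#'   (from [assign_cells()]).
#' @return data.frame (`cell`, `record_count`, `richness`), one row per
#'   non-empty cell.
#' @export
cell_richness <- function(records) {
  if (!nrow(records))
    return(data.frame(cell = character(0), record_count = integer(0),
                      richness = integer(0), stringsAsFactors = FALSE))
  stopifnot(all(c("accepted_name", "cell") %in% names(records)))
  cnt <- table(records$cell)
  pair <- !duplicated(paste(records$cell, records$accepted_name))
  ric <- table(records$cell[pair])
  cells <- names(cnt)
  data.frame(cell = cells, record_count = as.integer(cnt),
             richness = as.integer(ric[cells]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Sampling-effort regression
#'
#' Ordinary least squares of sqrt(richness) on sqrt(record count), the
#' standard check that richness differences are not artefacts of sampling
#' intensity.
#'
#' @param cells output of [cell_richness()].
#' @return list (`slope`, `intercept`, `r_squared`, `n`).
#' @export
effort_regression <- function(cells) {
  cells <- cells[cells$record_count > 0, , drop = FALSE]
  if (nrow(cells) < 3) stop("effort regression needs >= 3 cells with records")
  fit <- stats::lm(sqrt(richness) ~ sqrt(record_count), data = cells)
  r2 <- suppressWarnings(summary(fit)$r.squared) # exact fits warn in summary
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       n = nrow(cells))
}

#' Site-by-species presence matrix
#'
#' @param records data.frame with `accepted_name` and a site key column.
#' @param site name of the site key column (default "cell").
#' @return binary matrix, sites in rows.
#' @export
make_comm <- function(records, site = "cell") {
  tab <- table(records[[site]], records$accepted_name)
  m <- unclass(tab) > 0
  storage.mode(m) <- "integer"
  m
}

#' Permutation species-accumulation curve
#'
#' Accumulates sites in random order, recording the cumulative number of
#' distinct species; reports the per-size mean and a normal-approximation
#' 95% CI across permutations (via `vegan::specaccum`). `method = "exact"`
#' returns the closed-form expectation of the same process.
#'
#' @param comm site-by-species matrix from [make_comm()].
#' @param n_permutations number of random site orderings.
#' @param seed integer seed.
#' @param method "random" (permutation) or "exact" (analytic mean).
#' @return an `accum_curve`: data.frame (`sites`, `richness`, `sd`,
#'   `ci_lower`, `ci_upper`) with attribute `n_permutations`.
#' @export
accumulation_curve <- function(comm, n_permutations = 100, seed = 1L,
                               method = c("random", "exact")) {
  method <- match.arg(method)
  if (!nrow(comm)) stop("no non-empty sites")
  if (n_permutations < 1) stop("'n_permutations' must be >= 1")
  sac <- with_seed(seed, vegan::specaccum(comm, method = method,
                                          permutations = n_permutations))
  sd <- if (is.null(sac$sd)) rep(0, length(sac$richness)) else sac$sd
  sd[is.na(sd)] <- 0
  structure(
    data.frame(sites = sac$sites, richness = sac$richness, sd = sd,
               ci_lower = sac$richness - 1.96 * sd,
               ci_upper = sac$richness + 1.96 * sd),
    n_permutations = if (method == "random") n_permutations else NA_integer_,
    method = method,
    class = c("accum_curve", "data.frame"))
}

# closed-form expectation of the random accumulation curve at selected
# sizes: E[S(n)] = sum_s (1 - C(N - m_s, n) / C(N, n)); m_s = sites
# occupied by species s, N = total sites. Used inside the bootstrap null
# where the full vegan curve would be needlessly expensive.
expected_richness_curve <- function(m, N, sizes) {
  vapply(sizes, function(n) {
    sum(1 - exp(lchoose(N - m, n) - lchoose(N, n)))
  }, numeric(1))
}

#' Fit the Arrhenius power species-area relationship S = k * A^z
#'
#' Nonlinear least squares on the raw scale, initialized from the log-log
#' linear regression, with a Levenberg-Marquardt fallback.
#'
#' @param A,S curve points: areas (> 0) and species counts (> 0).
#' @return a `sar_fit`: list (`k`, `z`, `rss`, `n_points`).
#' @export
fit_arrhenius <- function(A, S) {
  ok <- is.finite(A) & is.finite(S) & A > 0 & S > 0
  A <- A[ok]; S <- S[ok]
  if (length(A) < 3) stop("Arrhenius fit needs >= 3 positive curve points")
  if (stats::sd(S) == 0) # flat curve: exact fit S = S0 * A^0
    return(structure(list(k = S[1], z = 0, rss = 0, n_points = length(A)),
                     class = "sar_fit"))
  ll <- stats::lm(log(S) ~ log(A))
  start <- list(k = exp(unname(stats::coef(ll)[1])),
                z = unname(stats::coef(ll)[2]))
  df <- data.frame(A = A, S = S)
  fit <- tryCatch(
    stats::nls(S ~ k * A^z, data = df, start = start, algorithm = "port",
               lower = c(k = 1e-12, z = -5), upper = c(k = Inf, z = 5),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit))
    fit <- tryCatch(
      minpack.lm::nlsLM(S ~ k * A^z, data = df, start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  if (is.null(fit)) {
    cond <- structure(
      class = c("karstflora_fit_error", "error", "condition"),
      list(message = sprintf(
        "Arrhenius fit did not converge (n = %d, log-log start k = %.3g, z = %.3g)",
        length(A), start$k, start$z), call = sys.call(-1)))
    stop(cond)
  }
  co <- stats::coef(fit)
  structure(list(k = unname(co["k"]), z = unname(co["z"]),
                 rss = sum(stats::resid(fit)^2), n_points = length(A)),
            class = "sar_fit")
}

#' @export
print.sar_fit <- function(x, ...) {
  cat(sprintf("Arrhenius S = k*A^z: k = %.4g, z = %.4g (n = %d, rss = %.4g)\n",
              x$k, x$z, x$n_points, x$rss))
  invisible(x)
}

#' Bootstrap null distribution of expected per-cell richness
#'
#' For each of `n_draws` draws the records are resampled with replacement at
#' full size; a 10 km-cell species-accumulation curve is built from the
#' resampled data (closed-form expectation evaluated at `n_eval` sizes, or
#' permutation means), the Arrhenius relationship is fitted to it, and each
#' 50 km cell receives an expected richness k * A^z with A the number of its
#' occupied 10 km subcells. A is recomputed per draw by default
#' (`occupancy = "draw"`), so the null reflects the sampling variability of
#' the resampled dataset; `occupancy = "observed"` holds A at its observed
#' value.
#'
#' @param records data.frame with `accepted_name`, `cell` (50 km key) and
#'   `subcell` (10 km key) columns, already restricted to the extent of
#'   interest.
#' @param n_draws number of bootstrap draws.
#' @param seed integer seed.
#' @param occupancy "draw" or "observed".
#' @param n_eval number of curve sizes used for the per-draw fit.
#' @return a `richness_null`: list with `cells` (data.frame: cell, observed
#'   richness, q25, q75, mean expected richness), `expected` (draws x cells
#'   matrix), `z` (per-draw exponents), `mean_curve_s10` (per-draw mean
#'   expected species in one 10 km cell), `n_draws`, `n_failed`.
#' @export
null_richness <- function(records, n_draws = 1000, seed = 1L,
                          occupancy = c("draw", "observed"), n_eval = 25) {
  occupancy <- match.arg(occupancy)
  stopifnot(all(c("accepted_name", "cell", "subcell") %in% names(records)))
  if (!nrow(records)) stop("no records in extent")
  # canonical ordering makes the null invariant to input record order
  records <- records[order(records$cell, records$subcell,
                           records$accepted_name), , drop = FALSE]
  n <- nrow(records)
  sp <- factor(records$accepted_name)
  sub <- factor(records$subcell)
  coarse <- factor(records$cell)
  cells <- levels(coarse)
  obs_cells <- cell_richness(records)
  obs_A <- subcell_occupancy_from_keys(records$cell, records$subcell)

  expected <- matrix(NA_real_, n_draws, length(cells),
                     dimnames = list(NULL, cells))
  zs <- rep(NA_real_, n_draws)
  s10 <- rep(NA_real_, n_draws)
  with_seed(seed, {
    for (b in seq_len(n_draws)) {
      idx <- sample.int(n, n, replace = TRUE)
      dsub <- sub[idx]; dsp <- sp[idx]; dcoarse <- coarse[idx]
      pair_key <- paste(as.integer(dsub), as.integer(dsp))
      first <- !duplicated(pair_key)
      usub <- dsub[first]; usp <- dsp[first]
      m <- table(usp)
      m <- m[m > 0]
      N <- length(unique(usub))
      if (N < 3 || length(m) < 1) next
      sizes <- unique(round(seq(1, N, length.out = min(n_eval, N))))
      ES <- expected_richness_curve(as.integer(m), N, sizes)
      fit <- tryCatch(fit_arrhenius(sizes, ES), error = function(e) NULL)
      if (is.null(fit)) next
      A <- if (occupancy == "draw") {
        ck <- paste(as.integer(dcoarse[first]), as.integer(usub))
        occ <- table(dcoarse[first][!duplicated(ck)])
        out <- setNames(rep(0, length(cells)), cells)
        out[names(occ)] <- as.numeric(occ)
        out
      } else obs_A
      pos <- A > 0
      expected[b, pos] <- fit$k * A[pos]^fit$z
      zs[b] <- fit$z
      s10[b] <- fit$k # expected species in a single 10 km cell: k * 1^z
    }
  })
  ok <- !is.na(zs)
  n_failed <- sum(!ok)
  if (n_failed > 0.05 * n_draws)
    warning(sprintf("%d of %d bootstrap draws failed to fit", n_failed, n_draws))
  q <- apply(expected, 2, stats::quantile,
             probs = c(0.25, 0.75), na.rm = TRUE, type = 7)
  cells_df <- data.frame(
    cell = cells,
    richness = obs_cells$richness[match(cells, obs_cells$cell)],
    q25 = q[1, ], q75 = q[2, ],
    mean_expected = colMeans(expected, na.rm = TRUE),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(cells = cells_df, expected = expected,
                 z = zs[ok], mean_curve_s10 = s10[ok],
                 n_draws = n_draws, n_failed = n_failed,
                 occupancy = occupancy),
            class = "richness_null")
}

# occupied-subcell count per coarse cell from key columns
subcell_occupancy_from_keys <- function(cell, subcell) {
  key <- paste(cell, subcell)
  first <- !duplicated(key)
  occ <- table(cell[first])
  setNames(as.numeric(occ), names(occ))
}

#' Classify observed richness against the bootstrap null
#'
#' Strictly below the 25th quantile of the null -> -1 (lower outlier),
#' strictly above the 75th -> 2 (upper outlier), otherwise 1.
#'
#' @param observed named numeric vector of observed richness per cell.
#' @param null a `richness_null` (or a data.frame with cell/q25/q75).
#' @return data.frame (`cell`, `richness`, `q25`, `q75`, `outlier_class`).
#' @export
classify_outliers <- function(observed, null) {
  nd <- if (inherits(null, "richness_null")) null$cells else null
  cells <- names(observed)
  idx <- match(cells, nd$cell)
  if (anyNA(idx)) {
    warning("no null for cell(s): ",
            paste(cells[is.na(idx)], collapse = ", "), "; skipped")
    cells <- cells[!is.na(idx)]
    idx <- idx[!is.na(idx)]
  }
  q25 <- nd$q25[idx]; q75 <- nd$q75[idx]
  obs <- unname(observed[cells])
  cls <- ifelse(obs < q25, -1L, ifelse(obs > q75, 2L, 1L))
  data.frame(cell = cells, richness = obs, q25 = q25, q75 = q75,
             outlier_class = cls, stringsAsFactors = FALSE, row.names = NULL)
}

#' Resampling comparison of a karst statistic against the study area
#'
#' Draws `n_samples` samples of study-area cells (without replacement within
#' a sample), each of the same size as the karst cell set; computes each
#' sample's mean statistic; then performs the one-sample two-sided t-test of
#' those sample means against the observed karst mean (degrees of freedom
#' `n_samples - 1`). Because the t statistic under this construction scales
#' with sqrt(n_samples), an empirical randomization p (two-sided proportion
#' of sample means at least as extreme as the observed mean) is also
#' reported and is the calibrated measure of significance.
#'
#' @param study_stat per-cell statistic over the study area.
#' @param karst_stat per-cell statistic over the karst cells.
#' @param n_samples number of random samples.
#' @param seed integer seed.
#' @return a `resample_test`: list (`observed`, `sample_means`, `t`, `df`,
#'   `p_value`, `p_empirical`, `n_samples`, `n_cells`).
#' @export
resample_extent_test <- function(study_stat, karst_stat, n_samples = 1000,
                                 seed = 1L) {
  k <- length(karst_stat)
  if (k > length(study_stat))
    stop("karst cell count exceeds study-area cell count")
  if (k < 1) stop("no karst cells")
  observed <- mean(karst_stat)
  means <- with_seed(seed, vapply(seq_len(n_samples), function(i)
    mean(sample(study_stat, k, replace = FALSE)), numeric(1)))
  resample_summary(means, observed, k)
}

# one-sample two-sided t of the replicate means against the observed value
# (df = n_samples - 1) plus the empirical randomization p
resample_summary <- function(means, observed, n_cells) {
  tt <- stats::t.test(means, mu = observed)
  p_emp <- 2 * min(mean(means <= observed), mean(means >= observed))
  structure(list(observed = observed, sample_means = means,
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, p_empirical = min(1, p_emp),
                 n_samples = length(means), n_cells = n_cells),
            class = "resample_test")
}

#' Resampling comparison for an arbitrary per-sample statistic
#'
#' Generalization of [resample_extent_test()] for statistics that are not a
#' mean of per-cell values (e.g. the proportion of small-range species among
#' the species present in a sample of cells): draws samples of cell keys of
#' the karst size, applies `stat_fn` to each, and tests the replicate values
#' against the observed karst value the same way.
#'
#' @param study_cells character vector of study-area cell keys.
#' @param karst_cells character vector of karst cell keys.
#' @param stat_fn function(cell keys) -> scalar statistic.
#' @param n_samples number of random samples.
#' @param seed integer seed.
#' @return a `resample_test`.
#' @export
resample_cells_test <- function(study_cells, karst_cells, stat_fn,
                                n_samples = 1000, seed = 1L) {
  k <- length(karst_cells)
  if (k > length(study_cells))
    stop("karst cell count exceeds study-area cell count")
  observed <- stat_fn(karst_cells)
  means <- with_seed(seed, vapply(seq_len(n_samples), function(i)
    stat_fn(sample(study_cells, k, replace = FALSE)), numeric(1)))
  resample_summary(means, observed, k)
}

#' @export
print.resample_test <- function(x, ...) {
  cat(sprintf(paste0(
    "Resampling test: observed mean = %.4g, %d samples of %d cells\n",
    "  t = %.4g, df = %d, p = %.3g (parametric); p = %.3g (empirical)\n"),
    x$observed, x$n_samples, x$n_cells, x$t, x$df, x$p_value, x$p_empirical))
  invisible(x)
}
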