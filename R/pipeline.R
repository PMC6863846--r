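# End-to-end orchestration. Stages communicate only via files under the
# output directory (CSV / GeoJSON), never in-memory, so any stage can be
# rerun or swapped; each stage writes a machine-readable manifest (stage,
# seed, input hashes) sufficient to re-execute it bit-identically.

pipeline_stages <- c("simulate", "clean", "grid", "richness", "endemism",
                     "validate_karst", "conservation", "report")

#' Pipeline configuration
#'
#' Defaults reproduce the study's stated settings: a 5 km buffer zone,
#' 1,000 bootstrap draws for the richness null, 2,000 draws for the
#' endemism randomization, 1,000 resampling samples for the extent t-tests,
#' 50 km analysis cells with 10 km subcells.
#'
#' @param out_dir output directory (created if needed).
#' @param synth a `landscape_spec` for the simulate stage.
#' @param buffer_km buffer applied to the karst extent.
#' @param cell_km,subcell_km analysis and subcell grid sizes, km.
#' @param n_draws_richness,n_draws_we,n_samples_ttest resampling sizes.
#' @param alpha two-tailed significance level.
#' @param category_probs red-list category probabilities for the simulate
#'   stage (defaults scaled from the published country-level table).
#' @param seed master seed; overrides `synth$seed`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, synth = landscape_spec(),
                            buffer_km = 5, cell_km = 50, subcell_km = 10,
                            n_draws_richness = 1000, n_draws_we = 2000,
                            n_samples_ttest = 1000, alpha = 0.05,
                            category_probs = NULL, seed = 1L) {
  if (!is.null(seed)) synth$seed <- as.integer(seed)
  if (is.null(category_probs)) {
    # published country-level evaluation rates (counts / 34,388 names)
    pub <- c(EX = 5, EW = 2, CR = 55, EN = 157, VU = 271, NT = 43, LC = 747)
    category_probs <- pub / 34388
  }
  structure(list(out_dir = out_dir, synth = synth, buffer_km = buffer_km,
                 cell_km = cell_km, subcell_km = subcell_km,
                 n_draws_richness = n_draws_richness,
                 n_draws_we = n_draws_we,
                 n_samples_ttest = n_samples_ttest, alpha = alpha,
                 category_probs = category_probs,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

out_path <- function(config, ...) file.path(config$out_dir, ...)

require_inputs <- function(config, files, stage) {
  paths <- out_path(config, files)
  missing <- files[!file.exists(paths)]
  if (length(missing))
    stop(sprintf("stage '%s' is missing upstream output(s): %s", stage,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(paths)
}

write_manifest <- function(config, stage, inputs, outputs) {
  man <- list(stage = stage, seed = config$seed,
              params = config[setdiff(names(config), c("out_dir", "synth"))],
              synth = unclass(config$synth),
              inputs = as.list(tools::md5sum(out_path(config, inputs))),
              outputs = outputs)
  jsonlite::write_json(man, out_path(config, sprintf("manifest_%s.json", stage)),
                       auto_unbox = TRUE, digits = NA)
}

landscape_rect <- function(spec) {
  karst_extent(list(rbind(c(0, 0), c(spec$width_km, 0),
                          c(spec$width_km, spec$height_km),
                          c(0, spec$height_km))), "custom", 0)
}

#' Run one pipeline stage
#'
#' Stages: simulate, clean, grid, richness, endemism, validate_karst,
#' conservation, report. Each reads its upstream files from
#' `config$out_dir`, writes its outputs there, and records a manifest.
#'
#' @param stage stage name.
#' @param config a `pipeline_config`.
#' @return invisibly, the stage's primary in-memory result.
#' @export
run_stage <- function(stage, config) {
  stage <- match.arg(stage, pipeline_stages)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    c(list(stages = pipeline_stages), unclass(config)[names(config) != "synth"],
      list(synth = unclass(config$synth))),
    out_path(config, "config.json"), auto_unbox = TRUE, digits = NA)
  res <- switch(stage,
    simulate = stage_simulate(config),
    clean = stage_clean(config),
    grid = stage_grid(config),
    richness = stage_richness(config),
    endemism = stage_endemism(config),
    validate_karst = stage_validate(config),
    conservation = stage_conservation(config),
    report = stage_report(config))
  invisible(res)
}

#' Run the whole pipeline
#'
#' @param config a `pipeline_config`.
#' @param dry_run print the execution plan and write nothing.
#' @return invisibly, the report-stage result (NULL for dry runs).
#' @export
run_all <- function(config, dry_run = FALSE) {
  if (dry_run) {
    cat("Execution plan (out_dir =", config$out_dir, "):\n")
    for (s in pipeline_stages) cat("  -", s, "\n")
    return(invisible(NULL))
  }
  res <- NULL
  for (s in pipeline_stages) res <- run_stage(s, config)
  invisible(res)
}

stage_simulate <- function(config) {
  spec <- config$synth
  pool <- gen_species_pool(spec)
  occ <- gen_occurrences(pool, spec)
  karst <- gen_karst_polygons(spec)
  bb <- gen_backbones(pool, spec)
  rl <- gen_redlist(pool, config$category_probs, seed = spec$seed)
  write_occurrences_csv(occ, out_path(config, "occurrences.csv"))
  write_extent_geojson(karst, out_path(config, "karst_nbz.geojson"))
  write_backbone_csv(bb$A, out_path(config, "backbone_a.csv"))
  write_backbone_csv(bb$B, out_path(config, "backbone_b.csv"))
  utils::write.csv(rl, out_path(config, "redlist.csv"), row.names = FALSE)
  utils::write.csv(pool, out_path(config, "species_pool.csv"), row.names = FALSE)
  write_manifest(config, "simulate", character(0),
                 c("occurrences.csv", "karst_nbz.geojson", "backbone_a.csv",
                   "backbone_b.csv", "redlist.csv", "species_pool.csv"))
  invisible(list(pool = pool, occurrences = occ, karst = karst))
}

stage_clean <- function(config) {
  require_inputs(config, c("occurrences.csv", "backbone_b.csv"), "clean")
  occ <- read_occurrences_csv(out_path(config, "occurrences.csv"))
  backbone <- read_backbone_csv(out_path(config, "backbone_b.csv"))
  spec <- config$synth
  rect <- landscape_rect(spec)
  opts <- clean_options(lon_range = c(0, spec$width_km),
                        lat_range = c(0, spec$height_km))
  cl <- clean_coordinates(occ, land_polygons = rect,
                          country_polygons = list(BR = rect), options = opts)
  rs <- resolve_names(cl$records, backbone)
  cong <- backbone_congruence(unique(occ$verbatim_name), backbone)
  utils::write.csv(rs$records, out_path(config, "cleaned_occurrences.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(rs$unresolved, out_path(config, "unresolved_names.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  rep_df <- as.data.frame(cl$report)
  rep_df$input <- attr(cl$report, "input")
  rep_df$retained_total <- attr(cl$report, "retained")
  rep_df$pct_lost <- attr(cl$report, "pct_lost")
  utils::write.csv(rep_df, out_path(config, "clean_report.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(cong), out_path(config, "congruence_report.csv"),
                   row.names = FALSE)
  write_manifest(config, "clean", c("occurrences.csv", "backbone_b.csv"),
                 c("cleaned_occurrences.csv", "unresolved_names.csv",
                   "clean_report.csv", "congruence_report.csv"))
  invisible(list(records = rs$records, clean_report = cl$report,
                 congruence = cong))
}

stage_grid <- function(config) {
  require_inputs(config, c("cleaned_occurrences.csv", "karst_nbz.geojson"),
                 "grid")
  occ <- utils::read.csv(out_path(config, "cleaned_occurrences.csv"),
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  nbz <- read_extent_geojson(out_path(config, "karst_nbz.geojson"))
  bz5 <- buffer_extent(nbz, config$buffer_km)
  study <- bounding_box(bz5) # box within which all (buffered) karst lies
  grid50 <- grid_for_extent(study, config$cell_km)
  grid10 <- grid_for_extent(study, config$subcell_km)
  x <- occ$decimal_longitude; y <- occ$decimal_latitude
  occ$cell <- assign_cells(x, y, grid50, occ$record_id)$cell
  occ$subcell <- assign_cells(x, y, grid10, occ$record_id)$cell
  occ$inside_nbz <- point_in_extent(x, y, nbz)
  occ$inside_bz5 <- point_in_extent(x, y, bz5)
  occ$inside_study <- point_in_extent(x, y, study)
  write_extent_geojson(bz5, out_path(config, "karst_bz5.geojson"))
  write_extent_geojson(study, out_path(config, "study_area.geojson"))
  utils::write.csv(occ, out_path(config, "occurrences_gridded.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  write_grid_csv(grid50, unique(occ$cell), out_path(config, "grid50.csv"))
  areas <- data.frame(extent = c("landscape", "study_area", "NBZ", "BZ5"),
                      area_km2 = c(config$synth$width_km * config$synth$height_km,
                                   study$area_km2, nbz$area_km2, bz5$area_km2))
  utils::write.csv(areas, out_path(config, "extent_areas.csv"), row.names = FALSE)
  write_manifest(config, "grid",
                 c("cleaned_occurrences.csv", "karst_nbz.geojson"),
                 c("karst_bz5.geojson", "study_area.geojson",
                   "occurrences_gridded.csv", "grid50.csv", "extent_areas.csv"))
  invisible(list(records = occ, nbz = nbz, bz5 = bz5, study = study,
                 grid50 = grid50, grid10 = grid10))
}

read_gridded <- function(config, stage) {
  require_inputs(config, "occurrences_gridded.csv", stage)
  utils::read.csv(out_path(config, "occurrences_gridded.csv"),
                  stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

stage_richness <- function(config) {
  occ <- read_gridded(config, "richness")
  seed <- config$seed
  subsets <- list(study = occ[occ$inside_study, ],
                  nbz = occ[occ$inside_nbz, ],
                  bz5 = occ[occ$inside_bz5, ])
  metrics <- lapply(subsets, cell_richness)
  for (nm in names(metrics))
    utils::write.csv(metrics[[nm]],
                     out_path(config, sprintf("richness_cells_%s.csv", nm)),
                     row.names = FALSE)
  effort <- lapply(metrics[c("nbz", "bz5")], effort_regression)

  # study-area accumulation curve over 50 km cells
  acc <- accumulation_curve(make_comm(subsets$study, "cell"),
                            n_permutations = 100,
                            seed = derive_seed(seed, "accum_study"))
  utils::write.csv(as.data.frame(acc), out_path(config, "accumulation_study.csv"),
                   row.names = FALSE)

  # bootstrap richness null within the NBZ extent
  null <- null_richness(subsets$nbz, n_draws = config$n_draws_richness,
                        seed = derive_seed(seed, "null_richness"))
  obs <- setNames(metrics$nbz$richness, metrics$nbz$cell)
  outliers <- classify_outliers(obs, null)
  utils::write.csv(outliers, out_path(config, "outliers_nbz.csv"),
                   row.names = FALSE)
  sar <- data.frame(
    quantity = c("z_mean", "z_min", "z_max", "z_sd",
                 "s10_mean", "s10_min", "s10_max", "s10_sd"),
    value = c(mean(null$z), min(null$z), max(null$z), stats::sd(null$z),
              mean(null$mean_curve_s10), min(null$mean_curve_s10),
              max(null$mean_curve_s10), stats::sd(null$mean_curve_s10)))
  utils::write.csv(sar, out_path(config, "sar_summary.csv"), row.names = FALSE)

  tests <- list(
    nbz = resample_extent_test(metrics$study$richness, metrics$nbz$richness,
                               n_samples = config$n_samples_ttest,
                               seed = derive_seed(seed, "ttest_nbz")),
    bz5 = resample_extent_test(metrics$study$richness, metrics$bz5$richness,
                               n_samples = config$n_samples_ttest,
                               seed = derive_seed(seed, "ttest_bz5")))
  tdf <- do.call(rbind, lapply(names(tests), function(nm) {
    t <- tests[[nm]]
    data.frame(extent = nm, statistic = "mean_cell_richness",
               observed = t$observed, t = t$t, df = t$df,
               p_value = t$p_value, p_empirical = t$p_empirical)
  }))
  utils::write.csv(tdf, out_path(config, "richness_tests.csv"), row.names = FALSE)
  ef <- do.call(rbind, lapply(names(effort), function(nm)
    data.frame(extent = nm, slope = effort[[nm]]$slope,
               intercept = effort[[nm]]$intercept,
               r_squared = effort[[nm]]$r_squared, n = effort[[nm]]$n)))
  utils::write.csv(ef, out_path(config, "effort_regression.csv"),
                   row.names = FALSE)
  write_manifest(config, "richness", "occurrences_gridded.csv",
                 c("richness_cells_study.csv", "richness_cells_nbz.csv",
                   "richness_cells_bz5.csv", "accumulation_study.csv",
                   "outliers_nbz.csv", "sar_summary.csv", "richness_tests.csv",
                   "effort_regression.csv"))
  invisible(list(metrics = metrics, effort = effort, accumulation = acc,
                 null = null, outliers = outliers, tests = tests))
}

stage_endemism <- function(config) {
  occ <- read_gridded(config, "endemism")
  seed <- config$seed
  subsets <- list(study = occ[occ$inside_study, ],
                  nbz = occ[occ$inside_nbz, ],
                  bz5 = occ[occ$inside_bz5, ])
  ranges <- lapply(names(subsets), function(nm)
    range_sizes(subsets[[nm]], nm))
  names(ranges) <- names(subsets)
  we <- lapply(names(subsets), function(nm)
    weighted_endemism(subsets[[nm]], ranges[[nm]]))
  names(we) <- names(subsets)
  we$nbz <- we_randomization(we$nbz, ranges$nbz,
                             n_draws = config$n_draws_we,
                             alpha = config$alpha,
                             seed = derive_seed(seed, "we_null"))
  for (nm in names(we))
    utils::write.csv(we[[nm]], out_path(config, sprintf("endemism_%s.csv", nm)),
                     row.names = FALSE)
  for (nm in names(ranges))
    utils::write.csv(as.data.frame(ranges[[nm]]),
                     out_path(config, sprintf("ranges_%s.csv", nm)),
                     row.names = FALSE)

  # extent-restricted and conservative (study-wide) small-range proportions
  sr <- lapply(ranges, small_range_stats)
  conservative <- lapply(c(nbz = "nbz", bz5 = "bz5"), function(nm) {
    spp <- unique(subsets[[nm]]$accepted_name)
    rs <- ranges$study[ranges$study$species %in% spp, , drop = FALSE]
    small_range_stats(rs)
  })
  srdf <- rbind(
    do.call(rbind, lapply(names(sr), function(nm)
      data.frame(extent = nm, basis = "extent", count = sr[[nm]]$count,
                 total = sr[[nm]]$total, proportion = sr[[nm]]$proportion))),
    do.call(rbind, lapply(names(conservative), function(nm)
      data.frame(extent = nm, basis = "study_wide",
                 count = conservative[[nm]]$count,
                 total = conservative[[nm]]$total,
                 proportion = conservative[[nm]]$proportion))))
  utils::write.csv(srdf, out_path(config, "small_range_stats.csv"),
                   row.names = FALSE)

  # resampling test on the per-sample small-range proportion (study-wide r)
  sp_by_cell <- split(subsets$study$accepted_name, subsets$study$cell)
  r_study <- setNames(ranges$study$r, ranges$study$species)
  prop_fn <- function(cells) {
    spp <- unique(unlist(sp_by_cell[cells], use.names = FALSE))
    mean(r_study[spp] == 1)
  }
  study_cells <- names(sp_by_cell)
  tests <- lapply(c(nbz = "nbz", bz5 = "bz5"), function(nm)
    resample_cells_test(study_cells, unique(subsets[[nm]]$cell), prop_fn,
                        n_samples = config$n_samples_ttest,
                        seed = derive_seed(seed, paste0("sr_ttest_", nm))))
  tdf <- do.call(rbind, lapply(names(tests), function(nm) {
    t <- tests[[nm]]
    data.frame(extent = nm, statistic = "small_range_proportion",
               observed = t$observed, t = t$t, df = t$df,
               p_value = t$p_value, p_empirical = t$p_empirical)
  }))
  utils::write.csv(tdf, out_path(config, "small_range_tests.csv"),
                   row.names = FALSE)

  # extent endemics + the log-log endemics vs area table
  endems <- lapply(c(nbz = "inside_nbz", bz5 = "inside_bz5"), function(col) {
    df <- occ; df$inside <- df[[col]]
    extent_endemics(df)
  })
  areas <- utils::read.csv(out_path(config, "extent_areas.csv"),
                           stringsAsFactors = FALSE)
  a_nbz <- areas$area_km2[areas$extent == "NBZ"]
  a_bz5 <- areas$area_km2[areas$extent == "BZ5"]
  lae <- log_area_endemics(c(a_nbz, a_bz5),
                           c(max(1, length(endems$nbz)),
                             max(1, length(endems$bz5))),
                           labels = c("NBZ", "BZ5"))
  utils::write.csv(lae$points, out_path(config, "log_area_endemics.csv"),
                   row.names = FALSE)
  writeLines(c(endems$nbz), out_path(config, "endemics_nbz.txt"))
  writeLines(c(endems$bz5), out_path(config, "endemics_bz5.txt"))
  write_manifest(config, "endemism",
                 c("occurrences_gridded.csv", "extent_areas.csv"),
                 c("endemism_study.csv", "endemism_nbz.csv", "endemism_bz5.csv",
                   "ranges_study.csv", "ranges_nbz.csv", "ranges_bz5.csv",
                   "small_range_stats.csv", "small_range_tests.csv",
                   "log_area_endemics.csv", "endemics_nbz.txt",
                   "endemics_bz5.txt"))
  invisible(list(ranges = ranges, we = we, small_range = srdf, tests = tests,
                 endemics = endems))
}

stage_validate <- function(config) {
  occ <- read_gridded(config, "validate_karst")
  require_inputs(config, "karst_nbz.geojson", "validate_karst")
  nbz <- read_extent_geojson(out_path(config, "karst_nbz.geojson"))
  occ$x <- occ$decimal_longitude
  occ$y <- occ$decimal_latitude
  tagged <- keyword_filter(occ)
  prox <- proximity_filter(tagged, nbz, anchor_radius_km = 1)
  cong <- if (nrow(prox$retained))
    overlay_congruence(prox$retained, nbz, distance_threshold_km = 5)
  else list(n = 0, fraction_inside = NA, fraction_within_threshold = NA,
            candidates = prox$retained)
  utils::write.csv(prox$report, out_path(config, "validation_report.csv"),
                   row.names = FALSE)
  utils::write.csv(prox$excluded, out_path(config, "validation_excluded.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(cong$candidates,
                   out_path(config, "undocumented_candidates.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  summ <- data.frame(quantity = c("n_matched", "n_retained",
                                  "fraction_inside", "fraction_within_5km"),
                     value = c(nrow(tagged), cong$n, cong$fraction_inside,
                               cong$fraction_within_threshold))
  utils::write.csv(summ, out_path(config, "validation_summary.csv"),
                   row.names = FALSE)
  write_manifest(config, "validate_karst",
                 c("occurrences_gridded.csv", "karst_nbz.geojson"),
                 c("validation_report.csv", "validation_excluded.csv",
                   "undocumented_candidates.csv", "validation_summary.csv"))
  invisible(list(tagged = tagged, proximity = prox, congruence = cong))
}

stage_conservation <- function(config) {
  occ <- read_gridded(config, "conservation")
  require_inputs(config, c("redlist.csv", "extent_areas.csv"), "conservation")
  rl <- utils::read.csv(out_path(config, "redlist.csv"),
                        stringsAsFactors = FALSE)
  areas <- utils::read.csv(out_path(config, "extent_areas.csv"),
                           stringsAsFactors = FALSE)
  sets <- list(brazil = unique(occ$accepted_name),
               nbz = unique(occ$accepted_name[occ$inside_nbz]),
               bz5 = unique(occ$accepted_name[occ$inside_bz5]),
               study = unique(occ$accepted_name[occ$inside_study]))
  xt <- iucn_crosstab(sets, rl)
  utils::write.csv(as.data.frame(xt), out_path(config, "iucn_crosstab.csv"),
                   row.names = FALSE)

  subsets <- list(
    brazil = occ,
    study = occ[occ$inside_study, ],
    nbz = occ[occ$inside_nbz, ],
    bz5 = occ[occ$inside_bz5, ])
  flags <- c(brazil = NA, study = "inside_study", nbz = "inside_nbz",
             bz5 = "inside_bz5")
  area_of <- c(brazil = "landscape", study = "study_area", nbz = "NBZ",
               bz5 = "BZ5")
  ext <- lapply(names(subsets), function(nm) {
    sub <- subsets[[nm]]
    cr <- cell_richness(sub)
    nend <- if (is.na(flags[[nm]])) length(unique(sub$accepted_name)) else {
      df <- occ; df$inside <- df[[flags[[nm]]]]
      length(extent_endemics(df))
    }
    list(area_km2 = areas$area_km2[areas$extent == area_of[[nm]]],
         n_records = nrow(sub),
         n_taxa = length(unique(sub$accepted_name)),
         n_endemics = nend,
         max_cell_richness = if (nrow(cr)) max(cr$richness) else 0)
  })
  names(ext) <- names(subsets)
  st <- summary_table(ext)
  utils::write.csv(as.data.frame(st), out_path(config, "summary_table.csv"),
                   row.names = FALSE)
  write_manifest(config, "conservation",
                 c("occurrences_gridded.csv", "redlist.csv", "extent_areas.csv"),
                 c("iucn_crosstab.csv", "summary_table.csv"))
  invisible(list(crosstab = xt, summary = st))
}

stage_report <- function(config) {
  need <- c("clean_report.csv", "congruence_report.csv", "sar_summary.csv",
            "richness_tests.csv", "small_range_tests.csv",
            "small_range_stats.csv", "outliers_nbz.csv",
            "validation_summary.csv", "iucn_crosstab.csv", "summary_table.csv")
  require_inputs(config, need, "report")
  rd <- function(f) utils::read.csv(out_path(config, f),
                                    stringsAsFactors = FALSE)
  outliers <- rd("outliers_nbz.csv")
  report <- list(
    clean = rd("clean_report.csv"),
    congruence = rd("congruence_report.csv"),
    sar = rd("sar_summary.csv"),
    richness_tests = rd("richness_tests.csv"),
    small_range_tests = rd("small_range_tests.csv"),
    small_range_stats = rd("small_range_stats.csv"),
    outlier_class_counts = as.list(table(outliers$outlier_class)),
    validation = rd("validation_summary.csv"),
    iucn = rd("iucn_crosstab.csv"),
    summary_table = rd("summary_table.csv"))
  jsonlite::write_json(report, out_path(config, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  txt <- c("karstflora pipeline report",
           sprintf("seed: %d", config$seed),
           sprintf("records retained after cleaning: %s",
                   report$clean$retained_total[1]),
           sprintf("SAR slope z (bootstrap mean): %.3f",
                   report$sar$value[report$sar$quantity == "z_mean"]),
           sprintf("richness t-tests: %s",
                   paste(sprintf("%s t=%.2f p=%.3g", report$richness_tests$extent,
                                 report$richness_tests$t,
                                 report$richness_tests$p_empirical),
                         collapse = "; ")),
           sprintf("keyword-map congruence (<=5 km): %.3f",
                   report$validation$value[report$validation$quantity ==
                                             "fraction_within_5km"]))
  writeLines(txt, out_path(config, "report.txt"))
  write_manifest(config, "report", need, c("report.json", "report.txt"))
  invisible(report)
}
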