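test_that("crosstab reproduces the published percentage arithmetic", {
  pub <- published_counts("iucn")
  # rebuild a red list and species sets realizing the published counts
  mk <- function(col) {
    unlist(lapply(seq_len(nrow(pub)), function(i)
      sprintf("%s_%03d", pub$category[i], seq_len(pub[[col]][i]))))
  }
  sets <- list(brazil = mk("brazil"), nbz = mk("nbz"), bz5 = mk("bz5"),
               study = mk("study_area"))
  redlist <- data.frame(species = sets$brazil,
                        category = sub("_.*", "", sets$brazil),
                        stringsAsFactors = FALSE)
  xt <- iucn_crosstab(sets, redlist)
  cc <- xt[xt$category == "Conservation concern", ]
  expect_equal(cc$brazil_taxa, 533L)
  expect_equal(cc$nbz_taxa, 120L)
  expect_equal(cc$nbz_pct, 22.5)
  expect_equal(cc$bz5_pct, 34.7)
  cr <- xt[xt$category == "CR", ]
  expect_equal(cr$bz5_taxa, 15L)
  expect_equal(cr$bz5_pct, 27.3)
  tot <- xt[xt$category == "Total", ]
  expect_equal(tot$brazil_taxa, 1280L)
  expect_equal(tot$nbz_pct, 30.3)
  expect_equal(tot$study_pct, 84.5)
  # roll-up consistency in every column
  cats6 <- xt$category %in% c("EX", "EW", "CR", "EN", "VU", "NT")
  for (col in grep("_taxa$", names(xt), value = TRUE)) {
    expect_equal(sum(xt[[col]][cats6]), cc[[col]])
    expect_equal(cc[[col]] + xt[[col]][xt$category == "LC"], tot[[col]])
  }
  # column monotonicity for nested extents
  expect_true(all(xt$nbz_taxa <= xt$bz5_taxa))
  expect_true(all(xt$bz5_taxa <= xt$study_taxa))
})

test_that("the EX-VU-only roll-up is available as a switch", {
  redlist <- data.frame(species = c("a", "b", "c"),
                        category = c("NT", "VU", "LC"),
                        stringsAsFactors = FALSE)
  sets <- list(all = c("a", "b", "c"))
  with_nt <- iucn_crosstab(sets, redlist, concern_includes_nt = TRUE)
  without <- iucn_crosstab(sets, redlist, concern_includes_nt = FALSE)
  pick <- function(x) x$all_taxa[x$category == "Conservation concern"]
  expect_equal(pick(with_nt), 2L)
  expect_equal(pick(without), 1L)
})

test_that("empty extents give zero rows, not errors", {
  redlist <- data.frame(species = "a", category = "VU",
                        stringsAsFactors = FALSE)
  xt <- iucn_crosstab(list(brazil = "a", empty = character(0)), redlist)
  expect_true(all(xt$empty_taxa == 0))
  expect_true(all(xt$empty_pct == 0))
})

test_that("summary table reproduces the published extent percentages", {
  pub <- published_counts("extents")
  as_ext <- function(col) as.list(setNames(pub[[col]], pub$parameter))
  st <- summary_table(list(brazil = as_ext("brazil"),
                           study = as_ext("study_area"),
                           nbz = as_ext("nbz"), bz5 = as_ext("bz5")))
  val <- function(param, col) st[[col]][st$parameter ==
    c(area_km2 = "Area, km2", n_records = "Number of records",
      n_taxa = "Number of taxa", n_endemics = "Number of endemic taxa",
      max_cell_richness = "Max 50 km cell richness")[[param]]]
  expect_equal(val("n_records", "nbz_pct"), 7.4)
  expect_equal(val("n_taxa", "bz5_pct"), 38.3)
  # half-up recomputation of the area row gives 57.5 / 6.4; the printed
  # table's 57.4 / 6.3 imply truncation or unrounded areas, so only the
  # arithmetic from counts is asserted here
  expect_equal(val("area_km2", "study_pct"), 57.5)
  expect_equal(val("n_endemics", "study_pct"), 94.5)
  expect_equal(val("max_cell_richness", "nbz_pct"), 34.4)
  # identical extents give 100% everywhere
  st2 <- summary_table(list(a = as_ext("brazil"), b = as_ext("brazil")))
  expect_true(all(st2$b_pct == 100))
})

test_that("half-up rounding matches printed-table conventions", {
  expect_equal(pct_of(125, 1000), 12.5)
  expect_equal(karstflora:::round_half_up(0.25, 1), 0.3) # not banker's
  expect_equal(karstflora:::round_half_up(22.45, 1), 22.5)
  expect_error(pct_of(1, 0), "positive")
})
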