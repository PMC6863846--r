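mk_rec <- function(lon, lat, country = "BR", id = NULL) {
  n <- length(lon)
  data.frame(record_id = id %||% sprintf("r%03d", seq_len(n)),
             verbatim_name = "Genus species0001",
             decimal_longitude = lon, decimal_latitude = lat,
             coordinate_uncertainty_m = 0, country = country,
             habitat_notes = "", source = "t", stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

br <- square_extent(40, 0, 0, "custom")  # toy country polygon in degrees
opts <- clean_options(lon_range = c(-180, 180), lat_range = c(-90, 90))

test_that("each cleaning step removes its own pathology", {
  recs <- mk_rec(lon = c(0, 200, 12, 20, 90, 20.4, 25),
                 lat = c(0, 10, 12, 40.5, 10, 20.0, 30))
  # r1 zero-zero; r2 lon out of range; r3 lat == lon (12,12);
  # r4 outside BR polygon (lat 40.5); r5 off land; r6 near centroid (20,20);
  # r7 clean
  out <- clean_coordinates(recs, land_polygons = br,
                           country_polygons = list(BR = br), options = opts)
  rep <- out$report
  got <- setNames(rep$removed, rep$step)
  expect_equal(got[["zero_coordinates"]], 1)
  expect_equal(got[["out_of_range"]], 1)
  expect_equal(got[["lat_equals_lon"]], 1)
  # r4 and r5 both fail country containment; r5 would otherwise fail land
  expect_equal(got[["country_mismatch"]], 2)
  expect_equal(got[["centroid_proximity"]], 1)
  expect_equal(out$records$record_id, "r007")
  # conservation: input = retained + sum(removed)
  expect_equal(attr(rep, "input"),
               attr(rep, "retained") + sum(rep$removed))
})

test_that("cleaning percentage bookkeeping and idempotence hold", {
  recs <- mk_rec(lon = c(0, 0, 0, 200, runif(96, 1, 39)),
                 lat = c(0, 0, 0, 10, runif(96, 1, 5)))
  out <- clean_coordinates(recs, land_polygons = br,
                           country_polygons = list(BR = br), options = opts)
  expect_equal(attr(out$report, "pct_lost"), 4.0)
  # cleaning already-clean records removes nothing
  again <- clean_coordinates(out$records, land_polygons = br,
                             country_polygons = list(BR = br), options = opts)
  expect_equal(nrow(again$records), nrow(out$records))
  expect_equal(sum(again$report$removed), 0)
})

test_that("steps are individually switchable", {
  recs <- mk_rec(lon = c(0, 5), lat = c(0, 5))
  out <- clean_coordinates(recs, options = clean_options(steps = "out_of_range"))
  expect_equal(nrow(out$records), 2) # zero-coordinate rule not run
  expect_error(clean_options(steps = "bogus"), "bogus")
  expect_error(clean_coordinates(recs, land_polygons = "x"), "karst_extent")
})

test_that("name resolution maps statuses correctly", {
  bb <- karstflora:::as_backbone(data.frame(
    name = c("Aa bb", "Cc dd", "Ee ff"),
    status = c("accepted", "synonym", "not_found"),
    accepted_name = c("Aa bb", "Aa bb", NA), stringsAsFactors = FALSE))
  recs <- mk_rec(lon = 1:4, lat = rep(2, 4))
  recs$verbatim_name <- c("Aa bb", "Cc  dd", "Ee ff", "Zz zz")
  out <- resolve_names(recs, bb)
  expect_equal(out$records$accepted_name, c("Aa bb", "Aa bb"))
  expect_equal(out$unresolved$verbatim_name, c("Ee ff", "Zz zz"))
  # conservation: each record is retained or unresolved
  expect_equal(nrow(out$records) + nrow(out$unresolved), 4)
})

test_that("backbone congruence reproduces published-style arithmetic", {
  # the published worked example: 34,388 names, 5,708 synonymous, 1,732 not
  # found -> 16.6% / 78.3% / 5.0%
  counts <- published_counts("backbones")
  wc <- counts[counts$dataset == "bien_v3.4.5" & counts$backbone == "WC", ]
  expect_equal(pct_of(wc$synonymous, wc$total_names), 16.6)
  expect_equal(pct_of(wc$shared, wc$total_names), 78.3)
  fb <- counts[counts$dataset == "bien_v3.4.5" & counts$backbone == "FB2020", ]
  expect_equal(pct_of(fb$not_found, fb$total_names), 12.7)

  # a backbone accepting everything: 100% shared
  bb <- karstflora:::as_backbone(data.frame(
    name = c("A a", "B b"), status = "accepted",
    accepted_name = c("A a", "B b"), stringsAsFactors = FALSE))
  cong <- backbone_congruence(c("A a", "B b"), bb)
  expect_equal(cong$pct, c(100, 0, 0))
  expect_error(backbone_congruence(character(0), bb), "empty")
})

test_that("congruence percentages sum to 100 within rounding", {
  spec <- landscape_spec(n_species = 137, synonym_fraction = 0.23, seed = 2)
  pool <- gen_species_pool(spec)
  bb <- gen_backbones(pool, spec)
  cong <- backbone_congruence(pool$species, bb$B)
  expect_lte(abs(sum(cong$pct) - 100), 0.1)
  expect_equal(sum(cong$count), attr(cong, "total"))
})
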