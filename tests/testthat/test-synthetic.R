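test_that("landscape_spec validates fields and names the offender", {
  expect_error(landscape_spec(width_km = 50), "width_km")
  expect_error(landscape_spec(karst_fraction = 0.9), "karst_fraction")
  expect_error(landscape_spec(coord_error_fraction = 1.2),
               "coord_error_fraction")
  expect_error(landscape_spec(single_cell_fraction = -0.1),
               "single_cell_fraction")
})

test_that("generators are deterministic for a fixed seed", {
  spec <- small_spec()
  expect_identical(gen_species_pool(spec), gen_species_pool(spec))
  pool <- gen_species_pool(spec)
  expect_identical(gen_occurrences(pool, spec), gen_occurrences(pool, spec))
  expect_identical(gen_karst_polygons(spec), gen_karst_polygons(spec))
  expect_identical(gen_backbones(pool, spec), gen_backbones(pool, spec))
  expect_identical(gen_redlist(pool, c(VU = 0.2), seed = 5),
                   gen_redlist(pool, c(VU = 0.2), seed = 5))
})

test_that("species pool respects the single-cell target", {
  # degenerate bound: all ranges must fit one 50 km cell
  pool1 <- gen_species_pool(small_spec(single_cell_fraction = 1))
  expect_true(all(pool1$radius_km < 25))
  expect_equal(realized_single_cell_fraction(pool1), 1)
  # realized fraction tracks the target across seeds
  fr <- vapply(1:50, function(s) {
    spec <- landscape_spec(n_species = 200, single_cell_fraction = 0.4,
                           seed = s)
    realized_single_cell_fraction(gen_species_pool(spec))
  }, numeric(1))
  expect_true(all(abs(fr - 0.4) <= 0.07))
  # abundances normalized, radii positive
  pool <- gen_species_pool(small_spec())
  expect_equal(sum(pool$abundance), 1)
  expect_true(all(pool$radius_km > 0))
})

test_that("occurrence generator honours coordinate-error bookkeeping", {
  spec <- small_spec(coord_error_fraction = 0)
  occ <- gen_occurrences(gen_species_pool(spec), spec)
  expect_true(all(occ$coordinate_uncertainty_m == 0))
  expect_equal(occ$decimal_longitude, occ$x_true)

  spec2 <- small_spec(coord_error_fraction = 0.5)
  occ2 <- gen_occurrences(gen_species_pool(spec2), spec2)
  expect_equal(sum(occ2$coordinate_uncertainty_m == 5000),
               round(0.5 * nrow(occ2)))
  # jitter never exceeds the declared uncertainty
  d <- sqrt((occ2$decimal_longitude - occ2$x_true)^2 +
              (occ2$decimal_latitude - occ2$y_true)^2)
  expect_true(all(d <= occ2$coordinate_uncertainty_m / 1000 + 1e-9))

  spec0 <- small_spec(n_records = 0)
  expect_equal(nrow(gen_occurrences(gen_species_pool(spec0), spec0)), 0)
})

test_that("unbiased effort yields uniform sampling over the landscape", {
  # one species covering the whole landscape, so record positions are
  # uniform when effort_bias = 0; chi-square GOF over a 2x2 supergrid
  spec <- landscape_spec(width_km = 600, height_km = 600, n_species = 1,
                         n_records = 10000, effort_bias = 0,
                         coord_error_fraction = 0, seed = 4L)
  pool <- gen_species_pool(spec)
  pool$cx <- 300; pool$cy <- 300; pool$radius_km <- 430 # covers all corners
  occ <- gen_occurrences(pool, spec)
  cell <- paste(floor(occ$decimal_longitude / 300),
                floor(occ$decimal_latitude / 300))
  p <- stats::chisq.test(table(cell))$p.value
  expect_gt(p, 0.01)
})

test_that("karst polygon generator hits the target fraction", {
  spec <- small_spec(karst_fraction = 0.05)
  k <- gen_karst_polygons(spec)
  ratio <- k$area_km2 / (spec$width_km * spec$height_km)
  expect_true(ratio >= 0.03 && ratio <= 0.07)
  expect_identical(gen_karst_polygons(spec), k)
  # polygons are valid (positive area, convex orientation)
  expect_true(all(vapply(k$polygons, polygon_area, 0) > 0))
})

test_that("backbone generator reproduces the synonym structure", {
  spec <- landscape_spec(n_species = 500, synonym_fraction = 0.166, seed = 9)
  pool <- gen_species_pool(spec)
  bb <- gen_backbones(pool, spec)
  expect_true(all(bb$A$status == "accepted"))
  cong <- backbone_congruence(pool$species, bb$B)
  syn_pct <- cong$pct[cong$status == "synonymous"]
  expect_true(abs(syn_pct - 16.6) <= 1)
  nf_pct <- cong$pct[cong$status == "not_found"]
  expect_equal(nf_pct, 5.0)
  # synonym_fraction = 0 leaves only the fixed 5% not found
  spec0 <- landscape_spec(n_species = 500, synonym_fraction = 0, seed = 9)
  cong0 <- backbone_congruence(pool$species, gen_backbones(pool, spec0)$B)
  expect_equal(cong0$pct[cong0$status == "shared"], 95.0)
  # empty pool -> empty backbones
  empty <- pool[0, ]
  bbe <- gen_backbones(empty, spec)
  expect_equal(nrow(bbe$A), 0)
  expect_equal(nrow(bbe$B), 0)
})

test_that("red-list generator follows the category probabilities", {
  spec <- landscape_spec(n_species = 1000, seed = 21)
  pool <- gen_species_pool(spec)
  expect_equal(nrow(gen_redlist(pool, c(VU = 0))), 0)
  all_lc <- gen_redlist(pool, c(LC = 1))
  expect_equal(nrow(all_lc), 1000)
  expect_true(all(all_lc$category == "LC"))
  vu <- gen_redlist(pool, c(VU = 0.2), seed = 3)
  expect_true(abs(nrow(vu) - 200) <= 25)
  expect_error(gen_redlist(pool, c(VU = 0.7, LC = 0.7)), "sum")
  expect_error(gen_redlist(pool, c(XX = 0.1)), "category")
})

test_that("occurrence CSV dialect round-trips", {
  spec <- small_spec()
  occ <- gen_occurrences(gen_species_pool(spec), spec)
  path <- withr::local_tempfile(fileext = ".csv")
  write_occurrences_csv(occ, path)
  back <- read_occurrences_csv(path)
  expect_equal(back$verbatim_name, occ$verbatim_name)
  expect_equal(back$decimal_longitude, occ$decimal_longitude)
  expect_false("x_true" %in% names(back)) # bookkeeping stays internal
})
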