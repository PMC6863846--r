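test_that("range sizes count distinct occupied cells", {
  r <- rec_df(c("A", "A", "A", "B", "B", "B"),
              c("c1", "c1", "c1", "0_0", "0_1", "0_0"))
  rs <- range_sizes(r)
  expect_equal(rs$r[rs$species == "A"], 1L)
  expect_equal(rs$r[rs$species == "B"], 2L)
  # subset monotonicity: restricting records can only shrink ranges
  sub <- range_sizes(r[r$cell == "0_0", ])
  expect_true(all(sub$r <= rs$r[match(sub$species, rs$species)]))
})

test_that("weighted endemism closed forms hold", {
  one <- rec_df("A", "c1")
  we1 <- weighted_endemism(one, range_sizes(one))
  expect_equal(we1$WE, 1)
  expect_equal(we1$CWE, 1)
  # ranges {1,2,4} in one cell: WE = 1.75, CWE = 1.75/3
  recs <- rec_df(c("A", "B", "B", "C", "C", "C", "C"),
                 c("x", "x", "y", "x", "y", "z", "w"))
  we <- weighted_endemism(recs, range_sizes(recs))
  wx <- we[we$cell == "x", ]
  expect_equal(wx$WE, 1 + 1/2 + 1/4)
  expect_equal(wx$CWE, 1.75 / 3, tolerance = 1e-9)
  expect_error(weighted_endemism(recs, range_sizes(one)), "missing")
})

test_that("WE sums to the species total over any layout", {
  for (i in 1:25) {
    set.seed(i)
    recs <- random_layout(nsp = 20 + i, ncell = 10 + i, nrec = 150 + 7 * i)
    we <- weighted_endemism(recs, range_sizes(recs))
    expect_equal(sum(we$WE), length(unique(recs$accepted_name)),
                 tolerance = 1e-9)
    # CWE bounded by (0, 1]
    expect_true(all(we$CWE > 0 & we$CWE <= 1 + 1e-12))
  }
  # CWE = 1 iff every species in the cell is single-cell
  all1 <- rec_df(c("A", "B"), c("c1", "c1"))
  expect_equal(weighted_endemism(all1, range_sizes(all1))$CWE, 1)
})

test_that("WE randomization flags degenerate and extreme cells sensibly", {
  # identical ranges: null is degenerate, observed equals it -> ns
  ranges <- structure(data.frame(species = sprintf("s%d", 1:20), r = 2L),
                      class = c("range_size_table", "data.frame"))
  cells <- data.frame(cell = "c1", richness = 5L, WE = 2.5)
  out <- we_randomization(cells, ranges, n_draws = 100, seed = 1)
  expect_equal(out$significance, "ns")
  # a cell of only narrow-range species against a wide-ranged pool -> higher
  ranges2 <- structure(data.frame(species = sprintf("s%d", 1:50),
                                  r = c(rep(1L, 3), rep(25L, 47))),
                       class = c("range_size_table", "data.frame"))
  cells2 <- data.frame(cell = "c1", richness = 3L, WE = 3.0)
  out2 <- we_randomization(cells2, ranges2, n_draws = 500, seed = 2)
  expect_equal(out2$significance, "higher")
  # determinism
  out3 <- we_randomization(cells2, ranges2, n_draws = 500, seed = 2)
  expect_identical(out2, out3)
  expect_error(we_randomization(data.frame(cell = "c", richness = 99, WE = 1),
                                ranges, n_draws = 10), "pool")
})

test_that("small-range statistics and extent monotonicity", {
  rng <- function(r) structure(
    data.frame(species = sprintf("s%d", seq_along(r)), r = as.integer(r)),
    class = c("range_size_table", "data.frame"))
  expect_equal(small_range_stats(rng(c(1, 1, 1)))$proportion, 1)
  expect_equal(small_range_stats(rng(c(1, 1, 2, 5)))$proportion, 0.5)
  expect_error(small_range_stats(rng(integer(0))), "empty")
  # generator calibration: single-cell fraction ~ small-range proportion
  spec <- landscape_spec(n_species = 200, single_cell_fraction = 0.4,
                         seed = 31)
  pool <- gen_species_pool(spec)
  expect_lte(abs(realized_single_cell_fraction(pool) - 0.4), 0.07)
  # study-wide ranges never exceed extent-restricted small-range proportions
  set.seed(8)
  recs <- random_layout(nsp = 40, ncell = 25, nrec = 400)
  inside <- recs$cell %in% sprintf("c%02d", 1:8)
  sub <- recs[inside, ]
  p_extent <- small_range_stats(range_sizes(sub))$proportion
  rs_study <- range_sizes(recs)
  spp <- unique(sub$accepted_name)
  p_cons <- mean(rs_study$r[match(spp, rs_study$species)] == 1)
  expect_lte(p_cons, p_extent)
})

test_that("extent endemics require every record inside", {
  recs <- rec_df(c("A", "A", "B", "B", "C"), c("c1", "c2", "c1", "c3", "c4"))
  recs$inside <- c(TRUE, TRUE, TRUE, FALSE, TRUE)
  expect_setequal(extent_endemics(recs), c("A", "C"))
  # nested extents: NBZ endemics subset of BZ5 endemics
  recs$inside_big <- c(TRUE, TRUE, TRUE, TRUE, TRUE)
  small <- extent_endemics(recs)
  recs$inside <- recs$inside_big
  big <- extent_endemics(recs)
  expect_true(all(small %in% big))
  expect_equal(extent_endemics(recs[0, ]), character(0))
})

test_that("log-log endemics-area points match published values", {
  # Peninsular Malaysia karst (260 km2, 134 endemics) and the Brazilian
  # NBZ extent (318,126 km2, 468 endemics)
  out <- log_area_endemics(c(260, 318126), c(134, 468),
                           labels = c("malaysia", "brazil_nbz"))
  expect_equal(round(out$points$log10_area, 4), c(2.4150, 5.5026))
  expect_equal(round(out$points$log10_endemics, 4), c(2.1271, 2.6702))
  # single point: echoed without a regression
  single <- log_area_endemics(260, 134)
  expect_null(single$slope)
  expect_equal(nrow(single$points), 1)
  expect_warning(log_area_endemics(c(10, 20), c(0, 5)), "zero")
  expect_error(log_area_endemics(-1, 5), "positive")
})
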