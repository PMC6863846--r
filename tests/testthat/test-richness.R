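test_that("cell richness counts distinct names and is duplicate-idempotent", {
  r <- rec_df(c("A", "A", "A"), c("c1", "c1", "c1"))
  out <- cell_richness(r)
  expect_equal(out$richness, 1L)
  expect_equal(out$record_count, 3L)
  expect_equal(nrow(cell_richness(r[0, ])), 0)
  r2 <- random_layout()
  expect_equal(cell_richness(rbind(r2, r2))$richness,
               cell_richness(r2)$richness)
})

test_that("effort regression reproduces closed-form OLS", {
  # identity: every record a new species
  cells <- data.frame(cell = letters[1:5], record_count = c(1, 4, 9, 16, 25),
                      richness = c(1, 4, 9, 16, 25))
  f <- effort_regression(cells)
  expect_equal(f$slope, 1, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  # constant richness: slope 0
  cells$richness <- 9
  expect_equal(effort_regression(cells)$slope, 0, tolerance = 1e-12)
  # 5 fixed points against the hand-solved normal equations
  cells2 <- data.frame(cell = letters[1:5],
                       record_count = c(4, 9, 25, 49, 100),
                       richness = c(3, 7, 12, 20, 31))
  X <- cbind(1, sqrt(cells2$record_count))
  beta <- solve(t(X) %*% X, t(X) %*% sqrt(cells2$richness))
  f2 <- effort_regression(cells2)
  expect_equal(f2$intercept, beta[1], tolerance = 1e-9)
  expect_equal(f2$slope, beta[2], tolerance = 1e-9)
  expect_error(effort_regression(cells2[1:2, ]), ">= 3")
})

test_that("accumulation curve saturates at pooled richness", {
  # all cells share one species: flat curve at 1
  comm <- make_comm(rec_df(rep("A", 8), sprintf("c%d", 1:8)))
  acc <- accumulation_curve(comm, n_permutations = 10, seed = 1)
  expect_true(all(acc$richness == 1))
  # terminal mean equals pooled richness exactly, any permutation count
  set.seed(3)
  r <- random_layout(nsp = 25, ncell = 12, nrec = 150)
  comm2 <- make_comm(r)
  for (np in c(5, 50)) {
    acc2 <- accumulation_curve(comm2, n_permutations = np, seed = 2)
    expect_equal(acc2$richness[nrow(acc2)], length(unique(r$accepted_name)))
  }
  # monotone non-decreasing mean
  expect_true(all(diff(acc2$richness) >= -1e-9))
  expect_error(accumulation_curve(comm2, n_permutations = 0), ">= 1")
})

test_that("permutation mean tracks the hypergeometric expectation", {
  set.seed(11)
  r <- random_layout(nsp = 40, ncell = 20, nrec = 400)
  comm <- make_comm(r)
  acc <- accumulation_curve(comm, n_permutations = 200, seed = 5)
  exp_S <- hyper_expected_richness(comm, acc$sites)
  se <- acc$sd / sqrt(200)
  # 0.05-species absolute guard where the permutation distribution is
  # nearly degenerate (sd ~ 0 near the curve's saturated tail)
  expect_true(all(abs(acc$richness - exp_S) <= 3 * se + 0.05))
  # the internal closed form agrees with vegan's exact method
  sac <- vegan::specaccum(comm, method = "exact")
  own <- karstflora:::expected_richness_curve(colSums(comm > 0), nrow(comm),
                                              sac$sites)
  expect_equal(own, sac$richness, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("Arrhenius fit recovers exact power laws", {
  f <- fit_arrhenius(c(1, 4, 9, 16), c(10, 20, 30, 40))
  expect_equal(f$k, 10, tolerance = 1e-6)
  expect_equal(f$z, 0.5, tolerance = 1e-6)
  f2 <- fit_arrhenius(1:5, 1:5)
  expect_equal(f2$k, 1, tolerance = 1e-6)
  expect_equal(f2$z, 1, tolerance = 1e-6)
  # exact recovery across the plausible exponent range
  A <- c(1, 2, 4, 8, 16, 25)
  for (k in c(0.5, 10, 120)) for (z in c(0.1, 0.48, 0.9, 1.5)) {
    fz <- fit_arrhenius(A, k * A^z)
    expect_equal(fz$k, k, tolerance = 1e-6)
    expect_equal(fz$z, z, tolerance = 1e-6)
  }
  # flat curves are an exact degenerate fit
  ff <- fit_arrhenius(1:4, rep(3, 4))
  expect_equal(ff$k, 3)
  expect_equal(ff$z, 0)
  expect_error(fit_arrhenius(c(1, 2), c(1, 2)), ">= 3")
})

test_that("Arrhenius fit agrees with vegan's fitspecaccum", {
  set.seed(21)
  r <- random_layout(nsp = 60, ncell = 25, nrec = 600)
  comm <- make_comm(r)
  acc <- accumulation_curve(comm, n_permutations = 1, seed = 9,
                            method = "exact")
  own <- fit_arrhenius(acc$sites, acc$richness)
  sac <- vegan::specaccum(comm, method = "exact")
  vg <- vegan::fitspecaccum(sac, model = "arrhenius")
  expect_equal(own$z, unname(coef(vg)["z"]), tolerance = 1e-4)
  expect_equal(own$k, unname(coef(vg)["k"]), tolerance = 1e-3)
})

test_that("bootstrap richness null is deterministic and order-invariant", {
  set.seed(5)
  n <- 600
  r <- rec_df(sprintf("sp%02d", sample.int(30, n, TRUE)),
              sprintf("c%d", sample.int(6, n, TRUE)),
              subcell = sprintf("s%03d", sample.int(150, n, TRUE)))
  a <- null_richness(r, n_draws = 50, seed = 7)
  b <- null_richness(r, n_draws = 50, seed = 7)
  expect_identical(a$expected, b$expected)
  # invariant to record ordering
  perm <- sample.int(n)
  c2 <- null_richness(r[perm, ], n_draws = 50, seed = 7)
  expect_equal(sort(colnames(a$expected)), sort(colnames(c2$expected)))
  expect_equal(a$cells$q25[order(a$cells$cell)],
               c2$cells$q25[order(c2$cells$cell)], tolerance = 1e-9)
})

test_that("degenerate single-species data gives a unit null", {
  r <- rec_df(rep("A", 100), sprintf("c%d", rep(1:4, 25)),
              subcell = sprintf("s%03d", sample.int(60, 100, TRUE)))
  null <- null_richness(r, n_draws = 20, seed = 3)
  expect_equal(null$n_failed, 0)
  expect_true(all(abs(null$expected[!is.na(null$expected)] - 1) < 1e-9))
  expect_true(all(abs(null$z) < 1e-9))
})

test_that("outlier classification follows strict quantile rules", {
  nd <- data.frame(cell = c("a", "b", "c"), q25 = c(5, 5, 5),
                   q75 = c(10, 10, 10))
  out <- classify_outliers(c(a = 4, b = 7, c = 11), nd)
  expect_equal(out$outlier_class, c(-1L, 1L, 2L))
  # boundary values are non-outliers (strict inequalities)
  out2 <- classify_outliers(c(a = 5, b = 10), nd)
  expect_equal(out2$outlier_class, c(1L, 1L))
  expect_warning(classify_outliers(c(zz = 3), nd), "zz")
})

test_that("resampling test matches the hand-computed t statistic", {
  # centred case: observed equals the replicate mean
  t0 <- karstflora:::resample_summary(c(1, 2, 3), observed = 2, n_cells = 3)
  expect_equal(t0$t, 0)
  expect_equal(t0$p_value, 1)
  # hand-computed one-sample t: mean 2.5, sd 1.290994..., n 4
  t1 <- karstflora:::resample_summary(c(1, 2, 3, 4), observed = 0, n_cells = 4)
  expect_equal(t1$t, 2.5 / (sd(c(1, 2, 3, 4)) / 2), tolerance = 1e-12)
  expect_equal(t1$df, 3)
  # df = n_samples - 1 by construction
  tt <- resample_extent_test(rnorm(50), rnorm(10), n_samples = 200, seed = 1)
  expect_equal(tt$df, 199)
  expect_error(resample_extent_test(1:3, 1:5), "exceeds")
})
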