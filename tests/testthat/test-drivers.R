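test_that("distance transform is exact against the brute-force oracle", {
  # single target at the NW corner: cell (2,2) is 25 * sqrt(2)
  m <- matrix(2L, 3, 3); m[1, 1] <- 1L
  r <- cat_raster(m, lg2)
  d <- distance_to_class(r, 1L)
  expect_equal(d$values[2, 2], 25 * sqrt(2), tolerance = 1e-12)
  expect_equal(d$values[1, 1], 0)
  expect_true(all(distance_to_class(r, 1:2)$values == 0))
  expect_error(distance_to_class(r, 3L), "distance undefined")

  # exhaustive agreement on random grids up to 20x20
  set.seed(21)
  for (k in 1:6) {
    nr <- sample(2:20, 1); nc <- sample(2:20, 1)
    g <- cat_raster(matrix(sample(1:2, nr * nc, TRUE, prob = c(0.2, 0.8)),
                           nr, nc), lg2)
    if (!any(g$values == 1L)) g$values[1, 1] <- 1L
    expect_equal(distance_to_class(g, 1L)$values, oracle_distance(g, 1L),
                 tolerance = 1e-9)
  }
})

test_that("evidence likelihood is the category frequency within change", {
  # categories A=1 (30 change cells), B=2 (10 change cells)
  soil <- cat_raster(matrix(rep(c(1L, 2L), c(48, 16)), 8), lg2)
  chg <- matrix(0L, 8, 8)
  chg[c(1:30, 49:58)] <- 1L
  mask <- cat_raster(chg, new_legend(0:1, c("n", "y")))
  el <- evidence_likelihood(soil, mask)
  expect_equal(unique(el$values[soil$values == 1L]), 0.75)
  expect_equal(unique(el$values[soil$values == 2L]), 0.25)

  # values over categories sum to 1
  set.seed(5)
  soil2 <- cat_raster(matrix(sample(1:3, 100, TRUE), 10), lg3)
  mask2 <- cat_raster(matrix(as.integer(runif(100) < 0.3), 10),
                      new_legend(0:1, c("n", "y")))
  el2 <- evidence_likelihood(soil2, mask2)
  per_cat <- vapply(1:3, function(cc) unique(el2$values[soil2$values == cc]),
                    numeric(1))
  expect_equal(sum(per_cat), 1)

  # all change inside one category -> indicator
  mask3 <- cat_raster(matrix(as.integer(soil$values == 2L), 8),
                      new_legend(0:1, c("n", "y")))
  el3 <- evidence_likelihood(soil, mask3)
  expect_equal(unique(el3$values[soil$values == 2L]), 1)
  expect_equal(unique(el3$values[soil$values == 1L]), 0)

  # conditional mode: P(change | category)
  elc <- evidence_likelihood(soil, mask, mode = "conditional")
  expect_equal(unique(elc$values[soil$values == 1L]), 30 / 48)
  expect_equal(unique(elc$values[soil$values == 2L]), 10 / 16)

  zero <- cat_raster(matrix(0L, 8, 8), new_legend(0:1, c("n", "y")))
  expect_error(evidence_likelihood(soil, zero), "no change cells")
})

test_that("Cramer's V matches the hand chi-squared oracle", {
  # 2x2 table [[30,10],[10,30]]: chi2 = 20, V = 0.5
  v <- cat_raster(matrix(rep(c(1L, 2L), c(40, 40)), 8, 10), lg2)
  r <- cat_raster(matrix(rep(c(1L, 2L, 1L, 2L), c(30, 10, 10, 30)), 8, 10),
                  lg2)
  expect_equal(cramers_v(v, r), 0.5, tolerance = 1e-12)
  expect_equal(cramers_v(v, r),
               oracle_cramers_v(table(v$values, r$values)))

  # perfect association: V = 1
  expect_equal(cramers_v(v, v), 1)

  # continuous copy of the response is still a perfect predictor
  vc <- cont_raster(matrix(as.numeric(r$values), 8, 10))
  expect_equal(cramers_v(vc, r, n_bins = 16), 1)

  # response constant -> error
  const <- cat_raster(matrix(1L, 8, 10), lg2)
  expect_error(cramers_v(v, const), "constant")

  # independence: mean V below 0.05 at n = 10^4
  set.seed(13)
  vs <- replicate(5, {
    a <- cont_raster(matrix(rnorm(1e4), 100))
    b <- cat_raster(matrix(sample(1:2, 1e4, TRUE), 100), lg2)
    cramers_v(a, b, n_bins = 16)
  })
  expect_lt(mean(vs), 0.05)
})

test_that("Cramer's V is invariant to relabeling and monotone transforms", {
  set.seed(17)
  x <- cont_raster(matrix(rnorm(400), 20))
  resp <- cat_raster(matrix(sample(1:3, 400, TRUE), 20), lg3)
  v0 <- cramers_v(x, resp, n_bins = 8)

  relab <- resp
  relab$values <- matrix(c(3L, 1L, 2L)[resp$values], 20)
  expect_equal(cramers_v(x, relab, n_bins = 8), v0)

  # strictly monotone transform preserving bin membership boundaries is
  # approximated by an affine map (exactly bin-preserving)
  aff <- x
  aff$values <- 3 * x$values + 7
  expect_equal(cramers_v(aff, resp, n_bins = 8), v0, tolerance = 1e-12)
})

test_that("screening partitions by strict V > threshold, preserving order", {
  tab <- wales_screening_table()
  s <- screen_variables(tab, threshold = 0.15)
  expect_identical(nrow(s$retained), 14L)
  expect_identical(nrow(s$dropped), 6L)
  expect_setequal(s$dropped$cramers_v,
                  c(0.077, 0.135, 0.011, 0.065, 0.081, 0.013))
  expect_identical(s$retained$name,
                   tab$name[tab$cramers_v > 0.15])  # order preserved
  expect_true(all(s$retained$cramers_v > 0.15))
  expect_true(all(s$dropped$cramers_v <= 0.15))

  # boundary: V exactly at the threshold is dropped
  b <- screen_variables(data.frame(name = "x", cramers_v = 0.15), 0.15)
  expect_identical(nrow(b$retained), 0L)

  empty <- screen_variables(tab[0, ])
  expect_identical(nrow(empty$retained), 0L)
  expect_identical(nrow(empty$dropped), 0L)
  all_dropped <- screen_variables(tab, threshold = 1)
  expect_identical(nrow(all_dropped$retained), 0L)
})
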