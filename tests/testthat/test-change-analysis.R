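test_that("cross-tabulation matches the per-pixel enumeration oracle", {
  t1 <- cat_raster(matrix(c(1L, 1L, 2L, 2L), 2, byrow = TRUE), lg3)
  t2 <- cat_raster(matrix(c(1L, 2L, 2L, 2L), 2, byrow = TRUE), lg3)
  m <- cross_tabulate(t1, t2)
  expect_identical(m$counts, matrix(c(1L, 0L, 0L, 1L, 2L, 0L, 0L, 0L, 0L), 3,
                                    dimnames = list(lg3$name, lg3$name)))
  expect_identical(m$n_valid, 4L)
  expect_equal(m$cell_area, 0.0625)

  # nodata in either input excludes the cell
  t2n <- t2
  t2n$values[1, 1] <- t2n$nodata
  mn <- cross_tabulate(t1, t2n)
  expect_identical(mn$n_valid, 3L)
  expect_identical(mn$counts, oracle_crosstab(t1, t2n))

  # identity map -> diagonal only
  mi <- cross_tabulate(t1, t1)
  expect_true(all(mi$counts[upper.tri(mi$counts) | lower.tri(mi$counts)] == 0))

  # property: random grids agree with the oracle, and transpose symmetry
  set.seed(7)
  for (k in 1:5) {
    a <- cat_raster(matrix(sample(1:3, 48, TRUE), 6), lg3)
    b <- cat_raster(matrix(sample(1:3, 48, TRUE), 6), lg3)
    b$values[sample(48, 4)] <- b$nodata
    expect_identical(cross_tabulate(a, b)$counts, oracle_crosstab(a, b))
    expect_identical(cross_tabulate(a, b)$counts,
                     t(cross_tabulate(b, a)$counts))
  }
})

test_that("change budget arithmetic and conservation", {
  cm <- matrix(0L, 3, 3, dimnames = list(lg3$name, lg3$name))
  cm[1, 2] <- 10L; cm[2, 1] <- 4L; diag(cm) <- c(5L, 5L, 3L)
  m <- structure(list(counts = cm, legend = lg3, n_valid = sum(cm),
                      cell_area = 0.0625), class = "TransitionCountMatrix")
  b <- change_budget(m)
  expect_equal(b$by_class$net_ha[2], 0.375)   # class beta gains 6 px net
  expect_equal(b$by_class$net_ha[1], -0.375)
  expect_equal(b$by_class$net_ha,
               b$by_class$gains_ha - b$by_class$losses_ha)
  expect_equal(sum(b$by_class$net_ha), 0)
  expect_equal(b$contributions, -t(b$contributions))

  # diagonal-only matrix: no change at all
  d <- structure(list(counts = diag(3L) * 5L, legend = lg3, n_valid = 15L,
                      cell_area = 0.0625), class = "TransitionCountMatrix")
  dimnames(d$counts) <- list(lg3$name, lg3$name)
  bd <- change_budget(d)
  expect_true(all(bd$by_class$gains_ha == 0 & bd$by_class$losses_ha == 0))
})

test_that("transition masks mark change only, with nodata propagated", {
  t1 <- cat_raster(matrix(c(2L, 1L, 3L, 1L), 2), lg3)
  t2 <- cat_raster(matrix(c(1L, 1L, 1L, 2L), 2), lg3)
  mk <- transition_mask(t1, t2, from_set = 1:3, to_set = 1L)
  expect_identical(mk$values[1, 1], 1L)  # 2 -> 1: change into target
  expect_identical(mk$values[2, 1], 0L)  # 1 -> 1: persistence is not change
  expect_identical(mk$values[1, 2], 1L)  # 3 -> 1
  expect_identical(mk$values[2, 2], 0L)  # 1 -> 2: not into to_set

  expect_true(all(transition_mask(t1, t1, 1:3, 1:3)$values == 0L))
  t2$values[1, 1] <- t2$nodata
  expect_identical(transition_mask(t1, t2, 1:3, 1L)$values[1, 1], t1$nodata)
  expect_error(transition_mask(t1, t2, integer(), 1L), "non-empty")
})

test_that("trend surface equals the normal-equations oracle", {
  # constant mask: exact fit at any order
  const <- cat_raster(matrix(1L, 6, 6), new_legend(0:1, c("n", "y")))
  expect_equal(trend_surface(const, 2)$values, matrix(1, 6, 6),
               tolerance = 1e-8)

  # west->east increasing change density: positive eastward gradient
  set.seed(11)
  dens <- matrix(rep(seq(0.05, 0.95, length.out = 12), each = 12), 12)
  mk <- cat_raster(matrix(as.integer(runif(144) < dens), 12),
                   new_legend(0:1, c("n", "y")))
  ts1 <- trend_surface(mk, 1)
  expect_true(all(diff(t(ts1$values)[, 1]) > 0))
  expect_equal(ts1$values, oracle_trend(mk, 1), tolerance = 1e-6)

  # order 3 on a random 10x10 mask
  mk2 <- cat_raster(matrix(as.integer(runif(100) < 0.4), 10),
                    new_legend(0:1, c("n", "y")))
  expect_equal(trend_surface(mk2, 3)$values, oracle_trend(mk2, 3),
               tolerance = 1e-6)

  # residual sum of squares is non-increasing in order
  rss <- vapply(1:4, function(o) {
    sum((mk2$values - trend_surface(mk2, o)$values)^2)
  }, numeric(1))
  expect_true(all(diff(rss) <= 1e-9))

  expect_error(trend_surface(cat_raster(matrix(1L, 2, 2),
                                        new_legend(0:1, c("n", "y"))), 3),
               "polynomial terms")
})

test_that("total area is conserved between the two dates", {
  set.seed(3)
  a <- cat_raster(matrix(sample(1:3, 100, TRUE), 10), lg3)
  b <- cat_raster(matrix(sample(1:3, 100, TRUE), 10), lg3)
  m <- cross_tabulate(a, b)
  expect_equal(sum(m$counts) * m$cell_area, sum(class_areas(a)))
  expect_equal(sum(class_areas(a)), sum(class_areas(b)))
})
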