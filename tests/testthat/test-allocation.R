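# hand-built potential stack helper
pot_stack <- function(template, ...) {
  ps <- list(...)
  lapply(ps, function(m) cont_raster(m, cellsize = template$cellsize,
                                     crs_tag = template$crs_tag))
}

demand_from_px <- function(px, legend, cell_ha = 0.0625) {
  dimnames(px) <- list(legend$name, legend$name)
  structure(list(D = px * cell_ha, legend = legend, horizon_years = 15),
            class = "ChangeDemand")
}

test_that("zero demand projects the identity map", {
  cur <- cat_raster(matrix(c(1L, 1L, 2L, 2L), 2), lg2)
  res <- allocate(cur, list(), demand_from_px(matrix(0, 2, 2), lg2), seed = 1)
  expect_identical(res$map$values, cur$values)
  expect_identical(sum(res$realized), 0L)
  expect_identical(res$conflicts, 0L)
})

test_that("top-ranked pixels change, exactly meeting demand", {
  cur <- cat_raster(matrix(1L, 5, 5), lg2)
  pot <- matrix(runif(25, 0.1, 0.2), 5)
  top <- c(3L, 11L, 24L)
  pot[top] <- c(0.9, 0.95, 0.99)
  res <- allocate(cur, pot_stack(cur, "1_2" = pot),
                  demand_from_px(matrix(c(0, 3, 0, 0), 2, byrow = TRUE), lg2),
                  seed = 4)
  expect_identical(which(res$map$values == 2L), sort(top))
  expect_identical(res$realized["one", "two"], 3L)
  expect_identical(sum(res$unmet), 0L)
})

test_that("conflicts resolve to the higher potential", {
  # pixel 1 is top-ranked for both 1->2 (0.7) and 1->3 (0.9); it must go to
  # the 0.9 transition, and 1->2 continues to its next-ranked pixel (5)
  cur <- cat_raster(matrix(1L, 3, 3), lg3)
  p12 <- matrix(0.01, 3, 3); p12[1] <- 0.7; p12[5] <- 0.6
  p13 <- matrix(0.02, 3, 3); p13[1] <- 0.9
  res <- allocate(cur, pot_stack(cur, "1_2" = p12, "1_3" = p13),
                  demand_from_px(matrix(c(0, 1, 1, rep(0, 6)), 3,
                                        byrow = TRUE), lg3),
                  seed = 4)
  expect_identical(res$map$values[1], 3L)
  expect_identical(res$map$values[5], 2L)
  expect_identical(res$conflicts, 1L)
  expect_identical(sum(res$unmet), 0L)
})

test_that("realized + unmet equals demand; determinism under seed", {
  set.seed(8)
  spec <- synthetic_scenario(seed = 7, shape = c(50, 50))
  g <- generate_t1(spec)
  t2 <- evolve(g, spec)
  ct <- cross_tabulate(g$map, t2)
  P <- estimate_matrix(ct, 8, 15)
  dem <- change_demand(P, class_areas(g$map))
  # random-but-fixed potentials for all six transitions
  pots <- list()
  for (i in 1:3) for (j in setdiff(1:3, i)) {
    pots[[sprintf("%d_%d", i, j)]] <- cont_raster(matrix(runif(2500), 50),
                                                  crs_tag = "synthetic")
  }
  res <- allocate(g$map, pots, dem, seed = 12)
  px_demand <- round(dem$D / 0.0625)
  diag(px_demand) <- 0
  expect_equal(res$realized + res$unmet, px_demand, ignore_attr = TRUE)
  # pixel count conserved, each pixel transitions at most once
  expect_identical(length(res$map$values), 2500L)
  expect_identical(sum(res$map$values != g$map$values), sum(res$realized))

  res2 <- allocate(g$map, pots, dem, seed = 12)
  expect_identical(res2$map$values, res$map$values)

  # class areas of the projection track the Markov expectation
  proj_areas <- class_areas(res$map)
  expected <- as.numeric(class_areas(g$map) %*% P$P)
  slack <- 0.0625 * (3 + sum(res$unmet))
  expect_true(all(abs(proj_areas - expected) <= slack + 0.0625 * 3))

  expect_error(allocate(g$map, pots["1_2"], dem, seed = 1), "no potential")
})

test_that("multi-step projection recomputes dynamic variables", {
  spec <- synthetic_scenario(
    seed = 19, shape = c(60, 60), shares = c(0.5, 0.5),
    P_true = matrix(c(0.8, 0.2, 0.02, 0.98), 2, byrow = TRUE),
    drivers = list(list(name = "grad", type = "smooth-gradient", beta = 1)))
  g <- generate_t1(spec)
  t2 <- evolve(g, spec)
  ct <- cross_tabulate(g$map, t2)
  P <- estimate_matrix(ct, 8, 16)
  vars <- c(g$drivers,
            list(d2 = distance_to_class(g$map, 2L)))
  models <- list()
  for (oc in 1:2) {
    s <- draw_samples(g$map, t2, oc, vars, n = 600, seed = 40 + oc)
    models[[as.character(oc)]] <- train_submodel(s)
  }

  # steps = 1 reduces exactly to allocate on the full-horizon demand
  pr1 <- project(t2, models, vars, dynamic = list(d2 = 2L), P, steps = 1,
                 seed = 77)
  vars1 <- vars
  vars1$d2 <- distance_to_class(t2, 2L)
  pots <- list()
  for (m in models) pots <- c(pots, predict_potentials(m, vars1, t2))
  direct <- allocate(t2, pots, change_demand(P, class_areas(t2)), seed = 77)
  expect_identical(pr1$map$values, direct$map$values)

  # steps = 3: the dynamic distance layer differs between steps wherever the
  # target class moved
  pr3 <- project(t2, models, vars, dynamic = list(d2 = 2L), P, steps = 3,
                 seed = 77)
  mid <- pr3$steps[[1]]$map
  expect_false(identical(distance_to_class(t2, 2L)$values,
                         distance_to_class(mid, 2L)$values))

  # identity matrix, any steps: map unchanged
  ident <- P
  ident$P <- diag(2)
  dimnames(ident$P) <- dimnames(P$P)
  pid <- project(t2, models, vars, dynamic = list(d2 = 2L), ident,
                 steps = 2, seed = 3)
  expect_identical(pid$map$values, t2$values)
})
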