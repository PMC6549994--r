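counts_2x2 <- function(m = matrix(c(90L, 10L, 20L, 80L), 2, byrow = TRUE)) {
  dimnames(m) <- list(lg2$name, lg2$name)
  structure(list(counts = m, legend = lg2, n_valid = sum(m),
                 cell_area = 0.0625), class = "TransitionCountMatrix")
}

test_that("matrix estimation normalizes rows and rescales horizons", {
  cm <- counts_2x2()
  P8 <- estimate_matrix(cm, 8, 8)
  expect_equal(P8$P, matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE,
                            dimnames = list(lg2$name, lg2$name)))
  expect_equal(P8$horizon_years, 8)
  expect_true(is_row_stochastic(P8$P))

  # doubling the horizon is exactly the matrix square
  P16 <- estimate_matrix(cm, 8, 16)
  expect_equal(P16$P, P8$P %*% P8$P, tolerance = 1e-9)
  expect_equal(unname(P16$P[1, ]), c(0.83, 0.17), tolerance = 1e-9)

  # diagonal counts -> identity at any horizon
  ident <- estimate_matrix(counts_2x2(matrix(c(5L, 0L, 0L, 7L), 2)), 8, 15)
  expect_equal(unname(ident$P), diag(2), tolerance = 1e-12)

  # semigroup property of the fractional power
  P4 <- estimate_matrix(cm, 8, 4)
  expect_equal(P4$P %*% P4$P, P8$P, tolerance = 1e-6)

  # a class absent at t1 is an error
  empty <- counts_2x2(matrix(c(0L, 0L, 20L, 80L), 2, byrow = TRUE))
  expect_error(estimate_matrix(empty, 8, 15), "absent")

  # linear fallback scales off-diagonal mass and restores the diagonal
  Plin <- estimate_matrix(cm, 8, 16, rescale = "linear")
  expect_equal(unname(Plin$P[1, ]), c(0.8, 0.2))
  expect_true(is_row_stochastic(Plin$P))
})

test_that("published matrices pass the validator only at printed tolerance", {
  bau <- wales_transition_matrix("bau")
  ec <- wales_transition_matrix("ec")
  expect_true(is_row_stochastic(bau$P, tol = 0.005))
  expect_true(is_row_stochastic(ec$P, tol = 0.005))
  expect_false(is_row_stochastic(bau$P, tol = 1e-9))
  expect_false(is_row_stochastic(ec$P, tol = 1e-9))
})

test_that("scenario edits reproduce the published conservation matrix cells", {
  bau <- wales_transition_matrix("bau")
  ec <- apply_scenario(bau, wales_ec_scenario())
  # conifer -> broadleaf scaled by 1.5 (0.188 -> 0.282), donor = diagonal
  expect_equal(ec$P["conifer forest", "broadleaf forest"], 0.282,
               tolerance = 1e-12)
  expect_equal(ec$P["conifer forest", "conifer forest"], 0.660,
               tolerance = 1e-9)
  # mountain/heath/bog persistence 0.211 -> 0.316, donor = largest off-diag
  expect_equal(ec$P["mountain heath and bog", "mountain heath and bog"],
               0.316, tolerance = 1e-9)
  expect_equal(ec$P["mountain heath and bog", "semi-natural grassland"],
               0.347, tolerance = 1e-9)
  # broadleaf row pinned to identity
  expect_equal(unname(ec$P["broadleaf forest", ]), c(1, 0, 0, 0, 0, 0))
  # untouched rows unchanged
  expect_equal(ec$P["arable land", ], bau$P["arable land", ])
})

test_that("scenario edits preserve row sums and reject bad donors", {
  P <- structure(
    list(P = matrix(c(0.7, 0.2, 0.1,
                      0.15, 0.8, 0.05,
                      0.1, 0.1, 0.8), 3, byrow = TRUE,
                    dimnames = list(lg3$name, lg3$name)),
         horizon_years = 10, legend = lg3),
    class = "TransitionProbabilityMatrix")
  e1 <- apply_scenario(P, list(edit_scale_cell("alpha", "beta", 1.5)))
  expect_equal(rowSums(e1$P), rep(1, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
  e2 <- apply_scenario(P, list(edit_scale_diagonal("gamma", 1.1)))
  expect_equal(rowSums(e2$P), rep(1, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(e2$P["gamma", "gamma"], 0.88)

  # donor underflow: scaling a large cell beyond what the donor holds
  expect_error(
    apply_scenario(P, list(edit_scale_cell("beta", "alpha", 6.5))),
    "donor underflow")
  expect_error(
    apply_scenario(P, list(edit_scale_cell("alpha", "nosuch", 1.5))),
    "unknown class")
  # edits are order-dependent: identity row then scale fails (cell is 0)
  both <- apply_scenario(P, list(
    edit_fix_row_identity("alpha"),
    edit_scale_cell("alpha", "beta", 2, donor = "gamma")))
  expect_equal(unname(both$P["alpha", ]), c(1, 0, 0))
})

test_that("change demand distributes baseline areas along matrix rows", {
  P <- structure(
    list(P = matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE,
                    dimnames = list(lg2$name, lg2$name)),
         horizon_years = 15, legend = lg2),
    class = "TransitionProbabilityMatrix")
  d <- change_demand(P, c(one = 100, two = 50))
  expect_equal(unname(d$D), matrix(c(90, 10, 10, 40), 2, byrow = TRUE))
  expect_equal(rowSums(d$D), c(one = 100, two = 50))
  expect_equal(sum(d$D), 150)  # conservation

  ident <- P
  ident$P <- diag(2)
  dimnames(ident$P) <- dimnames(P$P)
  di <- change_demand(ident, c(one = 10, two = 20))
  expect_equal(unname(diag(di$D)), c(10, 20))
  expect_true(all(di$D[upper.tri(di$D) | lower.tri(di$D)] == 0))

  expect_error(change_demand(P, c(bad = 1, worse = 2)), "legend")
})

test_that("matrix CSV round-trips with legend labels", {
  bau <- wales_transition_matrix("bau")
  f <- withr::local_tempfile(fileext = ".csv")
  write_matrix_csv(bau, f)
  back <- read_matrix_csv(f)
  expect_equal(back, bau$P)
})
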