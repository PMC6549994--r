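# ---------------------------------------------------------------------------
# Synthetic landscapes with known dynamics: spatially autocorrelated class
# maps, covariate drivers, and two-date change governed by a known
# row-stochastic matrix — so every pipeline stage has a ground truth.
# ---------------------------------------------------------------------------

# dense separable Gaussian smoothing with edge renormalization
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  op <- function(n) {
    S <- outer(seq_len(n), seq_len(n),
               function(i, j) exp(-(i - j)^2 / (2 * sigma^2)))
    S / rowSums(S)
  }
  op(nrow(m)) %*% m %*% t(op(ncol(m)))
}

#' Describe a synthetic landscape scenario
#'
#' The stated world of the generator: grid geometry, class shares, spatial
#' autocorrelation length, the true per-base-interval transition matrix, and
#' covariate drivers with their effect sizes on the transition log-odds.
#'
#' @param seed integer seed governing all randomness downstream.
#' @param shape `c(nrows, ncols)` (default 100 x 100).
#' @param cellsize pixel size in map units (default 25 m, the resolution of
#'   the national land-cover products this emulates).
#' @param shares per-class target area shares (sum to 1); class codes are
#'   `seq_along(shares)`.
#' @param autocorr autocorrelation length in pixels (Gaussian smoothing sd,
#'   default 8 — patch sizes of a few hundred metres at 25 m pixels).
#' @param P_true row-stochastic K x K matrix of per-interval transition
#'   probabilities.
#' @param drivers list of driver specs: `list(name=, type=, beta=)`, type one
#'   of `"smooth-gradient"`, `"smoothed-noise"`, `"distance-to-random-lines"`;
#'   `beta` scales the driver's effect on the transition log-odds (0 = inert).
#' @param base_years length of the observed interval (default 8 years,
#'   matching a 2007-2015 style map pair).
#' @return a `SyntheticScenario`.
#' @export
synthetic_scenario <- function(seed, shape = c(100, 100), cellsize = 25,
                               shares = c(0.3, 0.3, 0.4), autocorr = 8,
                               P_true = NULL, drivers = list(),
                               base_years = 8) {
  K <- length(shares)
  stopifnot(abs(sum(shares) - 1) < 1e-9, autocorr >= 1)
  if (is.null(P_true)) {
    P_true <- matrix(0.05 / (K - 1), K, K)
    diag(P_true) <- 0.95
  }
  stopifnot(nrow(P_true) == K, is_row_stochastic(P_true, tol = 1e-9))
  structure(list(seed = seed, shape = shape, cellsize = cellsize,
                 shares = shares, autocorr = autocorr, P_true = P_true,
                 drivers = drivers, base_years = base_years,
                 legend = new_legend(seq_len(K), paste0("class_", seq_len(K)))),
            class = "SyntheticScenario")
}

make_driver <- function(type, shape, cellsize) {
  nr <- shape[1]; nc <- shape[2]
  v <- switch(type,
    "smooth-gradient" = {
      # west -> east ramp with a mild random tilt
      tilt <- runif(1, -0.3, 0.3)
      outer(seq_len(nr) / nr, seq_len(nc) / nc,
            function(r, c) c + tilt * r)
    },
    "smoothed-noise" = {
      f <- gauss_smooth(matrix(rnorm(nr * nc), nr, nc), 5)
      (f - min(f)) / (max(f) - min(f))
    },
    "distance-to-random-lines" = {
      tgt <- matrix(FALSE, nr, nc)
      for (k in 1:3) {  # random chords across the grid, densely rasterized
        a <- c(runif(1, 1, nr), runif(1, 1, nc))
        b <- c(runif(1, 1, nr), runif(1, 1, nc))
        tt <- seq(0, 1, length.out = 4 * max(nr, nc))
        rr <- pmin(pmax(round(a[1] + tt * (b[1] - a[1])), 1), nr)
        cc <- pmin(pmax(round(a[2] + tt * (b[2] - a[2])), 1), nc)
        tgt[cbind(rr, cc)] <- TRUE
      }
      edt_cpp(tgt) * cellsize
    },
    stop("unknown driver type: ", type))
  new_continuous_raster(v, cellsize = cellsize, crs_tag = "synthetic")
}

#' Generate the first-date synthetic map and its drivers
#'
#' Classes come from quantile-thresholding a Gaussian-smoothed white-noise
#' field at the scenario's target shares, which yields spatially
#' autocorrelated patches with (up to ties) exact share control. Drivers are
#' built per the scenario spec. Deterministic under the scenario seed.
#'
#' @param spec a `SyntheticScenario`.
#' @return list with `map` (`CategoricalRaster`) and `drivers` (named list of
#'   `ContinuousRaster`s).
#' @export
generate_t1 <- function(spec) {
  with_seed(spec$seed, {
    nr <- spec$shape[1]; nc <- spec$shape[2]
    if (nr * nc < length(spec$shares)) stop("grid too small for class count")
    f <- gauss_smooth(matrix(rnorm(nr * nc), nr, nc), spec$autocorr)
    qs <- quantile(f, cumsum(spec$shares)[-length(spec$shares)])
    cls <- matrix(findInterval(f, qs) + 1L, nr, nc)
    drv <- lapply(spec$drivers,
                  function(d) make_driver(d$type, spec$shape, spec$cellsize))
    names(drv) <- vapply(spec$drivers, `[[`, "", "name")
    list(map = new_categorical_raster(cls, spec$legend,
                                      cellsize = spec$cellsize,
                                      crs_tag = "synthetic"),
         drivers = drv)
  })
}

#' Evolve the synthetic map one base interval forward
#'
#' Each pixel of class i transitions to class j with probability
#' `P_true[i, j]` modulated multiplicatively by a logistic factor of its
#' driver values, renormalized within each origin class so that the
#' class-mean transition probabilities equal `P_true` exactly in expectation
#' (per-realization frequencies carry binomial sampling error). With all
#' driver effects zero the process is spatially homogeneous. Deterministic
#' under the scenario seed.
#'
#' @param t1 output of [generate_t1()] (list with `map` and `drivers`), or a
#'   `CategoricalRaster` (then `drivers` must be passed).
#' @param spec the `SyntheticScenario`.
#' @param drivers named driver list if `t1` is a bare raster.
#' @return the second-date `CategoricalRaster`.
#' @export
evolve <- function(t1, spec, drivers = NULL) {
  if (is.list(t1) && !is_categorical(t1)) {
    drivers <- t1$drivers
    t1 <- t1$map
  }
  betas <- vapply(spec$drivers, `[[`, 0, "beta")
  names(betas) <- vapply(spec$drivers, `[[`, "", "name")
  n_cell <- length(t1$values)
  lin <- rep(0, n_cell)
  for (nm in names(betas)) {
    if (betas[[nm]] == 0) next
    z <- as.vector(drivers[[nm]]$values)
    z <- (z - mean(z)) / max(stats::sd(z), .Machine$double.eps)
    lin <- lin + betas[[nm]] * z
  }
  mod <- stats::plogis(lin)
  K <- nrow(spec$P_true)
  out <- t1$values
  with_seed(spec$seed + 1L, {
    for (i in seq_len(K)) {
      idx <- which(t1$values == i)
      if (length(idx) == 0L) next
      m_i <- mod[idx] / mean(mod[idx])
      Q <- outer(m_i, spec$P_true[i, ])   # per-pixel off-diagonal probs
      Q[, i] <- 0
      tot <- rowSums(Q)
      over <- tot > 1                      # clip rare over-unit rows
      if (any(over)) Q[over, ] <- Q[over, , drop = FALSE] / tot[over]
      Q[, i] <- 1 - pmin(tot, 1)
      u <- runif(length(idx))
      cum <- Q %*% upper.tri(diag(K), diag = TRUE)
      cum[, K] <- 1  # guard against float shortfall in the last bin
      dest <- max.col(cum >= u, ties.method = "first")
      out[idx] <- dest
    }
  })
  r <- t1
  r$values <- matrix(as.integer(out), nrow(t1$values), ncol(t1$values))
  r
}
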