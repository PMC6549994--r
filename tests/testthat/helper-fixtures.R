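# Fixture builders and independent brute-force oracles shared by the suite.
# All fixtures are constructed in code; nothing is read from disk except
# round-trip temporaries the tests themselves write.

lg3 <- landmarkov::new_legend(1:3, c("alpha", "beta", "gamma"))
lg2 <- landmarkov::new_legend(1:2, c("one", "two"))

cat_raster <- function(m, legend = NULL, cellsize = 25, nodata = -9999L,
                       crs_tag = "local") {
  m <- as.matrix(m)
  if (is.null(legend)) {
    codes <- sort(unique(as.integer(m[!is.na(m) & m != nodata])))
    legend <- landmarkov::new_legend(codes, paste0("c", codes))
  }
  landmarkov::new_categorical_raster(m, legend, nodata = nodata,
                                     cellsize = cellsize, crs_tag = crs_tag)
}

cont_raster <- function(m, cellsize = 25, crs_tag = "local") {
  landmarkov::new_continuous_raster(as.matrix(m), cellsize = cellsize,
                                    crs_tag = crs_tag)
}

# oracle: per-pixel enumeration cross-tabulation
oracle_crosstab <- function(t1, t2) {
  K <- nrow(t1$legend)
  out <- matrix(0L, K, K, dimnames = list(t1$legend$name, t1$legend$name))
  for (i in seq_len(nrow(t1$values))) {
    for (j in seq_len(ncol(t1$values))) {
      a <- t1$values[i, j]; b <- t2$values[i, j]
      if (is.na(a) || is.na(b) || a == t1$nodata || b == t2$nodata) next
      out[match(a, t1$legend$code), match(b, t1$legend$code)] <-
        out[match(a, t1$legend$code), match(b, t1$legend$code)] + 1L
    }
  }
  out
}

# oracle: brute-force all-pairs Euclidean distance to nearest target cell
oracle_distance <- function(map, target) {
  v <- map$values
  tgt <- which(v %in% target & v != map$nodata, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(v), ncol(v))
  for (i in seq_len(nrow(v))) {
    for (j in seq_len(ncol(v))) {
      out[i, j] <- sqrt(min((tgt[, 1] - i)^2 + (tgt[, 2] - j)^2)) *
        map$cellsize
    }
  }
  out
}

# oracle: chi-squared / Cramer's V from a contingency table by definition
oracle_cramers_v <- function(tab) {
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  x2 <- sum((tab - e)^2 / e)
  sqrt(x2 / (n * (min(dim(tab)) - 1)))
}

# oracle: polynomial trend fit through the explicit normal equations
oracle_trend <- function(mask, order) {
  ok <- !is.na(mask$values) & mask$values != mask$nodata
  nr <- nrow(mask$values); nc <- ncol(mask$values)
  xs <- if (nc > 1) 2 * (seq_len(nc) - 1) / (nc - 1) - 1 else rep(0, nc)
  ys <- if (nr > 1) 2 * (nr - seq_len(nr)) / (nr - 1) - 1 else rep(0, nr)
  X <- matrix(xs, nr, nc, byrow = TRUE)[ok]
  Y <- matrix(ys, nr, nc)[ok]
  cols <- list()
  for (d in 0:order) for (p in d:0) cols[[length(cols) + 1L]] <- X^p * Y^(d - p)
  M <- do.call(cbind, cols)
  beta <- solve(t(M) %*% M, t(M) %*% as.numeric(mask$values[ok]))
  out <- matrix(NA_real_, nr, nc)
  out[ok] <- as.vector(M %*% beta)
  out
}

# join-count: fraction of rook-adjacent pixel pairs sharing a class
join_count <- function(map) {
  v <- map$values
  h <- v[, -1] == v[, -ncol(v)]
  w <- v[-1, ] == v[-nrow(v), ]
  mean(c(h, w))
}

# Standard synthetic world for driver/MLP recovery: one informative
# smooth-gradient driver (beta > 0) and three inert noise drivers.
# p_change = 0.3 keeps both sample strata at quota (balanced labels): with a
# rarer transition the stratified sample is majority-persist and the
# Bayes-argmax classifier is blind to any driver, so no selection procedure
# could recover it.
recovery_spec <- function(seed, shape = c(120, 120), beta = 3,
                          p_change = 0.3) {
  landmarkov::synthetic_scenario(
    seed = seed, shape = shape, shares = c(0.5, 0.5),
    P_true = matrix(c(1 - p_change, p_change, 0.05, 0.95), 2, byrow = TRUE),
    drivers = list(
      list(name = "alt", type = "smooth-gradient", beta = beta),
      list(name = "n1", type = "smoothed-noise", beta = 0),
      list(name = "n2", type = "smoothed-noise", beta = 0),
      list(name = "n3", type = "smoothed-noise", beta = 0)))
}

# the true per-pixel modulation factor used by evolve()
true_modulation <- function(spec, drivers) {
  lin <- 0
  for (d in spec$drivers) {
    if (d$beta == 0) next
    z <- as.vector(drivers[[d$name]]$values)
    lin <- lin + d$beta * (z - mean(z)) / sd(z)
  }
  plogis(lin)
}
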