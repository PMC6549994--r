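# ---------------------------------------------------------------------------
# Change analysis between two dates: cross-tabulation, gains/losses/net
# change budgets, Boolean transition masks, polynomial trend surfaces.
# ---------------------------------------------------------------------------

#' Cross-tabulate two categorical rasters
#'
#' Counts, for every ordered pair of classes, the pixels holding class i at the
#' first date and class j at the second. Cells that are nodata in either input
#' are excluded. Matrix rows and columns follow the legend order.
#'
#' @param t1,t2 co-registered `CategoricalRaster`s sharing one legend.
#' @return a `TransitionCountMatrix`: list with `counts` (K x K integer matrix,
#'   dimnames = class names), `legend`, `n_valid` and `cell_area` (hectares).
#' @export
cross_tabulate <- function(t1, t2) {
  assert_coregistered(t1, t2)
  if (!identical(t1$legend$code, t2$legend$code) ||
      !identical(t1$legend$name, t2$legend$name)) {
    stop("legend mismatch between the two rasters")
  }
  ok <- valid_mask(t1) & valid_mask(t2)
  if (!any(ok)) stop("zero valid cells in common")
  lg <- t1$legend
  f1 <- factor(t1$values[ok], levels = lg$code)
  f2 <- factor(t2$values[ok], levels = lg$code)
  counts <- table(f1, f2)
  counts <- matrix(as.integer(counts), nrow = nrow(lg),
                   dimnames = list(lg$name, lg$name))
  structure(
    list(counts = counts, legend = lg, n_valid = sum(ok),
         cell_area = cell_area_ha(t1)),
    class = "TransitionCountMatrix")
}

#' @export
print.TransitionCountMatrix <- function(x, ...) {
  cat(sprintf("TransitionCountMatrix: %d classes, %d valid pixels, cell %g ha\n",
              nrow(x$counts), x$n_valid, x$cell_area))
  print(x$counts)
  invisible(x)
}

#' Gains, losses, net change and pairwise contributions
#'
#' For each class j: gains = area moving into j from other classes, losses =
#' area moving out, net = gains - losses. The contribution of class i to the
#' net change of class j is `(counts[i,j] - counts[j,i]) * cell_area`
#' (antisymmetric, so net changes sum to zero over classes).
#'
#' @param m a `TransitionCountMatrix`.
#' @return a `ChangeBudget`: list with `by_class` (data.frame class / gains_ha /
#'   losses_ha / net_ha) and `contributions` (K x K signed ha matrix).
#' @export
change_budget <- function(m) {
  cm <- m$counts
  a <- m$cell_area
  gains <- (colSums(cm) - diag(cm)) * a
  losses <- (rowSums(cm) - diag(cm)) * a
  contrib <- (cm - t(cm)) * a
  structure(
    list(by_class = data.frame(class = rownames(cm), gains_ha = gains,
                               losses_ha = losses, net_ha = gains - losses,
                               row.names = NULL, stringsAsFactors = FALSE),
         contributions = contrib),
    class = "ChangeBudget")
}

#' @export
print.ChangeBudget <- function(x, ...) {
  print(x$by_class)
  invisible(x)
}

#' Boolean transition mask
#'
#' Marks 1 every cell whose class moved from a member of `from_set` to a member
#' of `to_set` between the two dates; persistence (class unchanged) is never
#' change, even when the class is in both sets. Nodata in either input
#' propagates.
#'
#' @param t1,t2 co-registered `CategoricalRaster`s.
#' @param from_set,to_set non-empty integer vectors of class codes.
#' @return a 0/1 `CategoricalRaster` (legend `0 = no_change, 1 = change`).
#' @export
transition_mask <- function(t1, t2, from_set, to_set) {
  assert_coregistered(t1, t2)
  if (length(from_set) == 0L || length(to_set) == 0L) {
    stop("from_set and to_set must be non-empty")
  }
  ok <- valid_mask(t1) & valid_mask(t2)
  v <- matrix(NA_integer_, nrow(t1$values), ncol(t1$values))
  v[ok] <- as.integer(t1$values[ok] %in% from_set &
                      t2$values[ok] %in% to_set &
                      t1$values[ok] != t2$values[ok])
  v[!ok] <- t1$nodata
  new_categorical_raster(v, new_legend(0:1, c("no_change", "change")),
                         nodata = t1$nodata, xll = t1$xll, yll = t1$yll,
                         cellsize = t1$cellsize, crs_tag = t1$crs_tag)
}

# design matrix of bivariate monomials x^p * y^q, p + q <= order, on
# coordinates standardized to [-1, 1] for numerical stability
poly_terms <- function(x, y, order) {
  cols <- list()
  nm <- character()
  for (d in 0:order) {
    for (p in d:0) {
      q <- d - p
      cols[[length(cols) + 1L]] <- x^p * y^q
      nm <- c(nm, paste0("x", p, "y", q))
    }
  }
  mm <- do.call(cbind, cols)
  colnames(mm) <- nm
  mm
}

standardize_coord <- function(v) {
  rng <- range(v)
  if (diff(rng) == 0) return(rep(0, length(v)))
  2 * (v - rng[1]) / diff(rng) - 1
}

#' Trend surface of change intensity
#'
#' Fits the 0/1 change indicator by least squares on a bivariate polynomial of
#' pixel-centre coordinates up to `order`, and returns the fitted surface
#' evaluated over the grid. This is the classic polynomial trend-surface map of
#' where change concentrates spatially.
#'
#' @param mask a 0/1 `CategoricalRaster` (e.g. from [transition_mask()]).
#' @param order polynomial order (>= 1; default 3, cubic).
#' @return a `ContinuousRaster` of fitted change intensity (valid cells only).
#' @export
trend_surface <- function(mask, order = 3) {
  if (order < 1) stop("order must be >= 1")
  ok <- valid_mask(mask)
  n_terms <- (order + 1) * (order + 2) / 2
  if (sum(ok) < n_terms) {
    stop(sprintf("only %d valid cells for %d polynomial terms", sum(ok),
                 n_terms))
  }
  ctr <- pixel_centers(mask)
  xs <- standardize_coord(ctr$x)
  ys <- standardize_coord(ctr$y)
  X <- matrix(xs, nrow(mask$values), ncol(mask$values), byrow = TRUE)
  Y <- matrix(ys, nrow(mask$values), ncol(mask$values))
  mm <- poly_terms(X[ok], Y[ok], order)
  fit <- lm.fit(mm, as.numeric(mask$values[ok]))
  out <- matrix(NA_real_, nrow(mask$values), ncol(mask$values))
  out[ok] <- as.vector(mm %*% ifelse(is.na(fit$coefficients), 0,
                                     fit$coefficients))
  new_continuous_raster(out, xll = mask$xll, yll = mask$yll,
                        cellsize = mask$cellsize, crs_tag = mask$crs_tag,
                        units = "change intensity")
}
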