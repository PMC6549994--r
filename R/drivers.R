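# ---------------------------------------------------------------------------
# Driver variables: distance transforms, evidence likelihood, Cramer's V
# screening.
# ---------------------------------------------------------------------------

#' Euclidean distance to the nearest cell of a class set
#'
#' Exact Euclidean distance (pixel centre to pixel centre, in map units) from
#' every cell to the nearest cell whose class is in `target`. Target cells have
#' distance 0. Distance-to-class layers are the pipeline's dynamic variables:
#' they must be recomputed whenever the map changes during projection.
#'
#' @param map a `CategoricalRaster`.
#' @param target non-empty set of class codes.
#' @return a `ContinuousRaster` of distances (map units).
#' @export
distance_to_class <- function(map, target) {
  tgt <- valid_mask(map) & matrix(map$values %in% target, nrow(map$values))
  if (!any(tgt)) stop("no cells of target class(es) present; distance undefined")
  d <- edt_cpp(tgt) * map$cellsize
  d[!valid_mask(map)] <- NA_real_
  new_continuous_raster(d, xll = map$xll, yll = map$yll,
                        cellsize = map$cellsize, crs_tag = map$crs_tag,
                        units = "map units")
}

#' Evidence likelihood of change for a categorical layer
#'
#' Converts a qualitative layer (e.g. soil type, or a historical LULC map)
#' into a continuous suitability surface: each category c receives the
#' relative frequency with which c occurs inside observed change areas,
#' `EL(c) = #(change cells with category c) / #(change cells)`, so the values
#' over categories sum to 1. The alternative reading
#' `mode = "conditional"` instead assigns `P(change | category)`.
#'
#' @param categorical a `CategoricalRaster` (the qualitative layer).
#' @param change a 0/1 `CategoricalRaster` change mask, co-registered.
#' @param mode `"relative_frequency"` (default) or `"conditional"`.
#' @return a `ContinuousRaster` of per-category values painted on the grid.
#' @export
evidence_likelihood <- function(categorical, change,
                                mode = c("relative_frequency", "conditional")) {
  mode <- match.arg(mode)
  assert_coregistered(categorical, change)
  ok <- valid_mask(categorical) & valid_mask(change)
  ch <- ok & change$values == 1L
  if (!any(ch)) stop("change mask contains no change cells")
  codes <- categorical$legend$code
  n_ch <- tabulate(match(categorical$values[ch], codes), length(codes))
  el <- if (mode == "relative_frequency") {
    n_ch / sum(n_ch)
  } else {
    n_all <- tabulate(match(categorical$values[ok], codes), length(codes))
    ifelse(n_all > 0, n_ch / n_all, 0)
  }
  out <- matrix(NA_real_, nrow(categorical$values), ncol(categorical$values))
  out[ok] <- el[match(categorical$values[ok], codes)]
  new_continuous_raster(out, xll = categorical$xll, yll = categorical$yll,
                        cellsize = categorical$cellsize,
                        crs_tag = categorical$crs_tag,
                        units = "evidence likelihood")
}

# chi-squared statistic of a contingency table, empty rows/cols removed
chisq_stat <- function(tab) {
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  n <- sum(tab)
  expd <- outer(rowSums(tab), colSums(tab)) / n
  list(stat = sum((tab - expd)^2 / expd), dims = dim(tab), n = n)
}

#' Cramer's V association between a variable and a categorical response
#'
#' Measures how strongly a candidate driver is associated with a categorical
#' response (typically the observed-change map or a transition mask).
#' Continuous variables are discretized into `n_bins` equal-interval bins over
#' their valid range; categorical rasters use their classes directly. Then
#' `V = sqrt(chisq / (n * (min(r, c) - 1)))` on the bin x response table, with
#' empty rows/columns dropped before `min(r, c)`.
#'
#' @param variable a `ContinuousRaster` or `CategoricalRaster` driver.
#' @param response a `CategoricalRaster` with >= 2 classes among valid cells.
#' @param n_bins bins for continuous variables (default 256, equal interval).
#' @return V in `[0, 1]`.
#' @export
cramers_v <- function(variable, response, n_bins = 256) {
  assert_coregistered(variable, response)
  ok <- valid_mask(variable) & valid_mask(response)
  resp <- response$values[ok]
  if (length(unique(resp)) < 2L) stop("response is constant; V undefined")
  v <- variable$values[ok]
  g <- if (is_categorical(variable)) {
    factor(v)
  } else {
    rng <- range(v)
    if (diff(rng) == 0) {
      factor(rep(1L, length(v)))
    } else {
      cut(v, breaks = seq(rng[1], rng[2], length.out = n_bins + 1L),
          include.lowest = TRUE)
    }
  }
  cs <- chisq_stat(table(g, factor(resp)))
  if (min(cs$dims) < 2L) return(0)
  sqrt(cs$stat / (cs$n * (min(cs$dims) - 1L)))
}

#' Screen driver variables by Cramer's V
#'
#' Partitions variables into retained (`V > threshold`, strictly) and dropped,
#' preserving input order. Values exactly at the threshold are dropped.
#'
#' @param vars data.frame with at least columns `name` and `cramers_v`
#'   (additional columns such as `type` are carried through).
#' @param threshold retention threshold (default 0.15).
#' @return a `ScreeningResult`: list with `retained`, `dropped` (data.frames)
#'   and `threshold`.
#' @export
screen_variables <- function(vars, threshold = 0.15) {
  stopifnot(is.data.frame(vars))
  if (nrow(vars) == 0L) {
    return(structure(list(retained = vars, dropped = vars,
                          threshold = threshold), class = "ScreeningResult"))
  }
  if (!all(c("name", "cramers_v") %in% names(vars))) {
    stop("vars needs columns 'name' and 'cramers_v'")
  }
  if (any(vars$cramers_v < 0 | vars$cramers_v > 1)) {
    stop("cramers_v values must lie in [0, 1]")
  }
  keep <- vars$cramers_v > threshold
  structure(list(retained = vars[keep, , drop = FALSE],
                 dropped = vars[!keep, , drop = FALSE],
                 threshold = threshold),
            class = "ScreeningResult")
}

#' @export
print.ScreeningResult <- function(x, ...) {
  cat(sprintf("Screening at V > %g: %d retained, %d dropped\n", x$threshold,
              nrow(x$retained), nrow(x$dropped)))
  invisible(x)
}
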