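# ---------------------------------------------------------------------------
# Spatial allocation: turn change demand + transition potentials into a
# projected map by greedy ranked assignment, and multi-step projection with
# dynamic-variable recomputation.
# ---------------------------------------------------------------------------

#' Allocate change demand onto the map by ranked potential
#'
#' For every demanded transition i -> j, the `D_ij` pixels of class i with the
#' highest potential for that transition change to j. A pixel claimed by
#' several transitions goes to the one for which its potential is highest; the
#' losing transition continues down its own ranking. Demand in hectares is
#' converted to whole pixels with round-half-even. Ties in potential are
#' broken by a seeded permutation of cell indices, so allocation is
#' deterministic given the seed. Shortfalls (fewer eligible pixels than
#' demanded) are reported as unmet demand, never redistributed.
#'
#' @param current a `CategoricalRaster`.
#' @param potentials a `PotentialStack` (or plain named list of
#'   `ContinuousRaster`s keyed `"<from>_<to>"` by class code) covering every
#'   demanded transition.
#' @param demand a `ChangeDemand` on the same legend.
#' @param seed tie-break seed (required).
#' @return an `AllocationResult`: `map` (projected `CategoricalRaster`),
#'   `realized` and `unmet` (K x K pixel-count matrices), `conflicts`
#'   (number of pixel claims displaced by a higher-potential transition).
#' @export
allocate <- function(current, potentials, demand, seed) {
  if (missing(seed)) stop("seed is required")
  if (!identical(current$legend$code, demand$legend$code)) {
    stop("legend mismatch between map and demand")
  }
  lg <- current$legend
  K <- nrow(lg)
  cell_ha <- cell_area_ha(current)
  px <- round(demand$D / cell_ha)  # round-half-even pixel demand
  if (any(px < 0)) stop("negative demand")
  storage.mode(px) <- "integer"
  diag(px) <- 0L

  keys <- which(px > 0, arr.ind = TRUE)
  realized <- matrix(0L, K, K, dimnames = dimnames(demand$D))
  unmet <- realized
  out_vals <- current$values
  if (nrow(keys) == 0L) {
    return(structure(list(map = current, realized = realized, unmet = unmet,
                          conflicts = 0L), class = "AllocationResult"))
  }

  tie_rank <- with_seed(seed, sample.int(length(current$values)))

  trans <- vector("list", nrow(keys))
  for (r in seq_len(nrow(keys))) {
    i <- keys[r, 1]; j <- keys[r, 2]
    key <- sprintf("%d_%d", lg$code[i], lg$code[j])
    pot <- potentials[[key]]
    if (is.null(pot)) stop("no potential raster for demanded transition ", key)
    assert_coregistered(current, pot)
    elig <- which(valid_mask(current) & current$values == lg$code[i] &
                  !is.na(pot$values))
    ord <- elig[order(-pot$values[elig], tie_rank[elig])]
    trans[[r]] <- list(i = i, j = j, cand = ord, pot = pot$values,
                       need = px[i, j], pos = 1L)
  }

  # assignment state per cell: winning transition row and its potential
  assigned_tr <- integer(length(current$values))
  assigned_pot <- rep(-Inf, length(current$values))
  conflicts <- 0L
  queue <- seq_along(trans)
  while (length(queue) > 0L) {
    r <- queue[1L]
    queue <- queue[-1L]
    t <- trans[[r]]
    while (t$need > 0L && t$pos <= length(t$cand)) {
      p <- t$cand[t$pos]
      t$pos <- t$pos + 1L
      my_pot <- t$pot[p]
      if (assigned_tr[p] == 0L) {
        assigned_tr[p] <- r
        assigned_pot[p] <- my_pot
        t$need <- t$need - 1L
      } else if (my_pot > assigned_pot[p]) {
        # equal potentials: first claimant keeps the pixel (claim order is
        # itself deterministic through the seeded tie rank)
        loser <- assigned_tr[p]
        assigned_tr[p] <- r
        assigned_pot[p] <- my_pot
        t$need <- t$need - 1L
        conflicts <- conflicts + 1L
        trans[[loser]]$need <- trans[[loser]]$need + 1L
        if (!(loser %in% queue)) queue <- c(queue, loser)
      }
    }
    trans[[r]] <- t
  }

  for (r in seq_along(trans)) {
    t <- trans[[r]]
    got <- px[t$i, t$j] - t$need
    realized[t$i, t$j] <- got
    unmet[t$i, t$j] <- t$need
  }
  chg <- which(assigned_tr > 0L)
  for (p in chg) out_vals[p] <- lg$code[trans[[assigned_tr[p]]]$j]

  map <- current
  map$values <- out_vals
  structure(list(map = map, realized = realized, unmet = unmet,
                 conflicts = conflicts), class = "AllocationResult")
}

#' @export
print.AllocationResult <- function(x, ...) {
  cat(sprintf("AllocationResult: %d pixels changed, %d unmet, %d conflicts\n",
              sum(x$realized), sum(x$unmet), x$conflicts))
  invisible(x)
}

#' Project a map forward under a transition matrix
#'
#' Repeats, `steps` times: recompute dynamic distance-to-class variables from
#' the current map, predict transition potentials from the sub-models, compute
#' per-step change demand from the per-step matrix (the full-horizon matrix
#' rescaled to `horizon / steps` by the principal fractional power), and
#' allocate. With `steps = 1` this is exactly [allocate()] on the full-horizon
#' demand.
#'
#' @param current the starting `CategoricalRaster`.
#' @param models list of `TransitionSubModel`s (one per origin class with
#'   demanded transitions).
#' @param variables named list of static `ContinuousRaster` drivers.
#' @param dynamic named list `variable name -> class-code set` of
#'   distance-to-class variables recomputed from the evolving map each step.
#' @param tpm the full-horizon `TransitionProbabilityMatrix`.
#' @param steps number of projection steps (>= 1).
#' @param seed allocation tie-break seed.
#' @return list with `map` (final `CategoricalRaster`) and `steps` (per-step
#'   `AllocationResult`s).
#' @export
project <- function(current, models, variables, dynamic = list(), tpm,
                    steps = 1, seed) {
  stopifnot(steps >= 1)
  if (missing(seed)) stop("seed is required")
  P_step <- if (steps == 1) tpm$P else {
    Ps <- matrix_power_frac(tpm$P, 1 / steps)
    Ps[Ps < 0] <- 0
    Ps / rowSums(Ps)
  }
  step_tpm <- new_tpm(P_step, tpm$horizon_years / steps, tpm$legend)
  cell_ha <- cell_area_ha(current)
  logs <- vector("list", steps)
  for (s in seq_len(steps)) {
    vars <- variables
    for (nm in names(dynamic)) {
      vars[[nm]] <- distance_to_class(current, dynamic[[nm]])
    }
    pots <- list()
    for (m in models) pots <- c(pots, predict_potentials(m, vars, current))
    areas <- class_areas(current)
    dem <- change_demand(step_tpm, areas)
    res <- allocate(current, pots, dem, seed = seed + s - 1L)
    logs[[s]] <- res
    current <- res$map
  }
  list(map = current, steps = logs)
}

#' Per-class areas of a categorical raster, in hectares
#' @param map a `CategoricalRaster`.
#' @return named numeric vector (legend names, legend order).
#' @export
class_areas <- function(map) {
  ok <- valid_mask(map)
  n <- tabulate(match(map$values[ok], map$legend$code), nrow(map$legend))
  setNames(n * cell_area_ha(map), map$legend$name)
}
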