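# ---------------------------------------------------------------------------
# Markov-chain change demand: matrix estimation, horizon rescaling,
# declarative scenario editing, demand computation, and matrix CSV I/O.
# ---------------------------------------------------------------------------

new_tpm <- function(P, horizon_years, legend) {
  dimnames(P) <- list(legend$name, legend$name)
  structure(list(P = P, horizon_years = horizon_years, legend = legend),
            class = "TransitionProbabilityMatrix")
}

#' @export
print.TransitionProbabilityMatrix <- function(x, ...) {
  cat(sprintf("TransitionProbabilityMatrix: %d classes, horizon %g years\n",
              nrow(x$P), x$horizon_years))
  print(round(x$P, 3))
  invisible(x)
}

#' Check that a matrix is row-stochastic
#'
#' @param P square numeric matrix (or `TransitionProbabilityMatrix`).
#' @param tol per-row tolerance on `|rowsum - 1|`. The strict default 1e-9
#'   suits computed matrices; published matrices rounded to 3 decimals need
#'   `tol = 0.005` (rounding can displace a row sum by up to 0.5 per mille per
#'   cell).
#' @return `TRUE`/`FALSE`.
#' @export
is_row_stochastic <- function(P, tol = 1e-9) {
  if (inherits(P, "TransitionProbabilityMatrix")) P <- P$P
  all(P >= -tol & P <= 1 + tol) && all(abs(rowSums(P) - 1) <= tol)
}

# principal fractional matrix power via eigendecomposition
matrix_power_frac <- function(P, t) {
  eg <- eigen(P)
  lam <- as.complex(eg$values)
  lt <- ifelse(Mod(lam) == 0, 0 + 0i, exp(t * log(lam)))
  Pt <- eg$vectors %*% diag(lt, nrow = length(lt)) %*% solve(eg$vectors)
  if (max(abs(Im(Pt))) > 1e-8) {
    stop("principal fractional power is not real for this matrix; ",
         "re-run with rescale = \"linear\"")
  }
  Re(Pt)
}

#' Estimate a transition probability matrix from observed change
#'
#' Row-normalizes the observed transition counts (the maximum-likelihood
#' Markov matrix for the observation interval) and rescales it to the
#' projection horizon. The default rescaling takes the principal fractional
#' matrix power `P^(target/base)` (eigendecomposition route), clamping any
#' small negative entries to 0 and renormalizing rows; `rescale = "linear"`
#' instead scales off-diagonal mass by `target/base` and restores the
#' diagonal.
#'
#' @param counts a `TransitionCountMatrix`.
#' @param base_years length of the observation interval (years).
#' @param target_years length of the projection horizon (years).
#' @param rescale `"power"` (default) or `"linear"`.
#' @return a `TransitionProbabilityMatrix` with `horizon_years = target_years`.
#' @export
estimate_matrix <- function(counts, base_years, target_years,
                            rescale = c("power", "linear")) {
  rescale <- match.arg(rescale)
  if (base_years <= 0 || target_years <= 0) stop("horizons must be > 0")
  cm <- counts$counts
  rs <- rowSums(cm)
  if (any(rs == 0)) {
    stop("class(es) absent at t1: ",
         paste(rownames(cm)[rs == 0], collapse = ", "))
  }
  P <- cm / rs
  t_ratio <- target_years / base_years
  if (t_ratio != 1) {
    if (rescale == "power") {
      P <- matrix_power_frac(P, t_ratio)
      P[P < 0] <- 0
      P <- P / rowSums(P)
    } else {
      off <- P
      diag(off) <- 0
      off <- off * t_ratio
      over <- rowSums(off) > 1
      if (any(over)) {
        stop("linear rescaling drives diagonal negative for: ",
             paste(rownames(cm)[over], collapse = ", "))
      }
      diag(off) <- 1 - rowSums(off)
      P <- off
    }
  }
  new_tpm(P, target_years, counts$legend)
}

# resolve a class reference (code, name, or normalized name) to a row index
class_index <- function(legend, ref) {
  norm <- function(s) gsub("[^a-z0-9]+", "_", tolower(trimws(s)))
  if (is.numeric(ref)) {
    i <- match(as.integer(ref), legend$code)
  } else {
    i <- match(norm(ref), norm(legend$name))
  }
  if (is.na(i)) stop("unknown class: ", ref)
  i
}

#' Declarative scenario edits
#'
#' Constructors for the three edit kinds applied by [apply_scenario()]:
#' `fix_row_identity` pins a class to full persistence (no conversion out);
#' `scale_cell` multiplies one off-diagonal transition probability by `factor`;
#' `scale_diagonal` multiplies a class's persistence probability. Scaled cells
#' are rounded half-to-even to 3 decimals (the precision of published
#' matrices) and the increment is compensated from a donor cell in the same
#' row: by default the diagonal for off-diagonal edits, and the row's largest
#' off-diagonal cell for diagonal edits.
#'
#' @param origin,dest class code or name.
#' @param factor multiplier (> 0, finite).
#' @param donor `"diagonal"`, `"largest_offdiagonal"`, or a class code/name.
#' @return a `ScenarioEdit`.
#' @name scenario_edits
NULL

#' @rdname scenario_edits
#' @export
edit_scale_cell <- function(origin, dest, factor, donor = "diagonal") {
  stopifnot(is.finite(factor), factor > 0)
  structure(list(kind = "scale_cell", origin = origin, dest = dest,
                 factor = factor, donor = donor), class = "ScenarioEdit")
}

#' @rdname scenario_edits
#' @export
edit_scale_diagonal <- function(origin, factor,
                                donor = "largest_offdiagonal") {
  stopifnot(is.finite(factor), factor > 0)
  structure(list(kind = "scale_diagonal", origin = origin, factor = factor,
                 donor = donor), class = "ScenarioEdit")
}

#' @rdname scenario_edits
#' @export
edit_fix_row_identity <- function(origin) {
  structure(list(kind = "fix_row_identity", origin = origin),
            class = "ScenarioEdit")
}

#' Apply scenario edits to a transition probability matrix
#'
#' Edits are applied in list order (the order is part of the scenario's
#' identity). An edit whose compensation would drive its donor cell negative
#' is an error, as is a donor equal to the edited cell.
#'
#' @param tpm a `TransitionProbabilityMatrix`, row-stochastic at least to
#'   printed-rounding tolerance (0.005 per row).
#' @param edits list of `ScenarioEdit`s (empty list = business as usual).
#' @return the edited `TransitionProbabilityMatrix`.
#' @export
apply_scenario <- function(tpm, edits) {
  P <- tpm$P
  lg <- tpm$legend
  if (!is_row_stochastic(P, tol = 0.005)) {
    stop("matrix is not row-stochastic even at printed-rounding tolerance")
  }
  scale_into <- function(P, i, j, factor, donor_j) {
    if (donor_j == j) stop("donor must differ from the edited cell")
    new_val <- round(factor * P[i, j], 3)  # round() is half-to-even
    if (new_val > 1) stop("edit drives cell above 1")
    inc <- new_val - P[i, j]
    if (P[i, donor_j] - inc < -1e-12) {
      stop(sprintf("donor underflow editing row '%s'", lg$name[i]))
    }
    P[i, j] <- new_val
    P[i, donor_j] <- max(P[i, donor_j] - inc, 0)
    P
  }
  for (e in edits) {
    stopifnot(inherits(e, "ScenarioEdit"))
    i <- class_index(lg, e$origin)
    P <- switch(e$kind,
      fix_row_identity = {
        P[i, ] <- 0
        P[i, i] <- 1
        P
      },
      scale_cell = {
        j <- class_index(lg, e$dest)
        donor_j <- if (identical(e$donor, "diagonal")) i
                   else class_index(lg, e$donor)
        scale_into(P, i, j, e$factor, donor_j)
      },
      scale_diagonal = {
        donor_j <- if (identical(e$donor, "largest_offdiagonal")) {
          off <- P[i, ]
          off[i] <- -Inf
          which.max(off)
        } else {
          class_index(lg, e$donor)
        }
        scale_into(P, i, i, e$factor, donor_j)
      },
      stop("unknown edit kind: ", e$kind))
  }
  new_tpm(P, tpm$horizon_years, lg)
}

#' Parse a scenario file
#'
#' Plain-text, one edit per line, `#` comments allowed:
#' \preformatted{
#' scale_cell conifer_forest broadleaf_forest 1.5 donor=diagonal
#' scale_diagonal mountain_heath_bog 1.5 donor=largest_offdiagonal
#' fix_row_identity broadleaf_forest
#' }
#' Class references match legend names case-insensitively with any
#' non-alphanumeric runs collapsed to `_`.
#'
#' @param path scenario file; an empty file is the business-as-usual scenario.
#' @return list of `ScenarioEdit`s.
#' @export
read_scenario <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, function(ln) {
    tok <- strsplit(ln, "\\s+")[[1]]
    kv <- grepl("=", tok[-1])
    args <- tok[-1][!kv]
    opts <- tok[-1][kv]
    donor <- sub("^donor=", "", opts[startsWith(opts, "donor=")])
    switch(tok[1],
      scale_cell = edit_scale_cell(args[1], args[2], as.numeric(args[3]),
                                   if (length(donor)) donor else "diagonal"),
      scale_diagonal = edit_scale_diagonal(
        args[1], as.numeric(args[2]),
        if (length(donor)) donor else "largest_offdiagonal"),
      fix_row_identity = edit_fix_row_identity(args[1]),
      stop("unknown scenario edit: ", tok[1]))
  })
}

#' Change demand from a probability matrix and baseline areas
#'
#' `D[i, j] = area_i * P[i, j]`: the area of class i expected to be class j at
#' the end of the horizon. Total area is conserved by construction.
#'
#' @param tpm a `TransitionProbabilityMatrix`.
#' @param baseline_areas non-negative per-class areas (ha), named by class name
#'   or given in legend order.
#' @return a `ChangeDemand`: list with `D` (K x K ha matrix), `legend`,
#'   `horizon_years`.
#' @export
change_demand <- function(tpm, baseline_areas) {
  lg <- tpm$legend
  if (!is.null(names(baseline_areas))) {
    if (!setequal(names(baseline_areas), lg$name)) {
      stop("baseline area names do not match the legend")
    }
    baseline_areas <- baseline_areas[lg$name]
  } else if (length(baseline_areas) != nrow(lg)) {
    stop("baseline areas length does not match the legend")
  }
  if (any(baseline_areas < 0)) stop("baseline areas must be >= 0")
  D <- diag(as.numeric(baseline_areas), nrow = nrow(lg)) %*% tpm$P
  dimnames(D) <- list(lg$name, lg$name)
  structure(list(D = D, legend = lg, horizon_years = tpm$horizon_years),
            class = "ChangeDemand")
}

#' Write / read a legend-labelled matrix CSV
#'
#' @param m matrix with dimnames, or `TransitionProbabilityMatrix`.
#' @param path CSV path (row labels in the first column).
#' @return `read_matrix_csv`: the labelled numeric matrix.
#' @export
write_matrix_csv <- function(m, path) {
  if (inherits(m, "TransitionProbabilityMatrix")) m <- m$P
  if (inherits(m, "TransitionCountMatrix")) m <- m$counts
  write.csv(as.data.frame(m, check.names = FALSE), path)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}
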