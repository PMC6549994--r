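# ---------------------------------------------------------------------------
# Per-origin-class MLP transition sub-models: stratified sampling of
# transitioned/persistent pixels, training with validation, backwards
# stepwise variable selection, and transition-potential prediction.
# ---------------------------------------------------------------------------

# evaluate code with a locally-seeded RNG, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# feature matrix at given cell indices from a named list of ContinuousRasters
feature_matrix <- function(variables, idx) {
  stopifnot(length(variables) > 0)
  X <- vapply(variables, function(v) v$values[idx], numeric(length(idx)))
  if (length(idx) == 1L) X <- matrix(X, nrow = 1)
  colnames(X) <- names(variables)
  X
}

#' Draw a stratified training/validation sample for one origin class
#'
#' Samples up to `n` pixels of the origin class, stratified with equal target
#' counts over the labels (each observed destination class plus persistence),
#' truncated to availability per label. Half of each label's pixels are tagged
#' `train`, half `validate` (sizes differing by at most 1). Pixels with a
#' missing value in any driver are ineligible. Deterministic under `seed`.
#'
#' @param t1,t2 co-registered `CategoricalRaster`s sharing one legend.
#' @param origin class code whose transitions are modelled.
#' @param variables named list of co-registered `ContinuousRaster` drivers.
#' @param n total sample-size target (default 10000).
#' @param seed integer seed (required; sampling must be reproducible).
#' @return a `SampleSet`: list with `X` (feature matrix), `label` (destination
#'   class code per row), `split` (`"train"`/`"validate"`), `idx` (cell index),
#'   `origin`, `seed`.
#' @export
draw_samples <- function(t1, t2, origin, variables, n = 10000, seed) {
  assert_coregistered(t1, t2)
  if (missing(seed)) stop("seed is required")
  for (v in variables) assert_coregistered(t1, v)
  ok <- valid_mask(t1) & valid_mask(t2)
  for (v in variables) ok <- ok & valid_mask(v)
  elig <- which(ok & t1$values == origin)
  if (length(elig) == 0L) stop("origin class ", origin, " absent at t1")
  dest <- t2$values[elig]
  labels <- sort(unique(dest))
  if (length(labels) < 2L) {
    stop("need >= 2 labels (transition + persistence) for origin ", origin)
  }
  per_label <- floor(n / length(labels))
  with_seed(seed, {
    extra_to_train <- TRUE  # alternate odd-label leftovers to keep halves +-1
    rows <- lapply(labels, function(lb) {
      pool <- elig[dest == lb]
      take <- min(per_label, length(pool))
      pick <- if (length(pool) == 1L) pool else sample(pool, take)
      ntr <- length(pick) %/% 2
      if (length(pick) %% 2 == 1L) {
        if (extra_to_train) ntr <- ntr + 1L
        extra_to_train <<- !extra_to_train
      }
      split <- rep("validate", length(pick))
      split[seq_len(ntr)] <- "train"   # pick is already in random order
      data.frame(idx = pick, label = lb, split = split,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    structure(
      list(X = feature_matrix(variables, df$idx), label = df$label,
           split = df$split, idx = df$idx, origin = origin, seed = seed),
      class = "SampleSet")
  })
}

mlp_defaults <- function(n_in, n_out) {
  list(hidden = max(4L, ceiling((n_in + n_out) / 2)),
       lr = 0.01, momentum = 0.5, max_epochs = 10000L, patience = 100L,
       restarts = 3L)
}

#' Train a transition sub-model
#'
#' Fits a single-hidden-layer MLP (sigmoid activations, full-batch gradient
#' descent with momentum) on the training half of a [draw_samples()] set,
#' scoring validation accuracy as the percentage of validation rows whose
#' arg-max output matches their label; the weights of the best validation
#' epoch are kept. Features are min-max scaled to `[0, 1]` using
#' training-half statistics. Accuracy >= 75% is flagged `good`.
#'
#' @param samples a `SampleSet`.
#' @param hyper optional list overriding any of `hidden`, `lr`, `momentum`,
#'   `max_epochs`, `patience`.
#' @param seed weight-initialization seed; defaults to the sample's seed.
#' @return a `TransitionSubModel`: weights, scaling, label set, validation
#'   accuracy (percent) and provenance.
#' @export
train_submodel <- function(samples, hyper = list(), seed = samples$seed) {
  labels <- sort(unique(samples$label))
  if (length(labels) < 2L) stop("degenerate sample: single label")
  tr <- samples$split == "train"
  hp <- utils::modifyList(mlp_defaults(ncol(samples$X), length(labels)), hyper)

  Xtr <- samples$X[tr, , drop = FALSE]
  lo <- apply(Xtr, 2, min)
  hi <- apply(Xtr, 2, max)
  scale_x <- function(X) {
    sweep(sweep(X, 2, lo), 2, pmax(hi - lo, .Machine$double.eps), "/")
  }
  y <- match(samples$label, labels)
  Y <- matrix(0, sum(tr), length(labels))
  Y[cbind(seq_len(sum(tr)), y[tr])] <- 1

  # a few random restarts guard against dead initializations (networks that
  # never leave the majority-class prediction); the best validation fit wins
  fit <- NULL
  for (r in seq_len(max(1L, hp$restarts))) {
    cand <- mlp_train_cpp(scale_x(Xtr), Y,
                          scale_x(samples$X[!tr, , drop = FALSE]),
                          y[!tr] - 1L, hp$hidden, hp$lr, hp$momentum,
                          hp$max_epochs, hp$patience,
                          as.integer(seed) + (r - 1L) * 7919L)
    if (is.null(fit) || cand$val_accuracy > fit$val_accuracy) fit <- cand
  }
  structure(
    list(origin = samples$origin, labels = labels,
         variables = colnames(samples$X),
         W1 = fit$W1, b1 = as.numeric(fit$b1), W2 = fit$W2,
         b2 = as.numeric(fit$b2), scale_lo = lo, scale_hi = hi,
         accuracy = fit$val_accuracy, good = fit$val_accuracy >= 75,
         epochs_run = fit$epochs_run, hyper = hp, seed = seed),
    class = "TransitionSubModel")
}

#' @export
print.TransitionSubModel <- function(x, ...) {
  cat(sprintf(
    "TransitionSubModel origin %d: %d labels, %d vars, accuracy %.1f%%%s\n",
    x$origin, length(x$labels), length(x$variables), x$accuracy,
    if (x$good) " (good)" else ""))
  invisible(x)
}

# forward pass on a raw (unscaled) feature matrix restricted to model variables
submodel_outputs <- function(model, X) {
  X <- X[, model$variables, drop = FALSE]
  Xs <- sweep(sweep(X, 2, model$scale_lo), 2,
              pmax(model$scale_hi - model$scale_lo, .Machine$double.eps), "/")
  O <- mlp_forward_cpp(Xs, model$W1, model$b1, model$W2, model$b2)
  colnames(O) <- as.character(model$labels)
  O
}

#' Backwards stepwise variable selection
#'
#' Repeatedly retrains the sub-model with each remaining variable held out and
#' drops the one whose removal degrades validation accuracy least, as long as
#' that degradation does not exceed `tolerance` accuracy points (a removal may
#' also improve accuracy). Optionally a second pass tests all pairwise
#' hold-outs after single hold-outs converge. Stops when no variable can be
#' dropped or one variable remains.
#'
#' @param samples a `SampleSet` containing the full candidate variable set.
#' @param tolerance maximum acceptable validation-accuracy drop (percentage
#'   points). The default 2 is about two binomial standard errors of the
#'   validation accuracy at the default validation-half sizes, i.e. "no
#'   statistically meaningful degradation".
#' @param pairs also test pairwise hold-outs after convergence (default FALSE).
#' @param hyper,seed passed to [train_submodel()].
#' @return list with `selected` (variable names), `accuracy` (of the final
#'   model), `trace` (data.frame of steps).
#' @export
backwards_stepwise <- function(samples, tolerance = 2, pairs = FALSE,
                               hyper = list(), seed = samples$seed) {
  vars <- colnames(samples$X)
  subsample <- function(keep) {
    s <- samples
    s$X <- s$X[, keep, drop = FALSE]
    s
  }
  acc <- train_submodel(samples, hyper, seed)$accuracy
  trace <- data.frame(dropped = NA_character_, accuracy = acc,
                      stringsAsFactors = FALSE)
  drop_pass <- function(vars, acc, arity) {
    repeat {
      if (length(vars) <= arity) return(list(vars = vars, acc = acc))
      cand <- utils::combn(vars, arity, simplify = FALSE)
      accs <- vapply(cand, function(out) {
        train_submodel(subsample(setdiff(vars, out)), hyper, seed)$accuracy
      }, numeric(1))
      best <- which.max(accs)
      if (acc - accs[best] > tolerance) return(list(vars = vars, acc = acc))
      vars <- setdiff(vars, cand[[best]])
      acc <- accs[best]
      trace <<- rbind(trace, data.frame(
        dropped = paste(cand[[best]], collapse = "+"), accuracy = acc,
        stringsAsFactors = FALSE))
    }
  }
  res <- drop_pass(vars, acc, 1L)
  if (pairs) res <- drop_pass(res$vars, res$acc, 2L)
  list(selected = res$vars, accuracy = res$acc, trace = trace)
}

#' Predict transition-potential rasters from a sub-model
#'
#' Applies the trained network to every valid pixel currently of the model's
#' origin class, yielding one potential surface in `[0, 1]` per transition
#' (origin to each non-persistence label). Pixels not of the origin class get
#' potential 0; pixels missing any driver value are nodata.
#'
#' @param model a `TransitionSubModel`.
#' @param variables named list of `ContinuousRaster` drivers covering the
#'   model's variables.
#' @param current the current `CategoricalRaster` map.
#' @return a `PotentialStack`: named list of `ContinuousRaster`s with names
#'   `"<origin>_<dest>"`, plus attributes `origin`.
#' @export
predict_potentials <- function(model, variables, current) {
  missing_vars <- setdiff(model$variables, names(variables))
  if (length(missing_vars) > 0L) {
    stop("missing variable raster(s): ", paste(missing_vars, collapse = ", "))
  }
  variables <- variables[model$variables]
  for (v in variables) assert_coregistered(current, v)
  ok <- valid_mask(current)
  for (v in variables) ok <- ok & valid_mask(v)
  at_origin <- ok & current$values == model$origin
  idx <- which(at_origin)
  O <- if (length(idx) > 0L) {
    submodel_outputs(model, feature_matrix(variables, idx))
  } else {
    matrix(0, 0, length(model$labels))
  }
  dests <- setdiff(model$labels, model$origin)
  out <- lapply(dests, function(d) {
    m <- matrix(0, nrow(current$values), ncol(current$values))
    m[!ok] <- NA_real_
    if (length(idx) > 0L) m[idx] <- O[, as.character(d)]
    new_continuous_raster(m, xll = current$xll, yll = current$yll,
                          cellsize = current$cellsize,
                          crs_tag = current$crs_tag, units = "potential")
  })
  names(out) <- sprintf("%d_%d", model$origin, dests)
  structure(out, origin = model$origin, class = "PotentialStack")
}
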