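# ---------------------------------------------------------------------------
# Pipeline orchestration and command-line entry point. A single INI-style
# config sequences change analysis -> driver screening -> sub-model training
# -> Markov/scenario matrices -> projection, with every stochastic stage's
# seed required in the config and echoed into the run log.
# ---------------------------------------------------------------------------

#' Parse a flat INI-style config
#'
#' Sections in `[name]` headers, `key = value` pairs, `#` comments. Values
#' stay strings; callers coerce.
#'
#' @param path config file.
#' @return named list of sections, each a named character vector.
#' @export
parse_config <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- list()
  sect <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      sect <- gsub("^\\[|\\]$", "", ln)
      if (is.null(cfg[[sect]])) cfg[[sect]] <- character()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(sect)) stop("key outside any section: ", ln)
      kv <- regmatches(ln, regexpr("=", ln), invert = TRUE)[[1]]
      cfg[[sect]][[trimws(kv[1])]] <- trimws(kv[2])
    } else {
      stop("unparseable config line: ", ln)
    }
  }
  cfg
}

cfg_get <- function(cfg, section, key, default = NULL) {
  v <- cfg[[section]][key]
  if (is.null(v) || is.na(v) || !nzchar(v)) default else unname(v)
}

cfg_need <- function(cfg, section, key) {
  v <- cfg_get(cfg, section, key)
  if (is.null(v)) stop(sprintf("config is missing [%s] %s", section, key))
  v
}

parse_codes <- function(s) as.integer(strsplit(s, "[,;\\s]+")[[1]])

# build one driver raster from its [driver:<name>] section
build_driver <- function(sec, t1, t2, legend) {
  type <- sec[["type"]]
  switch(type,
    continuous = read_raster(sec[["path"]], "continuous",
                             crs_tag = t1$crs_tag),
    distance = distance_to_class(t1, parse_codes(sec[["target"]])),
    evidence = {
      cat_r <- read_raster(sec[["path"]], "categorical", crs_tag = t1$crs_tag)
      from <- if (identical(sec[["from"]], "all")) legend$code
              else parse_codes(sec[["from"]])
      to <- if (identical(sec[["to"]], "all")) legend$code
            else parse_codes(sec[["to"]])
      evidence_likelihood(cat_r, transition_mask(t1, t2, from, to))
    },
    stop("unknown driver type: ", type))
}

#' Run the full projection pipeline from a config file
#'
#' Stages: (1) cross-tabulation, change budget and trend surface for the
#' observed interval; (2) driver construction and Cramer's V screening against
#' the second-date map; (3) per-origin MLP sub-models on the retained drivers;
#' (4) Markov matrix estimation, horizon rescaling and per-scenario edits;
#' (5) per-scenario projection and a change budget for the projected interval.
#' Any stage error aborts with the stage name. All CSV/ASCII outputs land in
#' `out_dir`, together with a run log echoing seeds and settings.
#'
#' @param config path to an INI-style config (see the packaged example in
#'   `system.file("extdata", package = "landmarkov")` or the vignette) or an
#'   already-parsed [parse_config()] list.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the main in-memory results per scenario.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) parse_config(config) else config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("landmarkov run %s", format(Sys.time(), "%Y-%m-%d")))
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # -- inputs ---------------------------------------------------------------
  legend <- stage("inputs", read_legend(cfg_need(cfg, "inputs", "legend")))
  t1 <- stage("inputs", read_raster(cfg_need(cfg, "inputs", "t1"),
                                    "categorical", legend = legend))
  t2 <- stage("inputs", read_raster(cfg_need(cfg, "inputs", "t2"),
                                    "categorical", legend = legend))
  stage("inputs", assert_coregistered(t1, t2))

  # -- change analysis ------------------------------------------------------
  counts <- stage("change", cross_tabulate(t1, t2))
  budget <- change_budget(counts)
  write_matrix_csv(counts, file.path(out_dir, "transition_counts.csv"))
  write.csv(budget$by_class, file.path(out_dir, "change_budget_t1_t2.csv"),
            row.names = FALSE)
  min_cells <- as.integer(cfg_get(cfg, "change", "min_transition_cells", "0"))
  off <- counts$counts
  diag(off) <- 0L
  dropped_tr <- which(off > 0 & off < min_cells, arr.ind = TRUE)
  if (nrow(dropped_tr) > 0) {
    note("dropped %d transitions under min_transition_cells=%d",
         nrow(dropped_tr), min_cells)
  }
  trend_order <- as.integer(cfg_get(cfg, "change", "trend_order", "3"))
  mask_to <- cfg_get(cfg, "change", "mask_to")
  if (!is.null(mask_to)) {
    from <- cfg_get(cfg, "change", "mask_from", "all")
    from <- if (identical(from, "all")) legend$code else parse_codes(from)
    to <- if (identical(mask_to, "all")) legend$code else parse_codes(mask_to)
    mask <- stage("change", transition_mask(t1, t2, from, to))
    write_raster(mask, file.path(out_dir, "change_mask.asc"))
    ts <- stage("change", trend_surface(mask, trend_order))
    write_raster(ts, file.path(out_dir, "trend_surface.asc"))
    note("trend surface order %d", trend_order)
  }

  # -- drivers + screening --------------------------------------------------
  drv_secs <- grep("^driver:", names(cfg), value = TRUE)
  drivers <- list()
  dynamic <- list()
  for (s in drv_secs) {
    nm <- sub("^driver:", "", s)
    drivers[[nm]] <- stage("drivers", build_driver(cfg[[s]], t1, t2, legend))
    if (identical(cfg_get(cfg, s, "dynamic", "false"), "true")) {
      if (!identical(cfg[[s]][["type"]], "distance")) {
        stop("stage 'drivers' failed: only distance variables can be dynamic")
      }
      dynamic[[nm]] <- parse_codes(cfg[[s]][["target"]])
    }
  }
  screening <- NULL
  if (length(drivers) > 0) {
    n_bins <- as.integer(cfg_get(cfg, "screening", "n_bins", "256"))
    vtab <- data.frame(
      name = names(drivers),
      cramers_v = vapply(drivers, function(d) {
        stage("screening", cramers_v(d, t2, n_bins = n_bins))
      }, numeric(1)),
      dynamic = names(drivers) %in% names(dynamic),
      stringsAsFactors = FALSE, row.names = NULL)
    thr <- as.numeric(cfg_get(cfg, "screening", "threshold", "0.15"))
    screening <- screen_variables(vtab, thr)
    vtab$retained <- vtab$cramers_v > thr
    write.csv(vtab, file.path(out_dir, "screening.csv"), row.names = FALSE)
    note("screening threshold %g: %d retained / %d dropped", thr,
         nrow(screening$retained), nrow(screening$dropped))
  }

  # -- transition sub-models ------------------------------------------------
  models <- list()
  acc_tab <- NULL
  if (!is.null(screening) && nrow(screening$retained) > 0) {
    retained <- drivers[screening$retained$name]
    dynamic <- dynamic[intersect(names(dynamic), names(retained))]
    n_samp <- as.integer(cfg_get(cfg, "sampling", "n", "10000"))
    seed <- as.integer(cfg_need(cfg, "sampling", "seed"))
    note("sampling n=%d seed=%d", n_samp, seed)
    origins <- cfg_get(cfg, "sampling", "origins")
    origins <- if (is.null(origins)) {
      legend$code[rowSums(off >= max(min_cells, 1L)) > 0]
    } else parse_codes(origins)
    for (oc in origins) {
      smp <- stage("train", draw_samples(t1, t2, oc, retained, n = n_samp,
                                         seed = seed + oc))
      models[[as.character(oc)]] <- stage("train", train_submodel(smp))
    }
    acc_tab <- data.frame(
      origin = vapply(models, function(m) m$origin, 0L),
      accuracy = vapply(models, function(m) m$accuracy, 0),
      good = vapply(models, function(m) m$good, TRUE),
      row.names = NULL)
    write.csv(acc_tab, file.path(out_dir, "submodel_accuracy.csv"),
              row.names = FALSE)
  }

  # -- markov + scenarios ---------------------------------------------------
  base_years <- as.numeric(cfg_need(cfg, "markov", "base_years"))
  target_years <- as.numeric(cfg_need(cfg, "markov", "target_years"))
  rescale <- cfg_get(cfg, "markov", "rescale", "power")
  P <- stage("markov", estimate_matrix(counts, base_years, target_years,
                                       rescale = rescale))
  write_matrix_csv(P, file.path(out_dir, "P_baseline.csv"))
  note("markov base=%g target=%g rescale=%s", base_years, target_years,
       rescale)

  scen_secs <- grep("^scenario:", names(cfg), value = TRUE)
  if (length(scen_secs) == 0) scen_secs <- character()
  results <- list()
  for (s in scen_secs) {
    nm <- sub("^scenario:", "", s)
    scn_file <- cfg_get(cfg, s, "file")
    edits <- if (is.null(scn_file)) list()
             else stage("markov", read_scenario(scn_file))
    P_s <- stage("markov", apply_scenario(P, edits))
    write_matrix_csv(P_s, file.path(out_dir, sprintf("P_%s.csv", nm)))
    res <- list(P = P_s)
    if (length(models) > 0) {
      steps <- as.integer(cfg_get(cfg, "allocation", "steps", "1"))
      aseed <- as.integer(cfg_need(cfg, "allocation", "seed"))
      proj <- stage("project",
                    project(t2, models, drivers[screening$retained$name],
                            dynamic, P_s, steps = steps, seed = aseed))
      write_raster(proj$map, file.path(out_dir,
                                       sprintf("projected_%s.asc", nm)))
      last <- proj$steps[[length(proj$steps)]]
      write_matrix_csv(Reduce(`+`, lapply(proj$steps, `[[`, "realized")),
                       file.path(out_dir, sprintf("realized_%s.csv", nm)))
      write_matrix_csv(Reduce(`+`, lapply(proj$steps, `[[`, "unmet")),
                       file.path(out_dir, sprintf("unmet_%s.csv", nm)))
      bud2 <- change_budget(cross_tabulate(t2, proj$map))
      write.csv(bud2$by_class,
                file.path(out_dir, sprintf("change_budget_%s.csv", nm)),
                row.names = FALSE)
      note("scenario %s: %d edits, steps=%d seed=%d, %d px changed, %d unmet",
           nm, length(edits), steps, aseed, sum(last$realized),
           sum(last$unmet))
      res$projection <- proj
    }
    results[[nm]] <- res
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(counts = counts, budget = budget, screening = screening,
                 models = models, accuracy = acc_tab, P = P,
                 scenarios = results, log = log_lines))
}

#' Command-line entry point
#'
#' Subcommands mirror the pipeline stages: `run --config FILE --out DIR`,
#' `change --t1 A --t2 B --legend L --out DIR`,
#' `markov --counts C --base-years X --target-years Y [--scenario S] --out F`,
#' `simulate --seed N --out DIR`. Installed as an Rscript at
#' `system.file("cli", "landmarkov.R", package = "landmarkov")`.
#'
#' @param args character vector of command-line arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return exit status, invisibly: 0 success, 2 validation error,
#'   3 stage failure.
#' @export
landmarkov_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  need <- function(flag) {
    v <- opt(flag)
    if (is.null(v)) stop("missing required option ", flag, call. = FALSE)
    v
  }
  run <- function(expr) {
    tryCatch({ force(expr); invisible(0L) },
      error = function(e) {
        message("error: ", conditionMessage(e))
        invisible(if (grepl("stage '", conditionMessage(e))) 3L else 2L)
      })
  }
  if (length(args) == 0) {
    message("usage: landmarkov <run|change|markov|simulate> [options]")
    return(invisible(2L))
  }
  cmd <- args[1]
  args <- args[-1]
  switch(cmd,
    run = run(run_pipeline(need("--config"), need("--out"))),
    change = run({
      legend <- read_legend(need("--legend"))
      t1 <- read_raster(need("--t1"), "categorical", legend = legend)
      t2 <- read_raster(need("--t2"), "categorical", legend = legend)
      out <- need("--out")
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      counts <- cross_tabulate(t1, t2)
      write_matrix_csv(counts, file.path(out, "transition_counts.csv"))
      write.csv(change_budget(counts)$by_class,
                file.path(out, "change_budget.csv"), row.names = FALSE)
    }),
    markov = run({
      cm <- read_matrix_csv(need("--counts"))
      lg <- new_legend(seq_len(nrow(cm)), rownames(cm))
      counts <- structure(list(counts = cm, legend = lg, n_valid = sum(cm),
                               cell_area = 0.0625),
                          class = "TransitionCountMatrix")
      P <- estimate_matrix(counts, as.numeric(need("--base-years")),
                           as.numeric(need("--target-years")))
      scn <- opt("--scenario")
      if (!is.null(scn)) P <- apply_scenario(P, read_scenario(scn))
      write_matrix_csv(P, need("--out"))
    }),
    simulate = run({
      spec <- synthetic_scenario(seed = as.integer(need("--seed")))
      out <- need("--out")
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      g <- generate_t1(spec)
      write_raster(g$map, file.path(out, "t1.asc"))
      write_raster(evolve(g, spec), file.path(out, "t2.asc"))
      for (nm in names(g$drivers)) {
        write_raster(g$drivers[[nm]], file.path(out, paste0(nm, ".asc")))
      }
      write.csv(spec$legend, file.path(out, "legend.csv"), row.names = FALSE)
    }),
    {
      message("unknown subcommand: ", cmd)
      invisible(2L)
    })
}
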