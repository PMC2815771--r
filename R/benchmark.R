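#' Simulation configuration dispatcher
#'
#' Builds one benchmark dataset from a flat configuration list, the same
#' layout used in grid/YAML configs: `space` plus the per-space parameters of
#' [simulate_coregulation_space()], [simulate_combined_space()] and
#' [simulate_orthologous_space()]. The motif model is either passed in
#' (`wm`) or generated from `width`/`target_ic`/`wm_seed`. Trees are given as
#' a `newick` string (with `branch_mode`) or as star-topology `proximities`.
#'
#' @param sim Named list; recognised fields: `space`, `n_genes`, `width`,
#'   `target_ic`, `ic_tolerance`, `wm_seed`, `bg_length`, `ref_proximity`,
#'   `proximities`, `newick`, `branch_mode`, `dropout_k`, `lost_species`,
#'   `lost_genes`, `background`.
#' @param seed Dataset seed.
#' @param wm Optional [weight_matrix()] overriding the generated one.
#' @param dataset_id Optional identifier.
#' @return A [benchmark_dataset()].
#' @export
simulate_from_config <- function(sim, seed, wm = NULL, dataset_id = NULL) {
  space <- match.arg(sim$space %||% "coregulation",
                     c("coregulation", "combined", "orthologous"))
  bg <- sim$background %||% rep(0.25, 4)
  if (is.null(wm))
    wm <- generate_wm(sim$width %||% 13L, sim$target_ic %||% 20,
                      tolerance = sim$ic_tolerance %||% 0.1,
                      seed = sim$wm_seed %||% seed)
  tree <- NULL
  if (space != "coregulation") {
    if (!is.null(sim$newick))
      tree <- parse_newick(sim$newick, sim$branch_mode %||% "proximity")
    else if (!is.null(sim$proximities))
      tree <- star_tree(unlist(sim$proximities))
    else stop("combined/orthologous configs need 'newick' or 'proximities'")
  }
  loss <- loss_spec(unlist(sim$lost_species) %||% character(),
                    unlist(sim$lost_genes) %||% integer())
  switch(space,
    coregulation = simulate_coregulation_space(
      n_genes = sim$n_genes %||% 10L, wm = wm,
      ref_proximity = sim$ref_proximity %||% 0.80,
      bg_length = sim$bg_length %||% 500L,
      dropout_k = sim$dropout_k %||% 0L, seed = seed, background = bg,
      dataset_id = dataset_id),
    combined = simulate_combined_space(
      n_genes = sim$n_genes %||% 10L, wm = wm, tree = tree, loss = loss,
      bg_length = sim$bg_length %||% 500L, seed = seed, background = bg,
      dataset_id = dataset_id),
    orthologous = simulate_orthologous_space(
      wm = wm, tree = tree, bg_length = sim$bg_length %||% 500L,
      seed = seed, loss = loss, background = bg, dataset_id = dataset_id))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Benchmark test grid
#'
#' A named collection of test configurations, each binding a simulation
#' config, a finder config and a replicate count. The synthetic benchmarks
#' use 100 independently seeded datasets per test; desk-scale runs override
#' `replicates`.
#'
#' @param ... `test_config()` entries (or one list of them).
#' @param baseline Name of the test whose F-value is the baseline for the
#'   cross-test comparison (typically the coregulation-space test), or `NULL`.
#' @return An object of class `test_grid`.
#' @export
test_grid <- function(..., baseline = NULL) {
  tests <- list(...)
  if (length(tests) == 1L && is.null(tests[[1L]]$name)) tests <- tests[[1L]]
  names(tests) <- vapply(tests, `[[`, character(1), "name")
  if (anyDuplicated(names(tests))) stop("test names must be unique")
  if (!is.null(baseline) && !baseline %in% names(tests))
    stop("baseline test not in grid: ", baseline)
  structure(list(tests = tests, baseline = baseline), class = "test_grid")
}

#' @rdname test_grid
#' @param name Unique test name.
#' @param sim Simulation config list (see [simulate_from_config()]).
#' @param finder A [finder_config()] (or a plain list of its arguments).
#' @param replicates Number of simulated datasets (>= 1; 100 in the full
#'   benchmark).
#' @export
test_config <- function(name, sim, finder = finder_config(),
                        replicates = 100L) {
  if (replicates < 1L) stop("replicates must be >= 1")
  if (!inherits(finder, "finder_config"))
    finder <- do.call(finder_config, finder)
  list(name = name, sim = sim, finder = finder,
       replicates = as.integer(replicates))
}

.test_seed <- function(master_seed, index) {
  (as.integer(master_seed) + 10007L * as.integer(index)) %% 2000000000L
}

#' Run a benchmark grid
#'
#' For every test: generate `replicates` datasets (per-test seeds derive from
#' the master seed via the test's position, so appending tests never perturbs
#' earlier ones; a common motif model is generated once per test and shared
#' by its replicates), run the finder on each dataset, evaluate against the
#' ground truth and summarize. Artifacts written under `out_dir`: one dataset
#' directory per replicate, a predictions TSV and single-test report per
#' test, a cross-test `summary.tsv` and — when the grid designates a
#' baseline — `comparison.tsv` with each test's F-value difference against
#' it. A failing test is recorded and skipped without aborting the grid.
#' Everything is reproducible (byte-identical artifacts) from
#' (grid, master_seed).
#'
#' @param grid A [test_grid()].
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing artifacts.
#' @param master_seed Integer master seed.
#' @param threshold Model-comparison threshold for [recovery()].
#' @return Named list of `test_summary` objects (failed tests carry a
#'   `condition` instead).
#' @export
run_grid <- function(grid, out_dir = NULL, master_seed = 1L,
                     threshold = MOTIF_MATCH_THRESHOLD) {
  stopifnot(inherits(grid, "test_grid"))
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summaries <- list()
  for (idx in seq_along(grid$tests)) {
    test <- grid$tests[[idx]]
    test_seed <- .test_seed(master_seed, idx)
    summaries[[test$name]] <- tryCatch({
      wm <- generate_wm(test$sim$width %||% 13L,
                        test$sim$target_ic %||% 20,
                        tolerance = test$sim$ic_tolerance %||% 0.1,
                        seed = test$sim$wm_seed %||% test_seed)
      datasets <- list()
      runs <- list()
      for (rep in seq_len(test$replicates)) {
        ds_id <- sprintf("%s_rep%03d", test$name, rep)
        ds <- simulate_from_config(test$sim, seed = test_seed + rep, wm = wm,
                                   dataset_id = ds_id)
        datasets[[ds_id]] <- ds
        if (!is.null(out_dir))
          write_dataset(ds, file.path(out_dir, test$name, ds_id))
        fc <- test$finder
        fc$seed <- test_seed + rep
        runs[[rep]] <- gibbs_find(ds, fc)
      }
      if (!is.null(out_dir)) {
        write_predictions(runs,
                          file.path(out_dir, test$name, "predictions.tsv"))
      }
      s <- summarize_test(runs, datasets, threshold, mode = "per-dataset")
      if (!is.null(out_dir))
        write_report(stats::setNames(list(s), test$name),
                     file.path(out_dir, test$name, "report.tsv"))
      s
    }, error = function(e) {
      warning("test '", test$name, "' failed: ", conditionMessage(e),
              call. = FALSE)
      structure(list(message = conditionMessage(e)), class = "test_failure")
    })
  }
  ok <- !vapply(summaries, inherits, logical(1), "test_failure")
  if (!is.null(out_dir)) {
    write_report(summaries[ok], file.path(out_dir, "summary.tsv"))
    if (!is.null(grid$baseline) && ok[[grid$baseline]]) {
      base <- summaries[[grid$baseline]]
      comp <- do.call(rbind, lapply(names(summaries)[ok], function(nm) {
        data.frame(test = nm, baseline = grid$baseline,
                   f_value = .fmt_num(summaries[[nm]]$f_value),
                   baseline_f = .fmt_num(base$f_value),
                   f_difference = .fmt_num(f_difference(summaries[[nm]], base)),
                   stringsAsFactors = FALSE)
      }))
      utils::write.table(comp, file.path(out_dir, "comparison.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  summaries
}

#' Read a grid configuration file
#'
#' YAML (or JSON) layout: a top-level `baseline` (optional) and a `tests`
#' list whose entries have `name`, `sim`, optional `finder` arguments and
#' `replicates`.
#'
#' @param path Config file path (`.yaml`/`.yml`/`.json`).
#' @return A [test_grid()].
#' @export
read_grid_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  tests <- lapply(cfg$tests, function(t)
    test_config(t$name, t$sim,
                finder = t$finder %||% finder_config(),
                replicates = t$replicates %||% 100L))
  test_grid(tests, baseline = cfg$baseline)
}
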