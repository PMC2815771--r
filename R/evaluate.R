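#' Match predicted sites against ground truth
#'
#' A predicted site is a *true positive* when, on the same (species, gene)
#' promoter, it covers at least half the length of an embedded ground-truth
#' site. Each predicted site is assigned to at most one truth site — the one
#' it overlaps most, ties broken by the leftmost truth start — and validates
#' as TP only if that overlap reaches half the truth site's length
#' (real-valued comparison, so a 13 bp site needs >= 6.5 bp covered). A truth
#' site is a *false negative* when no predicted site half-covers it; false
#' positives are the remaining predictions. Strand is ignored: a finder may
#' report either strand of the same window.
#'
#' @param predicted Data frame of predicted sites with columns `species`,
#'   `gene`, `start`, `end` (0-based half-open). May have zero rows.
#' @param truth Ground-truth data frame with the same coordinate columns
#'   (e.g. the `sites` element of a [benchmark_dataset()]).
#' @return List with data frames `tp`, `fp` (rows of `predicted`) and `fn`
#'   (rows of `truth`).
#' @export
match_sites <- function(predicted, truth) {
  predicted <- as.data.frame(predicted)
  truth <- as.data.frame(truth)
  np <- nrow(predicted)
  nt <- nrow(truth)
  is_tp <- logical(np)
  covered <- logical(nt)
  if (np && nt) {
    pkey <- paste(predicted$species, predicted$gene)
    tkey <- paste(truth$species, truth$gene)
    for (i in seq_len(np)) {
      js <- which(tkey == pkey[[i]])
      if (!length(js)) next
      ov <- pmax(0, pmin(predicted$end[[i]], truth$end[js]) -
                      pmax(predicted$start[[i]], truth$start[js]))
      half <- (truth$end[js] - truth$start[js]) / 2
      covered[js[ov >= half]] <- TRUE
      # assignment: the single maximal-overlap truth, leftmost start on ties
      ord <- order(-ov, truth$start[js])
      best <- js[ord[[1L]]]
      is_tp[[i]] <- ov[ord[[1L]]] >= (truth$end[[best]] - truth$start[[best]]) / 2
    }
  }
  list(tp = predicted[is_tp, , drop = FALSE],
       fp = predicted[!is_tp, , drop = FALSE],
       fn = truth[!covered, , drop = FALSE])
}

.pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den

#' Quality measures of a prediction
#'
#' Positive predictive value `PPV = 100 * TP / (TP + FP)`, sensitivity
#' `Sens = 100 * TP / (TP + FN)`, and their species-dependent variants
#' `spPPV` / `spSens` computed after restricting both predictions and truth
#' to the reference species (the species in which site annotations can be
#' judged). Measures with a zero denominator are reported as `NA` (undefined)
#' and excluded from downstream means.
#'
#' @param predicted,truth As in [match_sites()].
#' @param reference_species Label of the reference species (default `"REF"`).
#' @return Named list with `ppv`, `sens`, `sp_ppv`, `sp_sens` (percents or
#'   `NA`) plus the underlying counts `tp`, `fp`, `fn`, `sp_tp`, `sp_fp`,
#'   `sp_fn`.
#' @export
quality_measures <- function(predicted, truth, reference_species = "REF") {
  m <- match_sites(predicted, truth)
  sp_pred <- predicted[predicted$species == reference_species, , drop = FALSE]
  sp_truth <- truth[truth$species == reference_species, , drop = FALSE]
  sm <- match_sites(sp_pred, sp_truth)
  list(ppv = .pct(nrow(m$tp), nrow(m$tp) + nrow(m$fp)),
       sens = .pct(nrow(m$tp), nrow(m$tp) + nrow(m$fn)),
       sp_ppv = .pct(nrow(sm$tp), nrow(sm$tp) + nrow(sm$fp)),
       sp_sens = .pct(nrow(sm$tp), nrow(sm$tp) + nrow(sm$fn)),
       tp = nrow(m$tp), fp = nrow(m$fp), fn = nrow(m$fn),
       sp_tp = nrow(sm$tp), sp_fp = nrow(sm$fp), sp_fn = nrow(sm$fn))
}

#' Prediction run container
#'
#' One finder invocation on one dataset: the predicted sites, optionally the
#' predicted motif model, and whether the finder returned an output at all
#' (finders with internal significance filters may return nothing).
#'
#' @param dataset_id,finder_id Identifiers.
#' @param sites Data frame of predicted sites (`species`, `gene`, `start`,
#'   `end`, optionally `sequence`, `score`); must be empty when
#'   `has_output = FALSE`.
#' @param model Optional predicted [weight_matrix()]; when absent it is built
#'   from the predicted site sequences on demand.
#' @param has_output Did the finder return an output?
#' @return An object of class `prediction_run`.
#' @export
prediction_run <- function(dataset_id, finder_id, sites = NULL, model = NULL,
                           has_output = !is.null(sites) && nrow(sites) > 0L) {
  if (is.null(sites))
    sites <- data.frame(species = character(), gene = integer(),
                        start = integer(), end = integer(),
                        sequence = character(), score = numeric(),
                        stringsAsFactors = FALSE)
  if (!has_output && nrow(sites))
    stop("a run without output cannot carry predicted sites")
  structure(list(dataset_id = dataset_id, finder_id = finder_id,
                 has_output = isTRUE(has_output), sites = sites,
                 model = model),
            class = "prediction_run")
}

.run_model <- function(run, pseudocount = 0.25) {
  if (!is.null(run$model)) return(run$model)
  if (!is.null(run$sites$sequence) && nrow(run$sites) &&
      all(nzchar(run$sites$sequence)))
    return(build_wm_from_sites(run$sites$sequence, pseudocount,
                               label = paste0(run$finder_id, "_pred")))
  stop("prediction run carries neither a model nor site sequences")
}

#' Recovery of the correct motif model
#'
#' A run's output is *correct* (recovery 1) when its predicted motif model
#' matches the dataset's correct model (the weight matrix built from the
#' embedded sites) under [compare_motifs()]. Predicted models that fail the
#' comparison are rescued when the species-dependent quality of the predicted
#' sites is high: recovery is still 1 if both spPPV and spSens are above 50%,
#' or if either one is higher than 80% (strict inequalities).
#'
#' @param run A [prediction_run()] with `has_output = TRUE`.
#' @param correct_model The dataset's correct [weight_matrix()].
#' @param dataset The [benchmark_dataset()] the run was made on.
#' @param threshold Model-comparison threshold (see [compare_motifs()]).
#' @param reference_species Reference species for the rescue rule.
#' @return 0 or 1.
#' @export
recovery <- function(run, correct_model, dataset,
                     threshold = MOTIF_MATCH_THRESHOLD,
                     reference_species = "REF") {
  if (!run$has_output)
    stop("recovery is only defined for runs with an output")
  cmp <- compare_motifs(.run_model(run), correct_model, threshold)
  if (cmp$is_match) return(1L)
  q <- quality_measures(run$sites, dataset$sites, reference_species)
  sp_ppv <- q$sp_ppv
  sp_sens <- q$sp_sens
  rescue <- (!is.na(sp_ppv) && !is.na(sp_sens) && sp_ppv > 50 && sp_sens > 50) ||
    (!is.na(sp_ppv) && sp_ppv > 80) || (!is.na(sp_sens) && sp_sens > 80)
  as.integer(rescue)
}

#' F-value: harmonic mean of spPPV and spSens
#'
#' `F = 2ab / (a + b)` on the percent scale, defined as 0 when both inputs
#' are 0 and `NA` when either is undefined. `f_difference()` is the combined-
#' minus-coregulation contrast used to judge whether adding orthologs helped.
#'
#' @param sp_ppv,sp_sens Percents in \[0, 100\] (or `NA`).
#' @return Percent in \[0, 100\] (or `NA`).
#' @examples
#' f_value(50, 100)  # 66.67
#' @export
f_value <- function(sp_ppv, sp_sens) {
  if (is.na(sp_ppv) || is.na(sp_sens)) return(NA_real_)
  if (sp_ppv + sp_sens == 0) return(0)
  2 * sp_ppv * sp_sens / (sp_ppv + sp_sens)
}

#' @rdname f_value
#' @param summary_a,summary_b `test_summary` objects (see [summarize_test()]);
#'   conventionally the combined-space and coregulation-space summaries.
#' @export
f_difference <- function(summary_a, summary_b) {
  summary_a$f_value - summary_b$f_value
}

#' Summarize a test over its replicate runs
#'
#' Aggregates one test configuration: `d1_or_r1` counts the runs that
#' returned any output (D1 over independent datasets, R1 over repeated runs
#' on one dataset, chosen by `mode`); the recovery rate `RR` is the percent
#' of those outputs whose motif model was correct; the quality measures
#' (PPV, Sens, spPPV, spSens) are averaged *only over the correct outputs*,
#' skipping undefined values; and the F-value is the harmonic mean of the
#' mean spPPV and mean spSens.
#'
#' @param runs List of [prediction_run()] objects.
#' @param datasets Named list of [benchmark_dataset()] objects keyed by
#'   `dataset_id` (a single dataset may be shared by all runs in
#'   `"per-run"` mode).
#' @param threshold Model-comparison threshold.
#' @param mode `"per-dataset"` (synthetic benchmarks: one run per dataset,
#'   D1) or `"per-run"` (repeated runs on a fixed dataset, R1).
#' @param reference_species Reference species label.
#' @return An object of class `test_summary`: list with `n_runs`,
#'   `d1_or_r1`, `rr`, `ppv`, `sens`, `sp_ppv`, `sp_sens`, `f_value`, `mode`.
#' @export
summarize_test <- function(runs, datasets,
                           threshold = MOTIF_MATCH_THRESHOLD,
                           mode = c("per-dataset", "per-run"),
                           reference_species = "REF") {
  mode <- match.arg(mode)
  if (!length(runs)) stop("at least one run is required")
  if (inherits(datasets, "benchmark_dataset"))
    datasets <- stats::setNames(list(datasets), datasets$dataset_id)
  per <- lapply(runs, function(run) {
    ds <- datasets[[run$dataset_id]]
    if (is.null(ds)) stop("no dataset for run on '", run$dataset_id, "'")
    if (!run$has_output)
      return(list(output = FALSE, correct = FALSE))
    corr <- recovery(run, correct_motif_model(ds), ds, threshold,
                     reference_species) == 1L
    q <- quality_measures(run$sites, ds$sites, reference_species)
    list(output = TRUE, correct = corr, q = q)
  })
  d1 <- sum(vapply(per, `[[`, logical(1), "output"))
  correct <- vapply(per, `[[`, logical(1), "correct")
  rr <- .pct(sum(correct), d1)
  mean_q <- function(field) {
    vals <- vapply(per[correct], function(p) p$q[[field]], numeric(1))
    vals <- vals[!is.na(vals)]
    if (!length(vals)) NA_real_ else mean(vals)
  }
  sp_ppv <- mean_q("sp_ppv")
  sp_sens <- mean_q("sp_sens")
  structure(list(n_runs = length(runs), d1_or_r1 = d1, rr = rr,
                 n_correct = sum(correct),
                 ppv = mean_q("ppv"), sens = mean_q("sens"),
                 sp_ppv = sp_ppv, sp_sens = sp_sens,
                 f_value = f_value(sp_ppv, sp_sens), mode = mode),
            class = "test_summary")
}

#' @export
print.test_summary <- function(x, ...) {
  lbl <- if (x$mode == "per-dataset") "D1" else "R1"
  cat(sprintf("test_summary: %s = %d/%d, RR = %s\n", lbl, x$d1_or_r1,
              x$n_runs, .fmt_pct(x$rr)))
  cat(sprintf("  mean over correct outputs: PPV %s, Sens %s, spPPV %s, spSens %s, F %s\n",
              .fmt_pct(x$ppv), .fmt_pct(x$sens), .fmt_pct(x$sp_ppv),
              .fmt_pct(x$sp_sens), .fmt_pct(x$f_value)))
  invisible(x)
}

.fmt_pct <- function(x) if (is.na(x)) "undef" else sprintf("%.1f%%", x)
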