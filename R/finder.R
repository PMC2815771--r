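#' Configuration of the built-in Gibbs motif finder
#'
#' @param width Motif width in bp (>= 4).
#' @param mode `"oops"` (exactly one site per sequence) or `"zoops"` (zero or
#'   one site per sequence).
#' @param iterations Gibbs sweeps per restart (>= 1).
#' @param restarts Independent restarts; the best by log-likelihood ratio is
#'   returned.
#' @param seed Integer seed; the finder is deterministic given
#'   (input, config).
#' @param significance_threshold Optional minimum mean per-site log2
#'   likelihood ratio (bits per site); below it the run reports no output.
#'   [GIBBS_SIGNIFICANCE_THRESHOLD] is a null-calibrated default cut-off.
#' @param pseudocount Pseudocount for the motif and background models.
#' @param site_prior Prior probability that a sequence carries a site
#'   (`"zoops"` mode only).
#' @return An object of class `finder_config`.
#' @export
finder_config <- function(width = 13L, mode = c("oops", "zoops"),
                          iterations = 150L, restarts = 3L, seed = 1L,
                          significance_threshold = NULL, pseudocount = 0.25,
                          site_prior = 0.8) {
  mode <- match.arg(mode)
  if (width < 4L) stop("width must be >= 4")
  if (iterations < 1L) stop("iterations must be >= 1")
  if (restarts < 1L) stop("restarts must be >= 1")
  structure(list(width = as.integer(width), mode = mode,
                 iterations = as.integer(iterations),
                 restarts = as.integer(restarts), seed = as.integer(seed),
                 significance_threshold = significance_threshold,
                 pseudocount = pseudocount, site_prior = site_prior),
            class = "finder_config")
}

#' Baseline Gibbs site-sampling motif finder
#'
#' A collapsed Gibbs sampler over site start positions with a
#' product-multinomial motif model and a 0th-order background model estimated
#' from the input (pseudocount 0.25 each): in every sweep one sequence's site
#' position is resampled from its predictive distribution given the sites
#' currently assigned in the other sequences; in `"zoops"` mode a no-site
#' state competes under the `site_prior`. Each restart ends with two greedy
#' (argmax) sweeps, and the restart with the highest total log2
#' likelihood-ratio wins. All sequences — including orthologs — are treated
#' independently; the finder has no evolutionary model. It exists so the
#' simulate/find/evaluate loop runs end-to-end offline; external finders'
#' predictions can replace it through the predictions TSV.
#'
#' @param records A [benchmark_dataset()] or its `records` data frame
#'   (`species`, `gene`, `sequence`).
#' @param cfg A [finder_config()].
#' @param dataset_id Identifier for the run (defaulted from the dataset).
#' @param finder_id Finder label (default `"gibbs"`).
#' @return A [prediction_run()]; `sites$score` holds each site's log2
#'   likelihood ratio and the run's `model` the weight matrix built from the
#'   predicted sites. When `significance_threshold` is set and the mean
#'   per-site score falls below it, the run has `has_output = FALSE`.
#' @export
gibbs_find <- function(records, cfg = finder_config(), dataset_id = NULL,
                       finder_id = "gibbs") {
  if (inherits(records, "benchmark_dataset")) {
    if (is.null(dataset_id)) dataset_id <- records$dataset_id
    records <- records$records
  }
  if (is.null(dataset_id)) dataset_id <- "dataset"
  w <- cfg$width
  pc <- cfg$pseudocount
  n <- nrow(records)
  if (n < 1L) stop("at least one sequence is required")
  seqs <- lapply(records$sequence, .encode_seq)
  if (any(lengths(seqs) < w))
    stop("all sequences must be at least as long as the motif width")
  npos <- lengths(seqs) - w + 1L

  # flat lookup index: row p of F[[i]] addresses the log-odds entries of the
  # window starting at p, so window scores are one vector-index + rowSums
  offsets <- matrix(4L * (seq_len(w) - 1L), nrow = 1L)
  Fidx <- lapply(seq_len(n), function(i) {
    M <- vapply(seq_len(w), function(j) seqs[[i]][seq_len(npos[i]) + j - 1L],
                integer(npos[i]))
    matrix(M, nrow = npos[i]) + offsets[rep(1L, npos[i]), , drop = FALSE]
  })

  base_counts <- tabulate(unlist(seqs), nbins = 4L)
  bg <- (base_counts + pc) / (sum(base_counts) + 4 * pc)
  log_bg <- log2(bg)

  site_counts <- function(z) {
    counts <- matrix(0, 4L, w)
    for (i in which(z > 0L)) {
      win <- seqs[[i]][z[i] + seq_len(w) - 1L]
      counts[cbind(win, seq_len(w))] <- counts[cbind(win, seq_len(w))] + 1
    }
    counts
  }
  log_odds <- function(counts, m) {
    theta <- (counts + pc) / (m + 4 * pc)
    log2(theta) - matrix(log_bg, 4L, w)
  }
  window_scores <- function(i, lo) {
    v <- lo[Fidx[[i]]]
    if (npos[i] == 1L) sum(v) else rowSums(matrix(v, nrow = npos[i]))
  }
  total_llr <- function(z) {
    m <- sum(z > 0L)
    if (!m) return(-Inf)
    lo <- log_odds(site_counts(z), m)
    sum(vapply(which(z > 0L), function(i) window_scores(i, lo)[z[i]],
               numeric(1)))
  }

  zoops <- cfg$mode == "zoops"
  log_none <- if (zoops)
    log2((1 - cfg$site_prior) / cfg$site_prior) else NULL

  best_z <- NULL
  best_llr <- -Inf
  .with_seed(cfg$seed, {
    for (r in seq_len(cfg$restarts)) {
      z <- vapply(npos, function(k) sample.int(k, 1L), integer(1))
      counts <- site_counts(z)
      for (iter in seq_len(cfg$iterations + 2L)) {
        greedy <- iter > cfg$iterations
        for (i in seq_len(n)) {
          if (z[i] > 0L) {
            win <- seqs[[i]][z[i] + seq_len(w) - 1L]
            counts[cbind(win, seq_len(w))] <- counts[cbind(win, seq_len(w))] - 1
          }
          m <- sum(z > 0L) - (z[i] > 0L)
          sc <- window_scores(i, log_odds(counts, m))
          opts <- if (zoops) c(log_none + log2(npos[i]), sc) else sc
          pick <- if (greedy) which.max(opts) else {
            p <- 2^(opts - max(opts))
            sample.int(length(opts), 1L, prob = p)
          }
          z[i] <- if (zoops) pick - 1L else pick
          if (z[i] > 0L) {
            win <- seqs[[i]][z[i] + seq_len(w) - 1L]
            counts[cbind(win, seq_len(w))] <- counts[cbind(win, seq_len(w))] + 1
          }
        }
      }
      llr <- total_llr(z)
      if (llr > best_llr) {
        best_llr <- llr
        best_z <- z
      }
    }
  })

  keep <- which(best_z > 0L)
  if (!length(keep))
    return(prediction_run(dataset_id, finder_id, has_output = FALSE))
  lo <- log_odds(site_counts(best_z), length(keep))
  scores <- vapply(keep, function(i) window_scores(i, lo)[best_z[i]],
                   numeric(1))
  mean_bits <- mean(scores)
  thr <- cfg$significance_threshold
  if (!is.null(thr) && mean_bits < thr)
    return(prediction_run(dataset_id, finder_id, has_output = FALSE))
  sites <- data.frame(
    species = records$species[keep], gene = records$gene[keep],
    start = best_z[keep] - 1L, end = best_z[keep] - 1L + w,
    strand = "+",
    sequence = substr(records$sequence[keep], best_z[keep],
                      best_z[keep] + w - 1L),
    score = scores, stringsAsFactors = FALSE)
  model <- build_wm_from_sites(sites$sequence, pc,
                               label = paste0(finder_id, "_", dataset_id))
  prediction_run(dataset_id, finder_id, sites = sites, model = model)
}

#' Null-calibrated significance cut-off for [gibbs_find()]
#'
#' Mean per-site log2 likelihood-ratio (bits per site) below which a run is
#' reported as having no output. Calibrated once as the upper 5% quantile of
#' the finder's score on 100 pure background datasets (10 uniform 500 bp
#' sequences, width 13, default sampler settings), where any "motif" is an
#' overfitting artefact.
#' @export
GIBBS_SIGNIFICANCE_THRESHOLD <- 14.2
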