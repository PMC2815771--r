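PREDICTION_COLUMNS <- c("dataset_id", "finder_id", "species", "gene",
                        "start", "end", "strand", "site_sequence", "score")

#' Write and read predicted motif sites
#'
#' The interchange format between motif finders and the evaluator is a TSV
#' with a header line and the columns `dataset_id`, `finder_id`, `species`,
#' `gene`, `start`, `end` (0-based half-open), `strand`, `site_sequence`,
#' `score`. External tools' outputs can be converted into it (see
#' [parse_meme_output()]); runs without output simply contribute no rows.
#'
#' @param runs A list of [prediction_run()] objects (or a single one).
#' @param path TSV path.
#' @return `write_predictions()` returns `path` invisibly;
#'   `read_predictions()` a data frame with the columns above.
#' @export
write_predictions <- function(runs, path) {
  if (inherits(runs, "prediction_run")) runs <- list(runs)
  rows <- lapply(runs, function(run) {
    if (!run$has_output || !nrow(run$sites)) return(NULL)
    data.frame(dataset_id = run$dataset_id, finder_id = run$finder_id,
               species = run$sites$species, gene = run$sites$gene,
               start = run$sites$start, end = run$sites$end,
               strand = if (!is.null(run$sites$strand)) run$sites$strand else "+",
               site_sequence = if (!is.null(run$sites$sequence))
                 run$sites$sequence else "",
               score = if (!is.null(run$sites$score)) run$sites$score
                 else NA_real_,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(NULL)))
  if (is.null(df)) df <- as.data.frame(
    stats::setNames(rep(list(character(0)), length(PREDICTION_COLUMNS)),
                    PREDICTION_COLUMNS))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(score = "numeric"))
  missing <- setdiff(PREDICTION_COLUMNS, names(df))
  if (length(missing))
    stop("prediction TSV lacks required columns: ",
         paste(missing, collapse = ", "))
  df
}

#' Group a prediction table into runs
#'
#' @param predictions Data frame from [read_predictions()].
#' @param dataset_ids All dataset ids of the test; datasets with no rows in
#'   the table become runs with `has_output = FALSE`.
#' @param finder_id Finder to extract (defaults to the single finder present).
#' @return List of [prediction_run()] objects, one per dataset id.
#' @export
prediction_runs <- function(predictions, dataset_ids, finder_id = NULL) {
  if (is.null(finder_id)) {
    finders <- unique(predictions$finder_id)
    if (length(finders) > 1L)
      stop("multiple finders present; specify finder_id")
    finder_id <- if (length(finders)) finders else "unknown"
  }
  predictions <- predictions[predictions$finder_id == finder_id, , drop = FALSE]
  lapply(dataset_ids, function(id) {
    rows <- predictions[predictions$dataset_id == id, , drop = FALSE]
    if (!nrow(rows)) return(prediction_run(id, finder_id, has_output = FALSE))
    prediction_run(id, finder_id, sites = data.frame(
      species = rows$species, gene = rows$gene,
      start = rows$start, end = rows$end, strand = rows$strand,
      sequence = rows$site_sequence, score = rows$score,
      stringsAsFactors = FALSE))
  })
}

#' Adapter for MEME plain-text output
#'
#' Extracts the predicted sites of each motif from a classic MEME text report
#' (the `sites sorted by position p-value` blocks) and returns them in the
#' package's prediction-table layout. Sequence names are expected to be the
#' simulator's FASTA headers `dataset_id|species|gene` (a bare
#' `species|gene` is also accepted). MEME's 1-based starts are converted to
#' 0-based half-open coordinates.
#'
#' @param path Path to a MEME text output file (or a character vector of its
#'   lines via `lines`).
#' @param lines Alternative to `path`: the lines of the report.
#' @param dataset_id Fallback dataset id when headers carry only
#'   `species|gene`.
#' @param finder_id Finder id recorded in the table (default `"meme"`).
#' @param motif Which motif block to extract (default 1).
#' @return Data frame in the [read_predictions()] layout.
#' @export
parse_meme_output <- function(path = NULL, lines = NULL, dataset_id = NA,
                              finder_id = "meme", motif = 1L) {
  if (is.null(lines)) lines <- readLines(path)
  starts <- grep("sites sorted by position p-value", lines)
  if (length(starts) < motif)
    stop("no MEME site block found for motif ", motif)
  i <- starts[[motif]]
  # skip the header/dash lines that follow, then read until the closing dashes
  j <- i + 1L
  dashes <- 0L
  rows <- list()
  while (j <= length(lines)) {
    line <- lines[[j]]
    if (grepl("^-{5,}", trimws(line))) {
      dashes <- dashes + 1L
      if (dashes >= 3L) break
      j <- j + 1L
      next
    }
    if (dashes >= 2L && nzchar(trimws(line))) {
      tok <- strsplit(trimws(line), "\\s+")[[1L]]
      if (length(tok) >= 4L) {
        name <- tok[[1L]]
        tok <- tok[-1L]
        strand <- "+"
        if (tok[[1L]] %in% c("+", "-")) {
          strand <- tok[[1L]]
          tok <- tok[-1L]
        }
        start1 <- suppressWarnings(as.integer(tok[[1L]]))
        dna <- tok[grepl("^[ACGTacgt]+$", tok)]
        site <- dna[which.max(nchar(dna))]
        if (!is.na(start1) && length(site)) {
          parts <- strsplit(name, "|", fixed = TRUE)[[1L]]
          rows[[length(rows) + 1L]] <- data.frame(
            dataset_id = if (length(parts) >= 3L) parts[[1L]] else dataset_id,
            finder_id = finder_id,
            species = if (length(parts) >= 3L) parts[[2L]] else parts[[1L]],
            gene = as.integer(parts[[length(parts)]]),
            start = start1 - 1L,
            end = start1 - 1L + nchar(site),
            strand = strand,
            site_sequence = toupper(site),
            score = NA_real_,
            stringsAsFactors = FALSE)
        }
      }
    }
    j <- j + 1L
  }
  out <- do.call(rbind, c(rows, list(NULL)))
  if (is.null(out))
    stop("no site rows parsed from the MEME block")
  out
}

#' Write a per-test report table
#'
#' One row per test in the layout of the benchmark's result tables:
#' D1/R1, RR and the mean quality measures over correct outputs.
#'
#' @param summaries Named list of `test_summary` objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(summaries, path) {
  df <- do.call(rbind, lapply(names(summaries), function(nm) {
    s <- summaries[[nm]]
    data.frame(test = nm, mode = s$mode, n_runs = s$n_runs,
               d1_or_r1 = s$d1_or_r1, rr = .fmt_num(s$rr),
               ppv = .fmt_num(s$ppv), sens = .fmt_num(s$sens),
               sp_ppv = .fmt_num(s$sp_ppv), sp_sens = .fmt_num(s$sp_sens),
               f_value = .fmt_num(s$f_value), stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.fmt_num <- function(x) if (is.na(x)) "NA" else sprintf("%.4f", x)
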