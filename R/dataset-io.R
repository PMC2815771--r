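#' Write and read benchmark datasets
#'
#' A dataset directory holds `sequences.fasta` (headers
#' `dataset_id|species|gene`), `truth.gff3` (ground-truth sites, 1-based
#' inclusive coordinates, feature type `TF_binding_site`, the source motif
#' label in the `wm_label` attribute) and `manifest.json` (space tag,
#' generation config, seed). `read_dataset(write_dataset(ds, d))` restores
#' the dataset, and replaying the manifest's config and seed regenerates it
#' byte-identically.
#'
#' @param ds A [benchmark_dataset()].
#' @param directory Dataset directory (created if needed).
#' @return `write_dataset()` returns `directory` invisibly; `read_dataset()`
#'   returns a [benchmark_dataset()].
#' @export
write_dataset <- function(ds, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  headers <- paste(ds$dataset_id, ds$records$species, ds$records$gene,
                   sep = "|")
  seqs <- Biostrings::DNAStringSet(stats::setNames(ds$records$sequence,
                                                   headers))
  Biostrings::writeXStringSet(seqs, file.path(directory, "sequences.fasta"),
                              width = 80L)

  gff_path <- file.path(directory, "truth.gff3")
  if (nrow(ds$sites)) {
    gr <- GenomicRanges::GRanges(
      seqnames = paste(ds$dataset_id, ds$sites$species, ds$sites$gene,
                       sep = "|"),
      ranges = IRanges::IRanges(start = ds$sites$start + 1L,
                                end = ds$sites$end),
      strand = ds$sites$strand)
    gr$source <- "motifbench"
    gr$type <- "TF_binding_site"
    gr$wm_label <- ds$sites$wm_label
    rtracklayer::export(gr, gff_path, format = "gff3")
  } else {
    writeLines("##gff-version 3", gff_path)
  }

  manifest <- list(dataset_id = ds$dataset_id, space = ds$space,
                   seed = ds$seed, config = ds$config)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(directory)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(directory) {
  fasta <- file.path(directory, "sequences.fasta")
  gff <- file.path(directory, "truth.gff3")
  man_path <- file.path(directory, "manifest.json")
  if (!file.exists(fasta) || !file.exists(gff) || !file.exists(man_path))
    stop("not a dataset directory (missing files): ", directory)
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)

  seqs <- Biostrings::readDNAStringSet(fasta)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop("FASTA headers must be 'dataset_id|species|gene'")
  records <- data.frame(
    species = vapply(parts, `[[`, character(1), 2L),
    gene = as.integer(vapply(parts, `[[`, character(1), 3L)),
    sequence = as.character(seqs),
    stringsAsFactors = FALSE)

  gr <- rtracklayer::import(gff, format = "gff3")
  if (length(gr)) {
    sparts <- strsplit(as.character(GenomicRanges::seqnames(gr)), "|",
                       fixed = TRUE)
    sites <- data.frame(
      species = vapply(sparts, `[[`, character(1), 2L),
      gene = as.integer(vapply(sparts, `[[`, character(1), 3L)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      wm_label = as.character(gr$wm_label),
      stringsAsFactors = FALSE)
  } else {
    sites <- .bind_sites(list())
  }

  config <- manifest$config
  if (!is.null(config$background)) config$background <- unlist(config$background)
  benchmark_dataset(manifest$space, records, sites, config,
                    seed = manifest$seed, dataset_id = manifest$dataset_id)
}
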