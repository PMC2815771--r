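#' Benchmark dataset container
#'
#' A simulated benchmark dataset for one of the three information spaces:
#' *coregulation* (many coregulated promoters from the reference species
#' only), *orthologous* (a single promoter together with its orthologs) or
#' *combined* (many coregulated promoters, each with its orthologs). A
#' reference gene plus its orthologs forms an *orthologous set*; genes index
#' the sets and species the members.
#'
#' @param space One of `"coregulation"`, `"orthologous"`, `"combined"`.
#' @param records Data frame with columns `species`, `gene`, `sequence`;
#'   (species, gene) pairs unique, sequences non-empty.
#' @param sites Ground-truth data frame with columns `species`, `gene`,
#'   `start`, `end` (0-based half-open), `strand` (always `"+"`), `wm_label`.
#' @param config List of generation parameters (kept for the manifest).
#' @param seed Integer seed the dataset was generated from.
#' @param dataset_id Identifier string.
#' @return An object of class `benchmark_dataset`.
#' @export
benchmark_dataset <- function(space, records, sites, config = list(),
                              seed = NA_integer_,
                              dataset_id = paste0(space, "_", seed)) {
  space <- match.arg(space, c("coregulation", "orthologous", "combined"))
  stopifnot(is.data.frame(records),
            all(c("species", "gene", "sequence") %in% names(records)))
  if (anyDuplicated(records[c("species", "gene")]))
    stop("(species, gene) pairs must be unique within a dataset")
  if (any(!nzchar(records$sequence))) stop("sequences must be non-empty")
  sites <- as.data.frame(sites)
  if (nrow(sites)) {
    key <- paste(sites$species, sites$gene)
    rkey <- paste(records$species, records$gene)
    if (!all(key %in% rkey))
      stop("ground-truth sites must reference records in the dataset")
    len <- nchar(records$sequence)[match(key, rkey)]
    if (any(sites$start < 0) || any(sites$end <= sites$start) ||
        any(sites$end > len))
      stop("ground-truth coordinates out of bounds")
  }
  n_genes <- length(unique(records$gene))
  members <- table(records$gene)
  if (space == "coregulation" && any(members != 1L))
    stop("coregulation-space sets must have exactly one member each")
  if (space == "orthologous" && n_genes != 1L)
    stop("the orthologous space holds exactly one orthologous set")
  if (space == "combined" && (n_genes < 2L || any(members < 2L)))
    stop("combined-space datasets need >= 2 sets with >= 2 members each")
  structure(list(dataset_id = dataset_id, space = space,
                 records = records, sites = sites,
                 config = config, seed = as.integer(seed)),
            class = "benchmark_dataset")
}

#' @export
print.benchmark_dataset <- function(x, ...) {
  cat(sprintf(
    "benchmark_dataset '%s': %s space, %d sequences (%d sets), %d truth sites\n",
    x$dataset_id, x$space, nrow(x$records), length(unique(x$records$gene)),
    nrow(x$sites)))
  invisible(x)
}

#' Ground-truth site sequences of a dataset
#'
#' Extracts the embedded motif site of every ground-truth record; these
#' define the dataset's "correct motif model" via [build_wm_from_sites()].
#'
#' @param ds A [benchmark_dataset()].
#' @return Character vector of site sequences (empty if no sites).
#' @export
truth_site_sequences <- function(ds) {
  if (!nrow(ds$sites)) return(character())
  key <- paste(ds$sites$species, ds$sites$gene)
  rkey <- paste(ds$records$species, ds$records$gene)
  seqs <- ds$records$sequence[match(key, rkey)]
  substr(seqs, ds$sites$start + 1L, ds$sites$end)
}

#' Correct motif model of a dataset
#'
#' @param ds A [benchmark_dataset()].
#' @param pseudocount Pseudocount passed to [build_wm_from_sites()].
#' @return The [weight_matrix()] estimated from the embedded sites.
#' @export
correct_motif_model <- function(ds, pseudocount = 0.25) {
  build_wm_from_sites(truth_site_sequences(ds), pseudocount = pseudocount,
                      label = paste0(ds$dataset_id, "_truth"))
}

#' Draw an ancestral promoter with an embedded motif site
#'
#' An i.i.d. background sequence of `bg_length` bases with one site sampled
#' from `wm` overwriting a window at a uniformly random position, so the
#' total length stays exactly `bg_length`. Uses the current RNG state.
#'
#' @param bg_length Background length in bp (>= motif width); the synthetic
#'   promoters are 500 bp by default throughout the package.
#' @param wm A [weight_matrix()], or `NULL` for a pure background sequence.
#' @param background Background base distribution.
#' @return List with `sequence` (string) and `site` (`NULL`, or list with
#'   `start`, `end` 0-based half-open and `wm`).
#' @export
make_ancestor <- function(bg_length, wm, background = rep(0.25, 4)) {
  .check_background(background)
  if (!is.null(wm) && bg_length < wm_width(wm))
    stop("bg_length must be at least the motif width")
  idx <- sample.int(4L, bg_length, replace = TRUE, prob = background)
  site <- NULL
  if (!is.null(wm)) {
    w <- wm_width(wm)
    start <- sample.int(bg_length - w + 1L, 1L) - 1L  # 0-based
    idx[start + seq_len(w)] <- .encode_seq(sample_site(wm))
    site <- list(start = start, end = start + w, wm = wm)
  }
  list(sequence = .decode_seq(idx), site = site)
}

.with_seed <- function(seed, expr) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  expr
}

#' Simulate a coregulation-space dataset
#'
#' Ten (by default) independent promoters of coregulated genes in the
#' reference species. Each promoter is an independent ancestor (500 bp
#' background with one embedded site from the common motif model) evolved
#' along a single branch of proximity `ref_proximity` (0.80 by default, the
#' proximity of the reference species to the ancestor). `dropout_k` randomly
#' chosen genes carry no motif site at all, lowering the signal-to-noise
#' ratio in the coregulation direction.
#'
#' @param n_genes Number of coregulated genes.
#' @param wm The common motif [weight_matrix()].
#' @param ref_proximity Proximity of the reference species to the ancestor.
#' @param bg_length Promoter length in bp.
#' @param dropout_k Number of genes without a motif site (0..n_genes).
#' @param seed Integer seed; generation is fully reproducible from it.
#' @param background Background base distribution.
#' @param dataset_id Identifier (defaulted from space and seed).
#' @return A [benchmark_dataset()] whose records all belong to species `REF`.
#' @export
simulate_coregulation_space <- function(n_genes = 10L, wm,
                                        ref_proximity = 0.80,
                                        bg_length = 500L, dropout_k = 0L,
                                        seed = 1L,
                                        background = rep(0.25, 4),
                                        dataset_id = NULL) {
  if (dropout_k < 0L || dropout_k > n_genes)
    stop("dropout_k must lie in [0, n_genes]")
  tree <- star_tree(ref_proximity, "REF")
  .with_seed(seed, {
    dropped <- if (dropout_k > 0L) sample.int(n_genes, dropout_k) else integer()
    rec <- vector("list", n_genes)
    sit <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      anc <- make_ancestor(bg_length, if (g %in% dropped) NULL else wm,
                           background)
      leaf <- evolve_sequence(anc$sequence, tree, anc$site,
                              background = background)[["REF"]]
      rec[[g]] <- data.frame(species = "REF", gene = g,
                             sequence = leaf$sequence,
                             stringsAsFactors = FALSE)
      if (!is.null(leaf$site))
        sit[[g]] <- data.frame(species = "REF", gene = g,
                               start = leaf$site$start, end = leaf$site$end,
                               strand = "+", wm_label = leaf$site$wm_label,
                               stringsAsFactors = FALSE)
    }
    config <- list(space = "coregulation", n_genes = n_genes,
                   width = wm_width(wm), wm_label = wm_label(wm),
                   ref_proximity = ref_proximity, bg_length = bg_length,
                   dropout_k = dropout_k, background = background)
    if (is.null(dataset_id)) dataset_id <- paste0("coregulation_", seed)
    benchmark_dataset("coregulation", do.call(rbind, rec),
                      .bind_sites(sit), config, seed, dataset_id)
  })
}

.bind_sites <- function(lst) {
  lst <- lst[!vapply(lst, is.null, logical(1))]
  if (!length(lst))
    return(data.frame(species = character(), gene = integer(),
                      start = integer(), end = integer(),
                      strand = character(), wm_label = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}

#' Simulate a combined coregulation-orthology dataset
#'
#' Extends the coregulation space with orthologs: each of the `n_genes`
#' coregulated reference genes gets an independent ancestral promoter that is
#' evolved down `tree`, yielding one orthologous set per gene with one member
#' per leaf species. Motif loss can be applied in the orthologous direction
#' (`loss$lost_species`: the site is absent in every sequence of those
#' species) and/or the coregulation direction (`loss$lost_genes`: the whole
#' orthologous set of those genes carries no site).
#'
#' @inheritParams simulate_coregulation_space
#' @param tree A [proximity_tree] relating the species (must contain the
#'   reference leaf, conventionally `REF` at proximity 0.80).
#' @param loss A [loss_spec()].
#' @return A [benchmark_dataset()] in the combined space.
#' @export
simulate_combined_space <- function(n_genes = 10L, wm, tree,
                                    loss = loss_spec(), bg_length = 500L,
                                    seed = 1L, background = rep(0.25, 4),
                                    dataset_id = NULL) {
  bad <- setdiff(loss$lost_genes, seq_len(n_genes))
  if (length(bad))
    stop("lost genes outside 1..n_genes: ", paste(bad, collapse = ", "))
  missing_sp <- setdiff(loss$lost_species, tree_leaves(tree))
  if (length(missing_sp))
    stop("lost species absent from tree: ", paste(missing_sp, collapse = ", "))
  .with_seed(seed, {
    rec <- list()
    sit <- list()
    for (g in seq_len(n_genes)) {
      anc <- make_ancestor(bg_length,
                           if (g %in% loss$lost_genes) NULL else wm,
                           background)
      leaves <- evolve_sequence(anc$sequence, tree, anc$site, loss,
                                background = background)
      for (sp in names(leaves)) {
        rec[[length(rec) + 1L]] <- data.frame(
          species = sp, gene = g, sequence = leaves[[sp]]$sequence,
          stringsAsFactors = FALSE)
        s <- leaves[[sp]]$site
        if (!is.null(s))
          sit[[length(sit) + 1L]] <- data.frame(
            species = sp, gene = g, start = s$start, end = s$end,
            strand = "+", wm_label = s$wm_label, stringsAsFactors = FALSE)
      }
    }
    config <- list(space = "combined", n_genes = n_genes,
                   width = wm_width(wm), wm_label = wm_label(wm),
                   newick = write_newick(tree), bg_length = bg_length,
                   lost_species = loss$lost_species,
                   lost_genes = loss$lost_genes, background = background)
    if (is.null(dataset_id)) dataset_id <- paste0("combined_", seed)
    benchmark_dataset("combined", do.call(rbind, rec), .bind_sites(sit),
                      config, seed, dataset_id)
  })
}

#' Simulate an orthologous-space dataset
#'
#' A single reference promoter together with its simulated orthologs: one
#' orthologous set obtained by evolving one ancestral promoter down `tree`.
#'
#' @inheritParams simulate_combined_space
#' @return A [benchmark_dataset()] in the orthologous space.
#' @export
simulate_orthologous_space <- function(wm, tree, bg_length = 500L, seed = 1L,
                                       loss = loss_spec(),
                                       background = rep(0.25, 4),
                                       dataset_id = NULL) {
  if (length(loss$lost_genes))
    stop("coregulation-direction loss does not apply to a single set")
  missing_sp <- setdiff(loss$lost_species, tree_leaves(tree))
  if (length(missing_sp))
    stop("lost species absent from tree: ", paste(missing_sp, collapse = ", "))
  .with_seed(seed, {
    anc <- make_ancestor(bg_length, wm, background)
    leaves <- evolve_sequence(anc$sequence, tree, anc$site, loss,
                              background = background)
    rec <- list()
    sit <- list()
    for (sp in names(leaves)) {
      rec[[length(rec) + 1L]] <- data.frame(
        species = sp, gene = 1L, sequence = leaves[[sp]]$sequence,
        stringsAsFactors = FALSE)
      s <- leaves[[sp]]$site
      if (!is.null(s))
        sit[[length(sit) + 1L]] <- data.frame(
          species = sp, gene = 1L, start = s$start, end = s$end,
          strand = "+", wm_label = s$wm_label, stringsAsFactors = FALSE)
    }
    config <- list(space = "orthologous", n_genes = 1L,
                   width = wm_width(wm), wm_label = wm_label(wm),
                   newick = write_newick(tree), bg_length = bg_length,
                   lost_species = loss$lost_species, background = background)
    if (is.null(dataset_id)) dataset_id <- paste0("orthologous_", seed)
    benchmark_dataset("orthologous", do.call(rbind, rec), .bind_sites(sit),
                      config, seed, dataset_id)
  })
}
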