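.encode_seq <- function(s) {
  idx <- match(strsplit(toupper(s), "", fixed = TRUE)[[1L]], DNA_BASES)
  if (anyNA(idx)) stop("sequence must be over the alphabet A/C/G/T")
  idx
}

.decode_seq <- function(idx) paste(DNA_BASES[idx], collapse = "")

#' Single-parameter substitution transition matrix
#'
#' The copy-or-redraw form of the Felsenstein (F81) model used along each
#' branch: with proximity `q`, a base is copied unchanged with probability `q`
#' and otherwise redrawn from the equilibrium distribution \eqn{\pi}, giving
#' \deqn{P(a \to b) = q\,\delta_{ab} + (1 - q)\,\pi_b.}
#' With a uniform equilibrium this is the Jukes-Cantor model (used for
#' background positions); with a motif-column equilibrium it is the adapted
#' F81 model used for embedded motif positions. Matrices compose as
#' `T(q1) %*% T(q2) == T(q1 * q2)` for a shared equilibrium, so evolving over
#' two consecutive edges is the same as one edge with the product proximity.
#'
#' @param q Proximity in \[0, 1\].
#' @param equilibrium Equilibrium base probabilities (A, C, G, T).
#' @return A 4 x 4 row-stochastic matrix with rows/columns named A, C, G, T.
#' @examples
#' transition_matrix(1, rep(0.25, 4))  # identity
#' @export
transition_matrix <- function(q, equilibrium = rep(0.25, 4)) {
  if (length(q) != 1L || is.na(q) || q < 0 || q > 1)
    stop("q must be a single value in [0, 1]")
  .check_background(equilibrium)
  m <- q * diag(4) + (1 - q) * matrix(equilibrium, 4, 4, byrow = TRUE)
  dimnames(m) <- list(DNA_BASES, DNA_BASES)
  m
}

#' Motif-loss specification
#'
#' Declares where embedded motif sites are absent. `lost_species` removes the
#' site from every sequence of the named species (loss in the *orthologous*
#' direction: the mode of regulation is not conserved in that species);
#' `lost_genes` removes it from the named reference genes *and all their
#' orthologs* (loss in the *coregulation* direction: those genes are not truly
#' coregulated).
#'
#' @param lost_species Character vector of species labels.
#' @param lost_genes Integer vector of gene indices.
#' @return An object of class `loss_spec`.
#' @export
loss_spec <- function(lost_species = character(), lost_genes = integer()) {
  structure(list(lost_species = as.character(lost_species),
                 lost_genes = as.integer(lost_genes)),
            class = "loss_spec")
}

# evolve one parent sequence along one edge; site_cols maps sequence position
# -> motif column (0 = background); wm/background give the equilibria
.evolve_edge <- function(parent_idx, q, site_cols, wm, background) {
  n <- length(parent_idx)
  child <- parent_idx
  repl <- which(stats::runif(n) >= q)
  if (length(repl)) {
    bg_repl <- repl[site_cols[repl] == 0L]
    if (length(bg_repl))
      child[bg_repl] <- sample.int(4L, length(bg_repl), replace = TRUE,
                                   prob = background)
    motif_repl <- repl[site_cols[repl] > 0L]
    for (p in motif_repl)
      child[p] <- sample.int(4L, 1L, prob = unclass(wm)[, site_cols[p]])
  }
  child
}

# edge indices in deterministic pre-order (parents before children,
# siblings in edge-matrix order) so RNG consumption is reproducible
.preorder_edges <- function(phy) {
  root <- length(phy$tip.label) + 1L
  order <- integer(0)
  stack <- root
  while (length(stack)) {
    node <- stack[[1L]]
    stack <- stack[-1L]
    kids <- which(phy$edge[, 1L] == node)
    order <- c(order, kids)
    stack <- c(phy$edge[kids, 2L], stack)
  }
  order
}

#' Evolve an ancestral sequence down a phylogeny
#'
#' Recursively evolves an ancestral promoter sequence (background with an
#' optionally embedded motif site) from the root to every leaf of a
#' [proximity_tree]. Along each edge with proximity `q`, every position is
#' independently copied with probability `q` or redrawn from its equilibrium:
#' the background distribution for background positions (Jukes-Cantor for the
#' uniform default) and the corresponding weight-matrix column for motif
#' positions (adapted F81). The model is substitution-only, so all leaf
#' sequences keep the ancestor's length and the site window its coordinates.
#'
#' For a species listed in `loss$lost_species` the site window is replaced at
#' the leaf by freshly drawn background sequence and no ground-truth site is
#' reported for that leaf.
#'
#' Edges are traversed in deterministic pre-order, so results are reproducible
#' for a given RNG state regardless of tree shape.
#'
#' @param ancestor Ancestral sequence (character string over A/C/G/T).
#' @param tree A [proximity_tree]; leaf labels are the species.
#' @param site `NULL`, or a list with `start` (0-based inclusive) and `wm`
#'   (the [weight_matrix()] the embedded site was sampled from).
#' @param loss A [loss_spec()].
#' @param background Background base distribution.
#' @return Named list (one entry per leaf label) of lists with elements
#'   `sequence` (character string) and `site` (`NULL`, or a list with `start`,
#'   `end` in 0-based half-open coordinates and `wm_label`).
#' @export
evolve_sequence <- function(ancestor, tree, site = NULL, loss = loss_spec(),
                            background = rep(0.25, 4)) {
  .check_background(background)
  anc_idx <- .encode_seq(ancestor)
  n <- length(anc_idx)
  site_cols <- integer(n)
  if (!is.null(site)) {
    w <- wm_width(site$wm)
    if (site$start < 0 || site$start + w > n)
      stop("site annotation lies outside the ancestral sequence")
    site_cols[site$start + seq_len(w)] <- seq_len(w)
  }
  missing_sp <- setdiff(loss$lost_species, tree$tip.label)
  if (length(missing_sp))
    stop("lost species absent from tree: ", paste(missing_sp, collapse = ", "))

  phy <- tree
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  seqs <- vector("list", ntip + phy$Nnode)
  seqs[[root]] <- anc_idx
  out <- vector("list", ntip)
  names(out) <- phy$tip.label

  for (e in .preorder_edges(phy)) {
    par <- phy$edge[e, 1L]
    chi <- phy$edge[e, 2L]
    child_seq <- .evolve_edge(seqs[[par]], phy$edge.length[[e]], site_cols,
                              site$wm, background)
    if (chi > ntip) {
      seqs[[chi]] <- child_seq
    } else {
      sp <- phy$tip.label[[chi]]
      truth <- NULL
      if (!is.null(site)) {
        if (sp %in% loss$lost_species) {
          win <- which(site_cols > 0L)
          child_seq[win] <- sample.int(4L, length(win), replace = TRUE,
                                       prob = background)
        } else {
          truth <- list(start = site$start, end = site$start + wm_width(site$wm),
                        wm_label = attr(site$wm, "label"))
        }
      }
      out[[sp]] <- list(sequence = .decode_seq(child_seq), site = truth)
    }
  }
  out
}
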