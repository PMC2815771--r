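#' Proximity-parameterized phylogenies
#'
#' The species tree that relates a set of orthologous promoter sequences to
#' their common ancestor. Each edge carries a *proximity* `q` in (0, 1]: the
#' probability that a base is copied unchanged from parent to child along that
#' edge, with the complement redrawn from the model's equilibrium
#' distribution. Proximities compose multiplicatively along root-to-leaf
#' paths, so `q = 1` means an identical copy and small `q` a distant relative.
#'
#' A `proximity_tree` is an [ape::read.tree()]-style `phylo` object whose
#' `edge.length` slot holds proximities; all `ape` tooling therefore applies.
#'
#' @name proximity_tree
NULL

.as_proximity_tree <- function(phy) {
  if (is.null(phy$edge.length) || length(phy$edge.length) != nrow(phy$edge) ||
      anyNA(phy$edge.length))
    stop("every non-root edge must carry a branch value")
  if (any(phy$edge.length <= 0) || any(phy$edge.length > 1))
    stop("edge proximities must lie in (0, 1]")
  if (anyDuplicated(phy$tip.label))
    stop("leaf labels must be unique")
  class(phy) <- c("proximity_tree", "phylo")
  phy
}

#' Parse a Newick tree
#'
#' Branch values are read either directly as proximities (the native
#' parameterization of the simulator) or as expected substitutions per site,
#' converted through [branch_length_to_proximity()].
#'
#' @param text Newick string with branch values on all non-root edges.
#' @param branch_mode `"proximity"` (default) or `"distance"`.
#' @param equilibrium Equilibrium base distribution used for the distance
#'   conversion (uniform by default, i.e. Jukes-Cantor).
#' @return A [proximity_tree].
#' @examples
#' parse_newick("(REF:0.8,S2:0.9,S3:0.2)ROOT;")
#' @export
parse_newick <- function(text, branch_mode = c("proximity", "distance"),
                         equilibrium = rep(0.25, 4)) {
  branch_mode <- match.arg(branch_mode)
  phy <- tryCatch(suppressWarnings(ape::read.tree(text = text)),
                  error = function(e) NULL)
  if (is.null(phy)) stop("malformed Newick string")
  if (is.null(phy$edge.length) || anyNA(phy$edge.length))
    stop("every non-root edge must carry a branch value")
  if (branch_mode == "distance") {
    if (any(phy$edge.length < 0)) stop("substitution distances must be >= 0")
    phy$edge.length <- branch_length_to_proximity(phy$edge.length, equilibrium)
  }
  .as_proximity_tree(phy)
}

#' Write a tree to Newick
#'
#' @param tree A [proximity_tree].
#' @param branch_mode Emit branch values as proximities (default) or convert
#'   back to substitution distances.
#' @param equilibrium Equilibrium distribution for the distance conversion.
#' @return A Newick string.
#' @export
write_newick <- function(tree, branch_mode = c("proximity", "distance"),
                         equilibrium = rep(0.25, 4)) {
  branch_mode <- match.arg(branch_mode)
  phy <- tree
  class(phy) <- "phylo"
  if (branch_mode == "distance")
    phy$edge.length <- proximity_to_branch_length(phy$edge.length, equilibrium)
  ape::write.tree(phy)
}

#' Convert between substitution distance and proximity
#'
#' Under the F81 model with equilibrium \eqn{\pi}, a branch of length `t`
#' expected substitutions per site corresponds to a copy probability
#' \eqn{q = e^{-\beta t}} with \eqn{\beta = 1 / (1 - \sum_b \pi_b^2)}; for the
#' uniform (Jukes-Cantor) equilibrium \eqn{\beta = 4/3}. The two functions are
#' inverse to each other.
#'
#' @param t Expected substitutions per site (>= 0); vectorized.
#' @param q Proximity in (0, 1]; vectorized.
#' @param equilibrium Equilibrium base distribution.
#' @return `branch_length_to_proximity()` returns proximities in (0, 1];
#'   `proximity_to_branch_length()` returns distances >= 0.
#' @examples
#' branch_length_to_proximity(0.1673)  # ~0.80
#' @export
branch_length_to_proximity <- function(t, equilibrium = rep(0.25, 4)) {
  .check_background(equilibrium)
  if (any(t < 0)) stop("substitution distance must be >= 0")
  beta <- 1 / (1 - sum(equilibrium^2))
  exp(-beta * t)
}

#' @rdname branch_length_to_proximity
#' @export
proximity_to_branch_length <- function(q, equilibrium = rep(0.25, 4)) {
  .check_background(equilibrium)
  if (any(q <= 0) || any(q > 1)) stop("proximity must lie in (0, 1]")
  beta <- 1 / (1 - sum(equilibrium^2))
  -log(q) / beta
}

#' Root-to-leaf proximity
#'
#' Product of the edge proximities on the path from the root to a leaf, i.e.
#' the total copy probability relating that species to the ancestor.
#'
#' @param tree A [proximity_tree].
#' @param leaf Leaf (species) label.
#' @return Proximity in (0, 1].
#' @export
path_proximity <- function(tree, leaf) {
  tip <- match(leaf, tree$tip.label)
  if (is.na(tip)) stop("unknown leaf: ", leaf)
  root <- length(tree$tip.label) + 1L
  parent <- tree$edge[, 1L]
  child <- tree$edge[, 2L]
  q <- 1
  node <- tip
  while (node != root) {
    e <- match(node, child)
    q <- q * tree$edge.length[[e]]
    node <- parent[[e]]
  }
  q
}

#' Build a star phylogeny
#'
#' All species descend directly from the ancestral root; equal proximities
#' give the "equal star" topologies, differing ones the "unequal star"
#' (e.g. the reference ortholog at 0.80 with close relatives at 0.90, 0.85,
#' 0.75 and one distant species at 0.20).
#'
#' @param proximities Proximity in (0, 1] for each leaf.
#' @param labels Species labels, same length (defaults to `REF, S2, S3, ...`).
#' @return A [proximity_tree].
#' @examples
#' star_tree(c(0.80, 0.90, 0.85, 0.75, 0.20))
#' @export
star_tree <- function(proximities,
                      labels = c("REF", paste0("S", seq_along(proximities)))[
                        seq_along(proximities)]) {
  n <- length(proximities)
  if (n < 1L) stop("at least one leaf is required")
  if (length(labels) != n)
    stop("proximities and labels must have equal length")
  phy <- list(
    edge = cbind(rep(n + 1L, n), seq_len(n)),
    edge.length = as.numeric(proximities),
    tip.label = as.character(labels),
    node.label = "ROOT",
    Nnode = 1L
  )
  class(phy) <- "phylo"
  .as_proximity_tree(phy)
}

#' @export
print.proximity_tree <- function(x, ...) {
  cat(sprintf("proximity_tree: %d leaves (%s)\n", length(x$tip.label),
              paste(x$tip.label, collapse = ", ")))
  cat("newick:", write_newick(x), "\n")
  invisible(x)
}

# leaf labels in deterministic pre-order traversal order
tree_leaves <- function(tree) tree$tip.label
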