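# shared fixtures and independent oracles used across the test files

rand_seq <- function(n) paste(sample(DNA_BASES_T(), n, replace = TRUE),
                              collapse = "")
DNA_BASES_T <- function() c("A", "C", "G", "T")

# a weight matrix with flat-Dirichlet columns (null model for comparisons)
rand_wm <- function(width = 13L, label = "rand") {
  g <- matrix(stats::rgamma(4L * width, 1), 4L)
  weight_matrix(sweep(g, 2L, colSums(g), "/"), label = label)
}

point_mass_wm <- function(seq_string, label = seq_string) {
  idx <- match(strsplit(seq_string, "")[[1]], DNA_BASES_T())
  m <- matrix(0, 4L, length(idx))
  m[cbind(idx, seq_along(idx))] <- 1
  weight_matrix(m, label = label)
}

# brute-force site-matching oracle: plain double loop over interval pairs,
# independent of the package's implementation
oracle_match <- function(predicted, truth) {
  overlap <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2))
  np <- nrow(predicted); nt <- nrow(truth)
  tp <- logical(np); covered <- logical(nt)
  for (i in seq_len(np)) {
    best_j <- NA; best_ov <- -1
    for (j in seq_len(nt)) {
      if (predicted$species[i] != truth$species[j] ||
          predicted$gene[i] != truth$gene[j]) next
      ov <- overlap(predicted$start[i], predicted$end[i],
                    truth$start[j], truth$end[j])
      if (ov >= (truth$end[j] - truth$start[j]) / 2) covered[j] <- TRUE
      if (ov > best_ov ||
          (ov == best_ov && !is.na(best_j) &&
           truth$start[j] < truth$start[best_j])) {
        best_ov <- ov; best_j <- j
      }
    }
    if (!is.na(best_j) && best_ov >= (truth$end[best_j] - truth$start[best_j]) / 2)
      tp[i] <- TRUE
  }
  list(tp = which(tp), fp = which(!tp), fn = which(!covered))
}

# random small matching instance over a 60 bp promoter grid
rand_instance <- function(max_sites = 6L) {
  species <- sample(c("REF", "S2"), 1 + sample.int(2, 1), replace = TRUE)
  mk <- function(n) {
    w <- sample(6:13, n, replace = TRUE)
    st <- sample.int(47, n, replace = TRUE) - 1L
    data.frame(species = sample(species, n, replace = TRUE),
               gene = sample.int(2, n, replace = TRUE),
               start = st, end = pmin(st + w, 60L),
               stringsAsFactors = FALSE)
  }
  list(predicted = mk(sample.int(max_sites, 1)),
       truth = mk(sample.int(max_sites, 1)))
}

# tiny dataset with hand-placed truth sites for evaluation tests
toy_dataset <- function(n_genes = 10L, len = 100L, site_start = 10L,
                        width = 13L, species = "REF") {
  set.seed(99)
  records <- data.frame(
    species = species, gene = seq_len(n_genes),
    sequence = vapply(seq_len(n_genes), function(g) rand_seq(len), ""),
    stringsAsFactors = FALSE)
  sites <- data.frame(species = species, gene = seq_len(n_genes),
                      start = site_start, end = site_start + width,
                      strand = "+", wm_label = "toy",
                      stringsAsFactors = FALSE)
  benchmark_dataset("coregulation", records, sites,
                    dataset_id = "toy", seed = 99L)
}
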