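---
title: "Simulating and scoring phylogenetic motif-discovery benchmarks"
author: "motifbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and scoring phylogenetic motif-discovery benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifbench)
```

## Why this benchmark exists

De novo discovery of transcription-factor binding sites can draw on two
sources of statistical signal: *coregulation* (the same motif recurring in
the promoters of coregulated genes of one species) and *orthology* (the
motif being conserved across the orthologous promoters of related species).
Whether adding orthologs actually helps depends on the motif's degeneracy,
the evolutionary distances involved, and how often the site has been lost —
and the only way to study that relationship with a known answer is
simulation. This package generates promoter datasets with a planted,
evolved motif and scores any finder's predictions against that ground
truth.

## The generative model

**Motif model.** A weight matrix (WM) with `W = 13` columns, each a
probability vector over `{A, C, G, T}`. Specificity is measured as total
relative entropy to the background in bits (`information_content()`); a
"high-IC" motif (~24–26 bits) is close to an exact word, a "low-IC" motif
(~14 bits) is heavily degenerate. `generate_wm()` reaches any feasible
target IC by drawing columns from a symmetric Dirichlet and bisecting the
concentration parameter on fixed underlying draws, so results are
reproducible from the seed. The IC formula itself is the standard
relative-entropy definition; the background vector is configurable and
uniform by default.

**Promoters.** Each ancestral promoter is 500 bp of i.i.d. background with
one sampled site overwriting a window at a uniform position. Overwriting
(rather than inserting) keeps every sequence exactly 500 bp, which also
keeps orthologous sets trivially alignable — coordinates are shared across
the whole tree.

**Evolution.** Branches carry proximities `q ∈ (0, 1]`: a base is copied
with probability `q`, otherwise redrawn from its equilibrium — the
background distribution for background positions (Jukes–Cantor when
uniform) and WM column `i` for motif position `i` (a single-parameter F81
variant). Because `T(q1)·T(q2) = T(q1·q2)` for a shared equilibrium
(`transition_matrix()`; the identity is tested exactly), evolving through
internal nodes edge by edge is distributionally identical to evolving each
leaf directly at its path proximity; the implementation recurses per edge in
a fixed pre-order so that runs are reproducible regardless of tree shape.
The model is substitution-only — no indels, no rate heterogeneity, no motif
turnover — so sequence length and site coordinates are invariants.

**Spaces and defaults.** The simulator's defaults are the benchmark's study
conditions: ten coregulated genes, 500 bp promoters, 13 bp motifs, the
reference species at proximity 0.80. Topologies of interest are the equal
star (e.g. reference 0.80 plus four orthologs at 0.50), the unequal star
(0.80, 0.90, 0.85, 0.75 and one distant ortholog at 0.20) and trees with
internal nodes via arbitrary Newick input (`parse_newick()`, with a
distance mode that maps substitutions/site through `q = exp(-4t/3)` for
uniform equilibrium). Signal-to-noise is lowered either by reducing the
target IC or by omitting sites: `dropout_k` removes sites from k of the
coregulated genes; `loss_spec(lost_species=)` removes them from every
sequence of one species (orthologous direction, implemented as replacing
the site window with fresh background at the leaf); `loss_spec(lost_genes=)`
removes them from whole orthologous sets (coregulation direction).

## Scoring predictions

`match_sites()` applies the half-length rule: a predicted site is a true
positive if, on the same promoter, it covers at least half the length of an
embedded site (real-valued: 6.5 bp of a 13 bp site). Each prediction is
assigned to the single truth site it overlaps most (leftmost on ties) — the
benchmark never plants overlapping sites, so this one-to-one reading only
matters for degenerate inputs. Strand is ignored, since a finder may report
the reverse complement of the same window. PPV, Sens and their
species-dependent variants (restricted to the reference species) are
percentages; 0/0 cases are *undefined* (`NA`) and excluded from means
rather than coerced to 0 or 100, which would bias small tests.

A run's output is *correct* (`recovery()` = 1) when the WM built from its
predicted sites (pseudocount 0.25 per base, which keeps comparison scores
finite) matches the WM built from the embedded sites, or when the rescue
rule holds — spPPV and spSens both above 50%, or either higher than 80%,
strict inequalities. Summaries (`summarize_test()`) report D1 (datasets
with any output; R1 for repeated runs on one input), RR (percent of outputs
that are correct) and quality means taken *only over correct outputs*; the
F-value is the harmonic mean of the mean spPPV and mean spSens.

## Calibrated constants

Two thresholds are package constants, both calibrated once on explicit null
models:

- `MOTIF_MATCH_THRESHOLD = 0.314` for `compare_motifs()`. The score is the
  minimum over column offsets (requiring at least half the shorter width
  aligned) and both orientations of the mean per-column Euclidean distance.
  On 20,000 pairs of independent random 13-column WMs (flat-Dirichlet
  columns) the 5% quantile of that score is 0.314, i.e. unrelated models
  "match" about 5% of the time. The threshold is meant for motifs near 13
  columns; recalibrate for very different widths.
- `GIBBS_SIGNIFICANCE_THRESHOLD = 14.2` bits/site for the optional output
  filter of `gibbs_find()`. On 100 datasets of pure uniform background
  (10 × 500 bp, width 13) the finder's mean per-site log2 likelihood ratio —
  pure overfitting — stays below 14.2 in 95% of runs.

## The baseline finder

`gibbs_find()` is a collapsed Gibbs site sampler (product-multinomial motif
model, 0th-order background estimated from the input, pseudocount 0.25) in
one-site-per-sequence or zero-or-one (`zoops`) mode, with restarts and a
greedy polish. It deliberately treats all sequences — orthologs included —
independently: it is the package's stand-in for a classical,
non-phylogenetic finder, so the benchmark loop runs end to end offline.
It is not a reimplementation of any published tool; external finders plug
in through the predictions TSV (`parse_meme_output()` converts MEME text
reports).

## Numerical and design choices

- Internal coordinates are 0-based half-open (matching the predictions
  TSV); GFF3 output is 1-based inclusive, feature type `TF_binding_site`.
  All planted sites are on the + strand.
- Degenerate inputs: `bg_length = width` puts the site at position 0;
  single-leaf trees degenerate to one sequence; `dropout_k = n_genes`
  yields a dataset with no sites (its "correct model" is then undefined and
  `correct_motif_model()` errors — a test with no signal has no recovery
  question to ask).
- Seeding: every simulation function takes an explicit seed and
  saves/restores the caller's RNG state; grid tests derive per-test seeds
  from the master seed by position, so appending tests never changes
  earlier data; per-replicate seeds are `test_seed + replicate`.
- `generate_wm` edge cases: target 0 and `2·width` are reached in the
  Dirichlet limits (concentration → ∞ / → 0); infeasible targets error.

## Problem sizes used in the test suite

The shipped tests run desk-scale versions of the benchmark: stochastic
model checks use 10,000 positions/replicates (3-SE bands), oracle
comparisons 1,000 random instances, and the end-to-end check 20 datasets
per IC level at IC 25/20/14 with the default sampler settings — chosen as
the smallest sizes at which the binomial error bands are meaningfully
tight. The full-scale protocol (100 datasets per test) is the
`replicates = 100` default of `test_config()`.

## What passing tests do and do not show

The generator reproduces the *statistical* structure of the benchmark:
i.i.d. background, one site per promoter, exact F81/JC evolution, equal
lengths, known loss patterns. Real promoters violate most of this —
composition bias and repeats, indels that destroy the shared coordinate
system (real orthologs need alignment), multiple or zero sites per
promoter, motif turnover, and evolutionary rates that vary along the
sequence. Results on this benchmark therefore bound a finder's behaviour
under ideal conditions; they do not predict performance on real intergenic
data, where alignability is typically the binding constraint.
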