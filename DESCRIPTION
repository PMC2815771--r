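Package: motifbench
Title: Simulation and Evaluation Toolkit for Phylogenetic Motif Discovery Benchmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates synthetic promoter benchmark datasets for de novo
    transcription-factor motif discovery in the coregulation, orthologous and
    combined coregulation-orthology information spaces. Motif sites are sampled
    from weight matrices with controlled information content and evolved along
    proximity-parameterized phylogenies under Jukes-Cantor (background) and
    single-parameter Felsenstein F81 (motif columns) substitution models, with
    optional motif loss in the coregulation or orthologous direction. An
    evaluation engine scores any motif finder's predicted sites against the
    embedded ground truth (PPV, sensitivity, species-dependent variants,
    recovery rate with a quality-based rescue rule, F-value), and a built-in
    Gibbs site sampler allows the full simulate-find-evaluate loop to run
    without external tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
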