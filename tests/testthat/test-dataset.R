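wm13 <- generate_wm(13, 22, seed = 100, label = "highIC")

test_that("ancestral promoters embed one site at a uniform position", {
  set.seed(61)
  anc <- make_ancestor(500L, wm13)
  expect_equal(nchar(anc$sequence), 500L)
  expect_true(anc$site$start >= 0 && anc$site$end <= 500)
  expect_equal(anc$site$end - anc$site$start, 13L)

  degenerate <- make_ancestor(13L, wm13)
  expect_equal(degenerate$site$start, 0L)
  expect_equal(nchar(degenerate$sequence), 13L)

  expect_error(make_ancestor(10L, wm13), "at least the motif width")

  # start positions uniform on [0, 487]
  starts <- vapply(seq_len(10000), function(i)
    make_ancestor(500L, wm13)$site$start, 0L)
  expect_true(all(starts >= 0 & starts <= 487))
  bins <- table(cut(starts, breaks = seq(-0.5, 487.5, length.out = 11)))
  expect_gt(stats::chisq.test(bins)$p.value, 0.01)
})

test_that("coregulation space has one reference record per gene", {
  ds <- simulate_coregulation_space(10L, wm13, seed = 201)
  expect_equal(nrow(ds$records), 10L)
  expect_equal(nrow(ds$sites), 10L)
  expect_true(all(ds$records$species == "REF"))
  expect_true(all(nchar(ds$records$sequence) == 500L))

  drop2 <- simulate_coregulation_space(10L, wm13, dropout_k = 2L, seed = 202)
  expect_equal(nrow(drop2$records), 10L)
  expect_equal(nrow(drop2$sites), 8L)

  all_out <- simulate_coregulation_space(10L, wm13, dropout_k = 10L,
                                         seed = 203)
  expect_equal(nrow(all_out$sites), 0L)
  expect_error(simulate_coregulation_space(10L, wm13, dropout_k = 11L),
               "dropout_k")
})

test_that("combined space counts follow the tree and loss spec", {
  uneq <- star_tree(c(0.80, 0.90, 0.85, 0.75, 0.20))

  full <- simulate_combined_space(10L, wm13, uneq, seed = 301)
  expect_equal(nrow(full$records), 50L)
  expect_equal(nrow(full$sites), 50L)
  expect_true(all(nchar(full$records$sequence) == 500L))

  # loss in the orthologous direction: one species loses its site in each set
  sp_loss <- simulate_combined_space(10L, wm13, uneq,
                                     loss_spec(lost_species = "S4"),
                                     seed = 302)
  expect_equal(nrow(sp_loss$records), 50L)
  expect_equal(nrow(sp_loss$sites), 40L)
  expect_false("S4" %in% sp_loss$sites$species)

  # loss in the coregulation direction: two sets lose all their sites
  gene_loss <- simulate_combined_space(10L, wm13, uneq,
                                       loss_spec(lost_genes = c(3L, 7L)),
                                       seed = 303)
  expect_equal(nrow(gene_loss$records), 50L)
  expect_equal(nrow(gene_loss$sites), 40L)
  expect_setequal(setdiff(1:10, unique(gene_loss$sites$gene)), c(3L, 7L))

  expect_error(simulate_combined_space(10L, wm13, uneq,
                                       loss_spec(lost_species = "S9")),
               "absent from tree")
  expect_error(simulate_combined_space(10L, wm13, uneq,
                                       loss_spec(lost_genes = 12L)),
               "lost genes")
})

test_that("orthologous space is a single orthologous set", {
  eq10 <- star_tree(c(rep(0.5, 10)))
  ds <- simulate_orthologous_space(wm13, eq10, seed = 401)
  expect_equal(nrow(ds$records), 10L)
  expect_equal(nrow(ds$sites), 10L)
  expect_equal(unique(ds$records$gene), 1L)

  five <- simulate_orthologous_space(wm13, star_tree(rep(0.5, 5)), seed = 402)
  expect_equal(nrow(five$records), 5L)

  single <- simulate_orthologous_space(wm13, star_tree(0.8, "REF"),
                                       seed = 403)
  expect_equal(nrow(single$records), 1L)
  expect_equal(nrow(single$sites), 1L)
})

test_that("datasets regenerate bit-identically from (config, seed)", {
  uneq <- star_tree(c(0.80, 0.90, 0.85, 0.75, 0.20))
  a <- simulate_combined_space(10L, wm13, uneq, seed = 555)
  b <- simulate_combined_space(10L, wm13, uneq, seed = 555)
  expect_identical(a$records, b$records)
  expect_identical(a$sites, b$sites)
  c <- simulate_combined_space(10L, wm13, uneq, seed = 556)
  expect_false(identical(a$records$sequence, c$records$sequence))
})

test_that("dataset directories round-trip and honour GFF3 conventions", {
  ds <- simulate_combined_space(10L, wm13,
                                star_tree(c(0.80, 0.90, 0.85, 0.75, 0.20)),
                                loss = loss_spec(lost_species = "S4"),
                                seed = 606)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir, c("sequences.fasta",
                                               "truth.gff3",
                                               "manifest.json")))))
  back <- read_dataset(dir)
  expect_identical(back$space, ds$space)
  expect_identical(back$dataset_id, ds$dataset_id)
  expect_identical(back$seed, ds$seed)
  expect_equal(back$records[order(back$records$species, back$records$gene), ],
               ds$records[order(ds$records$species, ds$records$gene), ],
               ignore_attr = TRUE)
  ord <- function(s) s[order(s$species, s$gene, s$start), ]
  expect_equal(ord(back$sites), ord(ds$sites), ignore_attr = TRUE)

  # GFF3 is 1-based inclusive: internal [s, e) becomes s+1 .. e
  gff <- readLines(file.path(dir, "truth.gff3"))
  body <- gff[!startsWith(gff, "#")]
  fields <- strsplit(body[1], "\t")[[1]]
  expect_identical(fields[3], "TF_binding_site")
  row <- ds$sites[paste(ds$sites$species, ds$sites$gene, sep = "|") ==
                    sub("^[^|]+\\|", "", fields[1]), ][1, ]
  expect_equal(as.integer(fields[4]), row$start + 1L)
  expect_equal(as.integer(fields[5]), row$end)
})

test_that("manifest seed replay regenerates byte-identical FASTA", {
  ds <- simulate_coregulation_space(10L, wm13, seed = 707)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(ds, d1)
  man <- jsonlite::read_json(file.path(d1, "manifest.json"),
                             simplifyVector = TRUE)
  replay <- simulate_from_config(man$config, seed = man$seed, wm = wm13,
                                 dataset_id = man$dataset_id)
  write_dataset(replay, d2)
  expect_identical(readLines(file.path(d1, "sequences.fasta")),
                   readLines(file.path(d2, "sequences.fasta")))
})
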