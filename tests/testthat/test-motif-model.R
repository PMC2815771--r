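test_that("information content has its closed-form values", {
  uniform <- weight_matrix(matrix(0.25, 4, 13))
  expect_equal(information_content(uniform), 0)

  point <- point_mass_wm(strrep("A", 13))
  expect_equal(information_content(point), 26)

  half <- weight_matrix(matrix(c(0.5, 0.5, 0, 0), 4, 1))
  expect_equal(information_content(half), 1)

  # non-uniform background shifts the relative entropy
  expect_gt(information_content(point, c(0.1, 0.4, 0.4, 0.1)), 26)
  expect_error(information_content(point, c(0.5, 0.5, 0)), "4 bases")
})

test_that("weight matrix validation rejects malformed input", {
  expect_error(weight_matrix(matrix(0.3, 4, 5)), "sum to 1")
  expect_error(weight_matrix(matrix(0.25, 5, 4)), "4 rows")
  expect_error(weight_matrix(matrix(c(1.2, -0.2, 0, 0), 4, 1)),
               "non-negative")
})

test_that("generate_wm reaches its target IC and is seed-deterministic", {
  for (target in c(26, 13, 0)) {
    wm <- generate_wm(13, target, tolerance = 0.1, seed = 42)
    expect_equal(information_content(wm), target, tolerance = 0.1)
    expect_equal(wm_width(wm), 13L)
  }
  expect_identical(generate_wm(13, 18, seed = 7), generate_wm(13, 18, seed = 7))
  expect_false(identical(generate_wm(13, 18, seed = 7),
                         generate_wm(13, 18, seed = 8)))
  expect_error(generate_wm(13, 27), "target_ic")
  expect_error(generate_wm(13, -1), "target_ic")
})

test_that("sampled sites follow the column distributions", {
  set.seed(1)
  point <- point_mass_wm("ACGTACGTACGTA")
  expect_identical(as.character(sample_site(point)), "ACGTACGTACGTA")

  wm <- generate_wm(13, 14, seed = 2)
  sites <- sample_site(wm, 10000L)
  expect_true(all(nchar(sites) == 13L))
  counts <- build_wm_from_sites(sites, pseudocount = 0)
  # empirical column frequencies within 3 binomial SE of the WM entries
  # (normal approximation only trusted away from the p ~ 0 boundary)
  p <- unclass(wm)
  se <- sqrt(p * (1 - p) / 10000)
  dev <- abs(unclass(counts) - p)
  ok <- p < 0.005 | dev <= 3 * se
  # with 52 entries one ~3-sigma excursion is expected; none may exceed 4.5
  expect_lte(sum(!ok), 1L)
  expect_true(all(p < 0.005 | dev <= 4.5 * se))
  # and the estimator converges entrywise
  expect_lt(max(abs(unclass(counts) - unclass(wm))), 0.03)
})

test_that("build_wm_from_sites applies the pseudocount formula", {
  expect_equal(unclass(build_wm_from_sites("A", 0))[, 1],
               c(A = 1, C = 0, G = 0, T = 0))
  two <- build_wm_from_sites(c("AC", "AG"), 0)
  expect_equal(unclass(two)[, 1], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(unclass(two)[, 2], c(A = 0, C = 0.5, G = 0.5, T = 0))
  pc <- build_wm_from_sites(c("A", "C"), 0.25)
  expect_equal(unclass(pc)[, 1],
               c(A = 1.25, C = 1.25, G = 0.25, T = 0.25) / 3)
  expect_error(build_wm_from_sites(c("AA", "A")), "equal length")
  expect_error(build_wm_from_sites(character()), "at least one")
})

test_that("motif comparison is symmetric, strand-aware and calibrated", {
  wm <- generate_wm(13, 20, seed = 5)
  self <- compare_motifs(wm, wm)
  expect_equal(self$score, 0)
  expect_true(self$is_match)

  rc <- compare_motifs(wm, wm_reverse_complement(wm))
  expect_equal(rc$score, 0)
  expect_true(rc$is_match)

  set.seed(10)
  a <- rand_wm(13); b <- rand_wm(13)
  expect_equal(compare_motifs(a, b)$score, compare_motifs(b, a)$score)

  # differing widths: a sub-motif of itself still matches at offset
  sub <- weight_matrix(unclass(wm)[, 3:11], label = "sub")
  expect_equal(compare_motifs(wm, sub)$score, 0)

  # null false-match rate near the 5% calibration point
  set.seed(77)
  matches <- vapply(seq_len(1000), function(i)
    compare_motifs(rand_wm(13), rand_wm(13))$is_match, logical(1))
  expect_lt(mean(matches), 0.05 + 2 * sqrt(0.05 * 0.95 / 1000))
})

test_that("weight matrices round-trip through the text format", {
  wm <- generate_wm(13, 17, seed = 9, label = "highIC")
  path <- withr::local_tempfile(fileext = ".wm")
  write_wm(wm, path)
  back <- read_wm(path)
  expect_equal(unclass(back), unclass(wm), tolerance = 1e-12)
  expect_identical(wm_label(back), "highIC")

  # transposed W x 4 layout with '#pos A C G T' header
  tpath <- withr::local_tempfile(fileext = ".wm")
  m <- unclass(wm)
  lines <- c("#pos A C G T",
             vapply(seq_len(ncol(m)), function(j)
               paste(c(j, format(m[, j], digits = 17)), collapse = "\t"), ""))
  writeLines(lines, tpath)
  expect_equal(unclass(read_wm(tpath)), unclass(wm), tolerance = 1e-12,
               ignore_attr = TRUE)
})
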