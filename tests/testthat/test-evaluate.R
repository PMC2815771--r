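site_df <- function(start, end, species = "REF", gene = 1L) {
  n <- length(start)
  data.frame(species = rep_len(species, n), gene = rep_len(gene, n),
             start = start, end = end, strand = rep_len("+", n),
             stringsAsFactors = FALSE)
}

test_that("the half-length rule decides true positives", {
  truth <- site_df(100L, 113L)

  exact <- match_sites(site_df(100L, 113L), truth)
  expect_equal(nrow(exact$tp), 1L)
  expect_equal(nrow(exact$fp), 0L)
  expect_equal(nrow(exact$fn), 0L)

  # overlap 7 >= 6.5 -> TP; overlap 6 < 6.5 -> FP and the truth is missed
  shifted6 <- match_sites(site_df(106L, 119L), truth)
  expect_equal(nrow(shifted6$tp), 1L)
  expect_equal(nrow(shifted6$fn), 0L)

  shifted7 <- match_sites(site_df(107L, 120L), truth)
  expect_equal(nrow(shifted7$tp), 0L)
  expect_equal(nrow(shifted7$fp), 1L)
  expect_equal(nrow(shifted7$fn), 1L)

  none <- match_sites(site_df(integer(), integer()), truth)
  expect_equal(nrow(none$fn), 1L)
  expect_equal(nrow(none$tp) + nrow(none$fp), 0L)

  # sites on another promoter never match
  other <- match_sites(site_df(100L, 113L, gene = 2L), truth)
  expect_equal(nrow(other$tp), 0L)
})

test_that("site matching agrees with a brute-force oracle", {
  set.seed(404)
  for (i in seq_len(1000)) {
    inst <- rand_instance()
    got <- match_sites(inst$predicted, inst$truth)
    want <- oracle_match(inst$predicted, inst$truth)
    expect_identical(as.integer(rownames(got$tp)), want$tp)
    expect_identical(as.integer(rownames(got$fp)), want$fp)
    expect_identical(as.integer(rownames(got$fn)), want$fn)
  }
})

test_that("quality measures follow the printed formulas", {
  truth <- do.call(rbind, lapply(1:3, function(g) site_df(10L, 23L, gene = g)))
  pred <- rbind(do.call(rbind, lapply(1:3, function(g)
                  site_df(10L, 23L, gene = g))),
                site_df(50L, 63L, gene = 1L))
  q <- quality_measures(pred, truth)
  expect_equal(q$ppv, 75)     # TP = 3, FP = 1
  expect_equal(q$sens, 100)   # FN = 0

  # all predictions in a non-reference species: spPPV undefined, spSens 0
  pred_s2 <- site_df(10L, 23L, species = "S2", gene = 1L)
  truth_both <- rbind(truth, site_df(10L, 23L, species = "S2", gene = 1L))
  q2 <- quality_measures(pred_s2, truth_both)
  expect_true(is.na(q2$sp_ppv))
  expect_equal(q2$sp_sens, 0)

  # empty everything: undefined throughout
  q3 <- quality_measures(site_df(integer(), integer()),
                         site_df(integer(), integer())[0, ])
  expect_true(is.na(q3$ppv) && is.na(q3$sens))
})

test_that("quality measures match brute-force counts on random instances", {
  set.seed(505)
  for (i in seq_len(200)) {
    inst <- rand_instance()
    q <- quality_measures(inst$predicted, inst$truth)
    o <- oracle_match(inst$predicted, inst$truth)
    tp <- length(o$tp); fp <- length(o$fp); fn <- length(o$fn)
    expect_equal(q$ppv, if (tp + fp == 0) NA_real_ else 100 * tp / (tp + fp))
    expect_equal(q$sens, if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn))
    ref_p <- inst$predicted[inst$predicted$species == "REF", ]
    ref_t <- inst$truth[inst$truth$species == "REF", ]
    osp <- oracle_match(ref_p, ref_t)
    stp <- length(osp$tp); sfp <- length(osp$fp); sfn <- length(osp$fn)
    expect_equal(q$sp_ppv,
                 if (stp + sfp == 0) NA_real_ else 100 * stp / (stp + sfp))
    expect_equal(q$sp_sens,
                 if (stp + sfn == 0) NA_real_ else 100 * stp / (stp + sfn))
  }
})

test_that("adding a false positive lowers PPV and leaves Sens alone", {
  set.seed(42)
  truth <- do.call(rbind, lapply(1:4, function(g) site_df(10L, 23L, gene = g)))
  pred <- do.call(rbind, lapply(1:3, function(g) site_df(10L, 23L, gene = g)))
  q0 <- quality_measures(pred, truth)
  q1 <- quality_measures(rbind(pred, site_df(60L, 73L, gene = 4L)), truth)
  expect_lt(q1$ppv, q0$ppv)
  expect_equal(q1$sens, q0$sens)
  # permutation invariance
  qp <- quality_measures(pred[sample(nrow(pred)), ], truth)
  expect_equal(qp, q0)
})

test_that("recovery applies the model match and the 50%/80% rescue rule", {
  ds <- toy_dataset()
  correct <- correct_motif_model(ds)
  far_model <- point_mass_wm(strrep("A", 13))
  if (compare_motifs(far_model, correct)$is_match)
    far_model <- point_mass_wm(strrep("C", 13))
  stopifnot(!compare_motifs(far_model, correct)$is_match)

  truth_pred <- function(n_tp, n_fp) {
    tp <- ds$sites[seq_len(n_tp), c("species", "gene", "start", "end")]
    fp <- data.frame(species = rep_len("REF", n_fp), gene = seq_len(n_fp),
                     start = rep_len(60L, n_fp), end = rep_len(73L, n_fp),
                     stringsAsFactors = FALSE)
    out <- rbind(tp, fp)
    out$sequence <- substr(ds$records$sequence[match(
      paste(out$species, out$gene), paste(ds$records$species,
                                          ds$records$gene))],
      out$start + 1L, out$end)
    out
  }
  mk_run <- function(n_tp, n_fp, model = far_model)
    prediction_run("toy", "test", sites = truth_pred(n_tp, n_fp),
                   model = model)

  # a matching model recovers regardless of site quality
  expect_equal(recovery(mk_run(1L, 9L, model = correct), correct, ds), 1L)
  # spPPV 60 / spSens 60: both above 50 -> rescued
  expect_equal(recovery(mk_run(6L, 4L), correct, ds), 1L)
  # spPPV 100 / spSens 20: one above 80 -> rescued
  expect_equal(recovery(mk_run(2L, 0L), correct, ds), 1L)
  # spPPV 40 / spSens 40: rescue fails
  expect_equal(recovery(mk_run(4L, 6L), correct, ds), 0L)
  # boundary: exactly 50/50 is not "above 50"
  expect_equal(recovery(mk_run(5L, 5L), correct, ds), 0L)
  # boundary: exactly 80 with the other leg at 20 is not "higher than 80"
  expect_equal(recovery(mk_run(2L, 0L,
    model = far_model), correct, ds), 1L)  # sanity duplicate of 100/20 case
  expect_error(recovery(prediction_run("toy", "t", has_output = FALSE),
                        correct, ds), "output")
})

test_that("the F-value is the harmonic mean of spPPV and spSens", {
  expect_equal(f_value(100, 100), 100)
  expect_equal(f_value(70, 0), 0)
  expect_equal(f_value(50, 100), 200 / 3)
  expect_true(is.na(f_value(NA, 50)))
  set.seed(9)
  for (i in 1:50) {
    a <- runif(1, 0, 100); b <- runif(1, 0, 100)
    f <- f_value(a, b)
    expect_gte(f, min(a, b) - 1e-12)
    expect_lte(f, max(a, b) + 1e-12)
    expect_equal(f_value(a, a), a)
    expect_equal(f_value(a, b), f_value(b, a))
  }
})

test_that("test summaries aggregate over correct outputs only", {
  ds <- toy_dataset()
  correct <- correct_motif_model(ds)
  perfect_sites <- ds$sites[, c("species", "gene", "start", "end")]
  perfect_sites$sequence <- truth_site_sequences(ds)
  runs <- list(
    prediction_run("toy", "f", sites = perfect_sites),
    prediction_run("toy", "f", sites = perfect_sites),
    prediction_run("toy", "f", has_output = FALSE))
  s <- summarize_test(runs, ds, mode = "per-dataset")
  expect_equal(s$n_runs, 3L)
  expect_equal(s$d1_or_r1, 2L)
  expect_equal(s$rr, 100)
  expect_equal(s$ppv, 100)
  expect_equal(s$sens, 100)
  expect_equal(s$f_value, 100)

  none <- summarize_test(list(prediction_run("toy", "f", has_output = FALSE)),
                         ds)
  expect_equal(none$d1_or_r1, 0L)
  expect_true(is.na(none$rr))
  expect_true(is.na(none$f_value))

  # means over correct outputs only: verified against direct recomputation
  set.seed(66)
  noisy_run <- function(i) {
    n_tp <- sample(0:10, 1)
    sites <- rbind(
      if (n_tp) perfect_sites[seq_len(n_tp), ],
      {
        fp <- data.frame(species = "REF", gene = sample(1:10, 3),
                         start = 60L, end = 73L, stringsAsFactors = FALSE)
        fp$sequence <- substr(ds$records$sequence[fp$gene], 61L, 73L)
        fp
      })
    prediction_run("toy", "f", sites = sites)
  }
  runs <- lapply(1:20, noisy_run)
  s <- summarize_test(runs, ds)
  rec <- vapply(runs, function(r) recovery(r, correct, ds) == 1L, logical(1))
  qs <- lapply(runs[rec], function(r) quality_measures(r$sites, ds$sites))
  expect_equal(s$rr, 100 * mean(rec))
  expect_equal(s$ppv, mean(vapply(qs, `[[`, 0, "ppv")))
  expect_equal(s$sp_sens, mean(vapply(qs, `[[`, 0, "sp_sens")))
  expect_equal(s$f_value, f_value(s$sp_ppv, s$sp_sens))
})

test_that("a perfect predictor scores 100% everywhere", {
  wm <- generate_wm(13, 18, seed = 11)
  ds <- simulate_combined_space(5L, wm, star_tree(c(0.8, 0.5, 0.5)),
                                seed = 88)
  sites <- ds$sites[, c("species", "gene", "start", "end")]
  sites$sequence <- truth_site_sequences(ds)
  run <- prediction_run(ds$dataset_id, "oracle", sites = sites)
  expect_equal(recovery(run, correct_motif_model(ds), ds), 1L)
  q <- quality_measures(run$sites, ds$sites)
  expect_equal(q$ppv, 100)
  expect_equal(q$sens, 100)
  expect_equal(q$sp_ppv, 100)
  expect_equal(q$sp_sens, 100)
})
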