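test_that("k-mer frequencies: closed forms, feature-space size and length identity", {
  f <- count_kmer_frequencies(c(g1 = "AAAA"), 3L)
  expect_equal(unname(f[1, "AAA"]), 0.5)  # 2 windows / length 4
  expect_equal(sum(f), 0.5)               # all other 3-mers zero

  ds <- strong_dataset()
  tab <- count_kmer_frequencies(ds$transcripts[1:20], c(3L, 4L))
  expect_equal(ncol(tab), 320L)  # 4^3 + 4^4
  expect_identical(colnames(tab)[1:3], c("AAA", "AAC", "AAG"))
  expect_identical(colnames(tab)[65:66], c("AAAA", "AAAC"))

  # per-k frequency sums obey (L - k + 1)/L exactly for N-free sequences
  L <- nchar(ds$transcripts[1:20])
  sums3 <- rowSums(tab[, 1:64])
  sums4 <- rowSums(tab[, 65:320])
  expect_equal(unname(sums3), unname((L - 2) / L), tolerance = 1e-12)
  expect_equal(unname(sums4), unname((L - 3) / L), tolerance = 1e-12)

  set.seed(31)
  s <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = "")
  f1000 <- count_kmer_frequencies(c(x = s), 3L)
  expect_equal(sum(f1000), 998 / 1000, tolerance = 1e-12)
})

test_that("windows containing N are skipped while L keeps its full value", {
  f <- count_kmer_frequencies(c(g1 = "AANAA"), 2L)
  # windows: AA, AN, NA, AA -> only the two AA windows count; L = 5
  expect_equal(unname(f[1, "AA"]), 2 / 5)
  expect_equal(sum(f), 2 / 5)
  expect_warning(count_kmer_frequencies(c(a = "ACGT", b = "AC"), 4L), "shorter")
})

test_that("RF importance ranking recovers a strongly planted k-mer", {
  cfg <- simulation_config(n_pos = 500L, n_neg = 500L, n_unlabeled = 0L,
                           informative_kmers = "CGCG", kmer_enrichment = 5,
                           seed = 32L)
  labels <- simulate_expression(cfg)$labels
  seqs <- simulate_transcripts(cfg, labels)
  tab <- count_kmer_frequencies(seqs, 4L)
  for (s in c(1L, 2L)) {
    ranked <- rank_kmers_by_rf_importance(tab, labels, repetitions = 3L,
                                          seed = s, num_trees = 200L)
    expect_lte(which(ranked$kmer == "CGCG"), 5L)
  }
  ranked <- rank_kmers_by_rf_importance(tab, labels, repetitions = 3L,
                                        seed = 1L, num_trees = 200L)
  expect_equal(nrow(ranked), ncol(tab))
  expect_equal(sum(ranked$mean_importance), 1, tolerance = 1e-6)

  # permuted labels: the planted k-mer is no longer preferentially ranked
  set.seed(33)
  perm_pos <- sample(rownames(tab), length(labels$positives))
  perm <- list(positives = perm_pos,
               negatives = setdiff(rownames(tab), perm_pos))
  ranked0 <- rank_kmers_by_rf_importance(tab, perm, repetitions = 3L,
                                         seed = 1L, num_trees = 200L)
  expect_gt(which(ranked0$kmer == "CGCG"), 10L)

  # top of the ranking is stable under column permutation of the input
  perm_cols <- sample(ncol(tab))
  ranked_p <- rank_kmers_by_rf_importance(tab[, perm_cols], labels,
                                          repetitions = 3L, seed = 1L,
                                          num_trees = 200L)
  expect_equal(ranked_p$kmer[1], "CGCG")
})

test_that("top-m selection: identity case and grid behavior", {
  sf <- strong_features()
  ds <- strong_dataset()
  tab <- sf$kmers[, 1:32]  # small sub-table keeps the check fast
  ranked <- rank_kmers_by_rf_importance(tab, ds$labels, repetitions = 2L,
                                        seed = 7L, num_trees = 200L)
  sel1 <- select_top_kmers(ranked, tab, ds$labels, grid = 1L, folds = 5L,
                           repetitions = 1L, seed = 7L,
                           model_config = model_config("LR"))
  expect_equal(colnames(sel1$table), ranked$kmer[1])
  full <- select_top_kmers(ranked, tab, ds$labels, grid = ncol(tab),
                           folds = 5L, repetitions = 1L, seed = 7L,
                           model_config = model_config("LR"))
  expect_setequal(colnames(full$table), colnames(tab))
  expect_error(select_top_kmers(ranked, tab, ds$labels, grid = integer(0)),
               "empty")
  expect_error(select_top_kmers(ranked, tab, ds$labels, grid = 1000L),
               "exceeds")
})

test_that("selection does not underperform using every k-mer on planted data", {
  cfg <- simulation_config(n_pos = 150L, n_neg = 396L, n_unlabeled = 0L,
                           kmer_enrichment = 5, seed = 34L)
  labels <- simulate_expression(cfg)$labels
  seqs <- simulate_transcripts(cfg, labels)
  tab <- count_kmer_frequencies(seqs, c(3L, 4L))
  ranked <- rank_kmers_by_rf_importance(tab, labels, repetitions = 3L,
                                        seed = 8L, num_trees = 200L)
  grid <- c(5L, ncol(tab) - 1L)
  sel <- select_top_kmers(ranked, tab, labels, grid = grid, folds = 5L,
                          repetitions = 1L, seed = 8L,
                          model_config = model_config("LR"))
  aucs <- sel$auc_table$mean_roc_auc
  expect_gte(aucs[1], aucs[2] - 0.02)
})

test_that("Welch t-test matches the hand-computed statistic and handles degeneracy", {
  tab <- cbind(k1 = c(0.10, 0.12, 0.11, 0.20, 0.22, 0.21),
               k2 = rep(0.5, 6))
  rownames(tab) <- c("p1", "p2", "p3", "n1", "n2", "n3")
  labels <- list(positives = c("p1", "p2", "p3"),
                 negatives = c("n1", "n2", "n3"))
  res <- welch_ttest_kmers(tab, labels)

  # independent Welch oracle by direct formula
  x <- c(0.10, 0.12, 0.11); y <- c(0.20, 0.22, 0.21)
  se2x <- var(x) / 3; se2y <- var(y) / 3
  t_hand <- (mean(x) - mean(y)) / sqrt(se2x + se2y)
  df_hand <- (se2x + se2y)^2 / (se2x^2 / 2 + se2y^2 / 2)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  r1 <- res[res$kmer == "k1", ]
  expect_equal(r1$t, t_hand, tolerance = 1e-9)
  expect_equal(r1$df, df_hand, tolerance = 1e-9)
  expect_equal(r1$p, p_hand, tolerance = 1e-9)
  expect_true(r1$significant)

  r2 <- res[res$kmer == "k2", ]
  expect_true(r2$degenerate)
  expect_equal(r2$p, 1)
  expect_equal(r2$t, 0)
})

test_that("planted enrichment is significant at the generator's strength", {
  cfg <- simulation_config(n_pos = 500L, n_neg = 500L, n_unlabeled = 0L,
                           informative_kmers = "CGCG", kmer_enrichment = 5,
                           seed = 35L)
  labels <- simulate_expression(cfg)$labels
  seqs <- simulate_transcripts(cfg, labels)
  tab <- count_kmer_frequencies(seqs, 4L)
  res <- welch_ttest_kmers(tab, labels, kmers = "CGCG")
  expect_true(res$significant)
  expect_lt(res$p, 1e-6)
})
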