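# A toy annotation with a single chromosome of evenly spaced genes.
toy_annotation <- function(n, chrom = "chr1", prefix = "g") {
  data.frame(gene_id = sprintf("%s%04d", prefix, seq_len(n)),
             gene_symbol = sprintf("%s%04d", toupper(prefix), seq_len(n)),
             chromosome = chrom,
             start = seq_len(n) * 10000L,
             end = seq_len(n) * 10000L + 500L,
             strand = rep(c("+", "-"), length.out = n),
             biotype = "protein_coding", stringsAsFactors = FALSE)
}

test_that("hypothetical locus windows: exact fit, boundary extension, exhaustion", {
  ann <- toy_annotation(101L)
  loc <- build_hypothetical_locus("g0051", ann, N = 101L)
  expect_equal(loc$members, ann$gene_id)
  expect_equal(loc$N_actual, 101L)

  ann300 <- toy_annotation(300L)
  loc1 <- build_hypothetical_locus("g0001", ann300, N = 101L)
  expect_equal(loc1$members, ann300$gene_id[1:101])
  expect_equal(loc1$N_actual, 101L)
  loc_end <- build_hypothetical_locus("g0300", ann300, N = 101L)
  expect_equal(loc_end$members, ann300$gene_id[200:300])

  ann40 <- toy_annotation(40L)
  loc40 <- build_hypothetical_locus("g0020", ann40, N = 101L)
  expect_equal(loc40$N_actual, 40L)
  expect_setequal(loc40$members, ann40$gene_id)

  expect_error(build_hypothetical_locus("missing", ann, N = 101L), "missing")
  expect_error(build_hypothetical_locus("g0001", ann, N = 100L), "odd")
})

test_that("percentile rank follows L/N with strict tie handling", {
  ann <- toy_annotation(101L)
  loc <- build_hypothetical_locus("g0051", ann, N = 101L)
  p <- setNames(seq(0.001, 0.95, length.out = 101L), loc$members)

  p_top <- p; p_top["g0051"] <- 0.99
  r <- percentile_rank(loc, p_top)
  expect_equal(r$L, 100L)
  expect_equal(r$percentile, 100 / 101 * 100, tolerance = 1e-12)

  p_bot <- p; p_bot["g0051"] <- 0
  expect_equal(percentile_rank(loc, p_bot)$percentile, 0)

  # ties do not count toward L
  p_tie <- setNames(rep(0.5, 101L), loc$members)
  expect_equal(percentile_rank(loc, p_tie)$L, 0L)

  # sort-and-count oracle on random loci
  set.seed(71)
  for (i in 1:100) {
    probs <- setNames(runif(101), loc$members)
    r <- percentile_rank(loc, probs)
    oracle_L <- sum(sort(probs[names(probs) != "g0051"]) < probs["g0051"])
    expect_equal(r$L, oracle_L)
    expect_equal(r$percentile, oracle_L / 101 * 100, tolerance = 1e-12)
  }
})

test_that("percentile rank invariances", {
  ann <- toy_annotation(51L)
  loc <- build_hypothetical_locus("g0026", ann, N = 51L)
  set.seed(72)
  probs <- setNames(runif(51), loc$members)
  base <- percentile_rank(loc, probs)
  # strictly monotone transform leaves the rank unchanged
  expect_equal(percentile_rank(loc, probs^3)$percentile, base$percentile)
  expect_equal(percentile_rank(loc, log(probs + 1))$percentile,
               base$percentile)
  # adding a member scored below the target increases L by exactly 1
  ann2 <- rbind(ann, data.frame(gene_id = "g9999", gene_symbol = "G9999",
                                chromosome = "chr1", start = 5L, end = 100L,
                                strand = "+", biotype = "protein_coding"))
  loc2 <- build_hypothetical_locus("g0026", ann2, N = 53L)
  probs2 <- c(probs, g9999 = min(probs) / 2)
  loc2$members <- intersect(loc2$members, names(probs2))
  loc2$N_actual <- length(loc2$members)
  r2 <- percentile_rank(loc2, probs2)
  expect_equal(r2$L, base$L + 1L)
})

test_that("a random ranker centers near 50 and planted signal ranks high", {
  # expected percentile of a random ranker is (N-1)/(2N) * 100
  ann <- toy_annotation(41L)
  loc <- build_hypothetical_locus("g0021", ann, N = 41L)
  set.seed(73)
  ranks <- replicate(2000, {
    percentile_rank(loc, setNames(runif(41), loc$members))$percentile
  })
  expect_lt(abs(mean(ranks) - (40 / 82) * 100), 1.5)

  hist20 <- percentile_histogram(ranks, bins = 20L)
  expect_equal(sum(hist20$counts), 2000L)
  expect_equal(hist20$uniform_reference, 100)
  chi <- sum((hist20$counts - 100)^2 / 100)
  expect_lt(chi, qchisq(0.999, df = 19))

  all99 <- percentile_histogram(rep(99, 7), bins = 20L)
  expect_equal(unname(all99$counts[20]), 7L)
  expect_equal(sum(all99$counts), 7L)
})

test_that("leave-one-out validation ranks planted positives high, permuted labels near 50", {
  sf <- strong_features()
  ds <- strong_dataset()
  # subset of targets keeps the unit test fast; the full-preset protocol is
  # exercised in the acceptance suite
  labels_small <- list(positives = ds$labels$positives[1:25],
                       negatives = ds$labels$negatives)
  rep <- leave_one_out_validate(sf$features, labels_small, ds$annotation,
                                model_config("LR"), N_list = 41L, seed = 4L)
  expect_equal(nrow(rep$results), 25L)
  expect_true(all(rep$results$L < rep$results$N_actual))
  expect_gte(rep$summary$mean_percentile, 80)

  # monotone in the planted effect size
  mean_pct <- vapply(c(0, 3), function(eff) {
    cfg <- simulation_config(n_pos = 40L, n_neg = 106L, n_unlabeled = 0L,
                             n_samples = 30L, n_signal_samples = 15L,
                             expr_effect = eff, kmer_enrichment = 0,
                             genes_per_chromosome = 30L, seed = 74L)
    sim <- simulate_expression(cfg)
    lg <- log_transform(sim$expression)
    ann <- simulate_annotation(cfg, sim$labels)
    r <- leave_one_out_validate(lg$values, sim$labels, ann,
                                model_config("LR"), N_list = 21L, seed = 6L)
    r$summary$mean_percentile
  }, numeric(1))
  expect_gt(mean_pct[2], mean_pct[1])
  expect_gt(mean_pct[2], 80)
  expect_lt(abs(mean_pct[1] - 50), 15)
})
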