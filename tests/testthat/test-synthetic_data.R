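test_that("config validation catches inconsistent settings", {
  expect_error(simulation_config(n_signal_samples = 100L, n_samples = 60L),
               "n_signal_samples")
  expect_error(simulation_config(informative_kmers = character(0),
                                 kmer_enrichment = 5), "non-empty")
  expect_error(simulation_config(informative_kmers = "ACGTG"), "3- or 4-mers")
  expect_error(simulation_config(antisense_fraction = 1.5), "antisense_fraction")
})

test_that("label ratio and determinism of the expression simulator", {
  cfg <- simulation_config(seed = 11L)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$expression$values, b$expression$values)
  expect_length(a$labels$positives, cfg$n_pos)
  expect_length(a$labels$negatives, cfg$n_neg)
  expect_true(all(a$expression$values >= 0))
})

test_that("planted expression effect is recovered at the generating value", {
  # pooled class-mean difference of log2 values in signal columns ~ expr_effect
  cfg <- simulation_config(n_pos = 200L, n_neg = 200L, n_unlabeled = 0L,
                           expr_effect = 2.0, expr_noise_sd = 0.5, seed = 12L)
  sim <- simulate_expression(cfg)
  lg <- log_transform(sim$expression)$values
  sig <- seq_len(cfg$n_signal_samples)
  d_pos <- lg[sim$labels$positives, sig]
  d_neg <- lg[sim$labels$negatives, sig]
  diff <- mean(d_pos) - mean(d_neg)
  se <- sqrt(var(as.numeric(d_pos)) / length(d_pos) +
               var(as.numeric(d_neg)) / length(d_neg))
  expect_lt(abs(diff - 2.0), 3 * se + 0.02)  # +log2(RPKM+1) clipping bias slack

  cfg0 <- simulation_config(n_pos = 200L, n_neg = 200L, n_unlabeled = 0L,
                            expr_effect = 0, seed = 13L)
  sim0 <- simulate_expression(cfg0)
  lg0 <- log_transform(sim0$expression)$values
  diff0 <- mean(lg0[sim0$labels$positives, sig]) -
    mean(lg0[sim0$labels$negatives, sig])
  se0 <- sqrt(2 * var(as.numeric(lg0[, sig])) / (200 * cfg0$n_signal_samples))
  expect_lt(abs(diff0), 3 * se0)
})

test_that("transcript simulator plants detectable k-mer enrichment", {
  cfg <- simulation_config(n_pos = 500L, n_neg = 500L, n_unlabeled = 0L,
                           informative_kmers = "CGCG", kmer_enrichment = 5,
                           seed = 14L)
  labels <- simulate_expression(cfg)$labels
  seqs <- simulate_transcripts(cfg, labels)
  expect_true(all(nchar(seqs) >= cfg$seq_len_range[1]))
  expect_true(all(nchar(seqs) <= cfg$seq_len_range[2]))
  freq <- count_kmer_frequencies(seqs, 4L)[, "CGCG"]
  tt <- t.test(freq[labels$positives], freq[labels$negatives])
  expect_gt(mean(freq[labels$positives]), mean(freq[labels$negatives]))
  expect_lt(tt$p.value, 1e-6)

  # no enrichment -> no class difference
  cfg0 <- simulation_config(n_pos = 500L, n_neg = 500L, n_unlabeled = 0L,
                            kmer_enrichment = 0, seed = 15L)
  seqs0 <- simulate_transcripts(cfg0, labels)
  freq0 <- count_kmer_frequencies(seqs0, 4L)[, "CGCG"]
  tt0 <- t.test(freq0[labels$positives], freq0[labels$negatives])
  expect_gt(tt0$p.value, 0.001)
})

test_that("annotation layout: chromosomes, interspersion and antisense overlaps", {
  cfg <- simulation_config(n_pos = 40L, n_neg = 100L, n_unlabeled = 100L,
                           genes_per_chromosome = 40L,
                           antisense_fraction = 0.1, seed = 16L)
  labels <- simulate_expression(cfg)$labels
  ann <- simulate_annotation(cfg, labels)
  expect_equal(nrow(ann), 240L)

  # brute-force interval intersection against positive genes
  pos_ann <- ann[ann$gene_id %in% labels$positives, ]
  lnc_ann <- ann[ann$biotype == "lncRNA", ]
  n_overlap <- 0L
  for (i in seq_len(nrow(lnc_ann))) {
    hit <- pos_ann$chromosome == lnc_ann$chromosome[i] &
      pos_ann$start <= lnc_ann$end[i] & pos_ann$end >= lnc_ann$start[i] &
      pos_ann$strand != lnc_ann$strand[i]
    if (any(hit)) n_overlap <- n_overlap + 1L
  }
  expect_equal(n_overlap, 10L)

  # with no antisense fraction, no two records overlap and chromosomes are full
  cfg0 <- simulation_config(n_pos = 40L, n_neg = 100L, n_unlabeled = 100L,
                            genes_per_chromosome = 40L,
                            antisense_fraction = 0, seed = 17L)
  ann0 <- simulate_annotation(cfg0, labels)
  expect_equal(as.vector(table(ann0$chromosome)[paste0("chr", 1:6)]),
               rep(40L, 6L))
  by_chr <- split(ann0, ann0$chromosome)
  overlaps <- vapply(by_chr, function(d) {
    d <- d[order(d$start), ]
    any(d$start[-1] <= d$end[-nrow(d)])
  }, logical(1))
  expect_false(any(overlaps))
})

test_that("dataset bundle writes consistent, reproducible files", {
  cfg <- simulation_config(n_pos = 20L, n_neg = 53L, n_unlabeled = 10L,
                           genes_per_chromosome = 20L, seed = 18L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  for (f in c("expression.tsv", "transcripts.fa", "annotation.tsv",
              "positives.txt", "negatives.txt", "manifest.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), label = f)
  }
  # cross-file gene-id consistency through the io_formats readers
  expr <- read_expression_table(file.path(d1, "expression.tsv"))
  seqs <- read_fasta(file.path(d1, "transcripts.fa"))
  ann <- read_annotation(file.path(d1, "annotation.tsv"))
  lab <- read_labels(file.path(d1, "positives.txt"),
                     file.path(d1, "negatives.txt"))
  expect_setequal(gene_ids(expr), names(seqs))
  expect_setequal(gene_ids(expr), ann$gene_id)
  expect_true(all(c(lab$positives, lab$negatives) %in% gene_ids(expr)))
})
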