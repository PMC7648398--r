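# Shared fixtures, generated once per test run and cached. The "strong"
# dataset is the default synthetic preset (150/396 labeled genes, 60 samples,
# five planted k-mers at 5x enrichment, expression effect 2.0 on the log2
# scale).

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (!exists(key, envir = .fixtures)) assign(key, fn(), envir = .fixtures)
  get(key, envir = .fixtures)
}

strong_dataset <- function() {
  memo("strong", function() {
    cfg <- simulation_config(seed = 1L)
    expr <- simulate_expression(cfg)
    list(config = cfg,
         expression = expr$expression,
         labels = expr$labels,
         transcripts = simulate_transcripts(cfg, expr$labels),
         annotation = simulate_annotation(cfg, expr$labels))
  })
}

# Combined feature table for the strong dataset: 16 autoencoder codes over
# the log2 expression matrix plus the 25 top-ranked k-mers.
strong_features <- function() {
  memo("strong_features", function() {
    ds <- strong_dataset()
    lg <- log_transform(ds$expression)
    ae <- train_autoencoder(lg, autoencoder_spec(ncol(lg$values), 16L, seed = 5L))
    codes <- encode(ae, lg)
    kmers <- count_kmer_frequencies(ds$transcripts, c(3L, 4L))
    ranked <- rank_kmers_by_rf_importance(kmers, ds$labels,
                                          repetitions = 3L, seed = 5L)
    sel <- kmers[, ranked$kmer[1:25], drop = FALSE]
    list(features = cbind(codes, sel[rownames(codes), , drop = FALSE]),
         kmers = kmers, ranked = ranked)
  })
}

# Tiny linearly separable two-feature set.
separable_toy <- function(n_per_class = 20L) {
  set.seed(42)
  X <- rbind(cbind(rnorm(n_per_class, 3, 0.2), rnorm(n_per_class, 3, 0.2)),
             cbind(rnorm(n_per_class, -3, 0.2), rnorm(n_per_class, -3, 0.2)))
  rownames(X) <- c(sprintf("p%02d", seq_len(n_per_class)),
                   sprintf("n%02d", seq_len(n_per_class)))
  colnames(X) <- c("f1", "f2")
  list(features = X,
       labels = list(positives = rownames(X)[seq_len(n_per_class)],
                     negatives = rownames(X)[-seq_len(n_per_class)]))
}

# Independent Mann-Whitney AUC oracle: pairwise comparisons, ties count 1/2.
mann_whitney_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
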