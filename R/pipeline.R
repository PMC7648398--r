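# End-to-end pipeline: simulate or load the four inputs, build the
# expression-code and k-mer feature blocks, train the three class-weighted
# classifiers, run repeated cross-validation, the hypothetical-locus
# validation and the candidate prioritization, and write every artifact to a
# run directory with a manifest.

#' Assemble a run configuration
#'
#' Either `simulation` is set (a [simulation_config()]) or the four input
#' paths are; stage parameters default to the reduced-scale presets that run
#' in minutes on one CPU (the full-scale values are noted per parameter).
#'
#' @param simulation A [simulation_config()], or NULL to load real inputs.
#' @param expression_path,fasta_path,annotation_path Input paths (real mode).
#' @param positives_path,negatives_path Label list paths (real mode).
#' @param code_dim Autoencoder code size (full-scale choice: 48). Ignored
#'   when `code_grid` is given, in which case the size is selected by
#'   repeated CV over the grid.
#' @param code_grid Optional integer vector of candidate code sizes.
#' @param ae_epochs,ae_batch_size Autoencoder training protocol (100 / 64).
#' @param ks K-mer lengths (final choice c(3, 4), a 320-feature space).
#' @param top_m Number of top-ranked k-mers to keep (full-scale choice: 25).
#'   Ignored when `kmer_grid` is given.
#' @param kmer_grid Optional grid of candidate top-m values (full-scale
#'   protocol: 10..50 by 5).
#' @param rf_repetitions Forest refits averaged for the importance ranking
#'   (10).
#' @param algorithms Which classifiers to train.
#' @param folds,repetitions Cross-validation geometry (full scale: 10 / 50).
#' @param N_list Hypothetical-locus sizes (full scale: 101, 201, 401; the
#'   synthetic preset uses 41 so loci fit the 50-gene chromosomes).
#' @param locus_algorithm Classifier refit per leave-one-out target.
#' @param threshold Candidate call threshold (0.5).
#' @param pcc_threshold Co-expression threshold (0.95).
#' @param seed Single seed driving every random draw of the run.
#' @param out_dir Output directory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(simulation = simulation_config(),
                       expression_path = NULL, fasta_path = NULL,
                       annotation_path = NULL, positives_path = NULL,
                       negatives_path = NULL,
                       code_dim = 16L, code_grid = NULL,
                       ae_epochs = 100L, ae_batch_size = 64L,
                       ks = c(3L, 4L), top_m = 25L, kmer_grid = NULL,
                       rf_repetitions = 10L,
                       algorithms = c("LR", "SVM", "RF"),
                       folds = 10L, repetitions = 3L,
                       N_list = 41L, locus_algorithm = "LR",
                       threshold = 0.5, pcc_threshold = 0.95,
                       seed = 1L, out_dir = tempfile("lncprior_run_")) {
  algorithms <- match.arg(algorithms, c("LR", "SVM", "RF"),
                          several.ok = TRUE)
  if (is.null(simulation)) {
    paths <- c(expression_path, fasta_path, annotation_path,
               positives_path, negatives_path)
    if (length(paths) != 5L)
      stop("real mode needs all five input paths")
    absent <- paths[!file.exists(paths)]
    if (length(absent) > 0L)
      stop("input file(s) not found: ", paste(absent, collapse = ", "))
  }
  structure(list(simulation = simulation,
                 expression_path = expression_path, fasta_path = fasta_path,
                 annotation_path = annotation_path,
                 positives_path = positives_path,
                 negatives_path = negatives_path,
                 code_dim = as.integer(code_dim), code_grid = code_grid,
                 ae_epochs = as.integer(ae_epochs),
                 ae_batch_size = as.integer(ae_batch_size),
                 ks = as.integer(ks), top_m = as.integer(top_m),
                 kmer_grid = kmer_grid,
                 rf_repetitions = as.integer(rf_repetitions),
                 algorithms = algorithms, folds = as.integer(folds),
                 repetitions = as.integer(repetitions),
                 N_list = as.integer(N_list),
                 locus_algorithm = locus_algorithm,
                 threshold = threshold, pcc_threshold = pcc_threshold,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; a `simulation` block
#' mirrors [simulation_config()] fields (set `simulation: ~` for real mode).
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation))
    y$simulation <- do.call(simulation_config, y$simulation)
  do.call(run_config, y)
}

#' Run the full pipeline
#'
#' Simulate/load -> log2 transform -> autoencoder encode -> k-mer featurize
#' and select -> concatenate (codes first, then k-mers) -> train the
#' class-weighted models -> repeated stratified CV -> leave-one-out locus
#' validation -> candidate prioritization with co-expression and overlap
#' annotation. All artifacts are written to `config$out_dir` together with
#' `manifest.json` recording the seed and a hash of the configuration;
#' rerunning with an identical configuration reproduces the outputs
#' byte-identically.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the features, models, reports and
#'   candidate table.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # -- inputs -----------------------------------------------------------------
  if (!is.null(config$simulation)) {
    say("simulating dataset (seed ", config$simulation$seed, ")")
    sim <- simulate_dataset(config$simulation,
                            file.path(config$out_dir, "inputs"))
    expr_raw <- sim$expression; seqs <- sim$transcripts
    annotation <- sim$annotation; labels <- sim$labels
  } else {
    say("loading inputs")
    expr_raw <- read_expression_table(config$expression_path)
    seqs <- read_fasta(config$fasta_path)
    annotation <- read_annotation(config$annotation_path)
    labels <- read_labels(config$positives_path, config$negatives_path)
  }
  shared <- Reduce(intersect, list(gene_ids(expr_raw), names(seqs),
                                   annotation$gene_id))
  dropped <- length(gene_ids(expr_raw)) - length(shared)
  if (dropped > 0L)
    say(dropped, " gene(s) lacking expression, sequence or annotation dropped")
  expr_raw$values <- expr_raw$values[shared, , drop = FALSE]
  seqs <- seqs[shared]
  labels <- list(positives = intersect(labels$positives, shared),
                 negatives = intersect(labels$negatives, shared))

  # -- expression features ----------------------------------------------------
  expr_log <- log_transform(expr_raw)
  if (!is.null(config$code_grid)) {
    sel <- select_code_dimension(expr_log, labels, config$code_grid,
                                 folds = config$folds,
                                 repetitions = config$repetitions,
                                 ae_epochs = config$ae_epochs,
                                 ae_batch_size = config$ae_batch_size,
                                 seed = derive_seed(config$seed, 41L))
    code_dim <- sel$code_dim
    say("selected code_dim ", code_dim, " from grid")
  } else {
    code_dim <- config$code_dim
  }
  ae <- train_autoencoder(expr_log,
                          autoencoder_spec(ncol(expr_log$values), code_dim,
                                           epochs = config$ae_epochs,
                                           batch_size = config$ae_batch_size,
                                           seed = derive_seed(config$seed, 43L)))
  codes <- encode(ae, expr_log)
  say("autoencoder trained: ", code_dim, " codes, final MSE ",
      signif(utils::tail(ae$loss_trace, 1L), 4))

  # -- sequence features ------------------------------------------------------
  kmers <- count_kmer_frequencies(seqs, config$ks)
  ranked <- rank_kmers_by_rf_importance(kmers, labels,
                                        repetitions = config$rf_repetitions,
                                        seed = derive_seed(config$seed, 47L))
  if (!is.null(config$kmer_grid)) {
    ksel <- select_top_kmers(ranked, kmers, labels, grid = config$kmer_grid,
                             folds = config$folds,
                             repetitions = config$repetitions,
                             seed = derive_seed(config$seed, 53L))
    top_m <- ksel$top_m
    kmers_sel <- ksel$table
  } else {
    top_m <- config$top_m
    kmers_sel <- kmers[, ranked$kmer[seq_len(top_m)], drop = FALSE]
  }
  say("selected ", top_m, " k-mers")

  # -- combined features and models -------------------------------------------
  features <- cbind(codes, kmers_sel[rownames(codes), , drop = FALSE])
  weights <- make_class_weights(labels)
  say("class weights neg:pos = 1:", weights$w_pos_reported)
  models <- lapply(stats::setNames(config$algorithms, config$algorithms),
    function(a) train_model(features, labels,
                            model_config(a, seed = derive_seed(config$seed, 59L))))

  # -- evaluation -------------------------------------------------------------
  cv <- lapply(stats::setNames(config$algorithms, config$algorithms),
    function(a) repeated_cv(features, labels,
                            model_config(a, seed = derive_seed(config$seed, 61L)),
                            k = config$folds,
                            repetitions = config$repetitions,
                            seed = derive_seed(config$seed, 67L),
                            threshold = config$threshold))
  for (a in config$algorithms)
    say(a, " CV ROC AUC ", round(cv[[a]]$aggregate["roc_auc", "mean"], 4))

  # -- locus validation -------------------------------------------------------
  loci <- leave_one_out_validate(features, labels, annotation,
                                 model_config(config$locus_algorithm,
                                              seed = derive_seed(config$seed, 71L)),
                                 N_list = config$N_list,
                                 seed = derive_seed(config$seed, 73L))
  say("mean percentile rank: ",
      paste(sprintf("N=%d: %.1f", loci$summary$N, loci$summary$mean_percentile),
            collapse = ", "))

  # -- prioritization ---------------------------------------------------------
  candidates <- annotation$gene_id[annotation$biotype == "lncRNA"]
  candidates <- intersect(candidates,
                          setdiff(rownames(features),
                                  c(labels$positives, labels$negatives)))
  cand_table <- NULL
  if (length(candidates) > 0L && all(c("LR", "SVM", "RF") %in% names(models))) {
    cand_table <- prioritize_candidates(models,
                                        features[candidates, , drop = FALSE],
                                        threshold = config$threshold)
    overlap <- annotate_genomic_overlap(cand_table$gene_id, labels$positives,
                                        annotation)
    cand_table$overlap_annotation <- unname(overlap[cand_table$gene_id])
    called <- cand_table$gene_id[cand_table$n_models >= 1L]
    partners <- if (length(called) > 0L)
      coexpression_partners(called, expr_log, annotation,
                            config$pcc_threshold) else list()
    cand_table$coexpressed_partners <- vapply(cand_table$gene_id, function(g)
      if (g %in% names(partners) && nrow(partners[[g]]) > 0L)
        paste(sprintf("%s(%.3f)", partners[[g]]$partner, partners[[g]]$pcc),
              collapse = ";") else "", character(1))
    sm <- summarize_calls(cand_table)
    say(sm$n_any, " (", sm$pct_any, "%) of ", sm$n_candidates,
        " candidates called by at least one model; ", sm$n_consensus,
        " by all three")
  }

  # -- outputs ----------------------------------------------------------------
  write_run_outputs(config, features, cv, loci, cand_table, weights,
                    code_dim, top_m, ranked)
  invisible(list(config = config, labels = labels, annotation = annotation,
                 expression = expr_log, autoencoder = ae, features = features,
                 ranked_kmers = ranked, models = models, cv = cv,
                 loci = loci, candidates = cand_table))
}

write_run_outputs <- function(config, features, cv, loci, cand_table,
                              weights, code_dim, top_m, ranked) {
  out <- config$out_dir
  utils::write.table(data.frame(gene_id = rownames(features), features,
                                check.names = FALSE),
                     file.path(out, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ranked, file.path(out, "kmer_importance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cv_out <- lapply(cv, function(x)
    list(mean = as.list(x$aggregate[, "mean"]),
         sd = as.list(x$aggregate[, "sd"])))
  jsonlite::write_json(cv_out, file.path(out, "cv_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  utils::write.table(loci$results, file.path(out, "loci_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cand_table))
    utils::write.table(cand_table, file.path(out, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  cfg_plain <- unclass(config)
  if (!is.null(cfg_plain$simulation))
    cfg_plain$simulation <- unclass(cfg_plain$simulation)
  # config.json captures the scientific parameters only; file-system
  # locations vary between runs and would break the config hash
  cfg_plain <- cfg_plain[setdiff(names(cfg_plain),
                                 c("out_dir", "expression_path", "fasta_path",
                                   "annotation_path", "positives_path",
                                   "negatives_path"))]
  cfg_path <- file.path(out, "config.json")
  jsonlite::write_json(cfg_plain[!vapply(cfg_plain, is.null, logical(1))],
                       cfg_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest <- list(seed = config$seed,
                   config_hash = unname(tools::md5sum(cfg_path)),
                   code_dim = code_dim, top_m = top_m,
                   class_weight_pos = weights$w_pos_reported,
                   folds = config$folds, repetitions = config$repetitions,
                   N_list = config$N_list, threshold = config$threshold)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out)
}
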