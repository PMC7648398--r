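# Sequence feature block: length-normalized k-mer frequencies and the
# random-forest importance ranking used to select the informative subset.

all_kmer_names <- function(ks) {
  unlist(lapply(sort(unique(as.integer(ks))), function(k)
    Biostrings::mkAllStrings(c("A", "C", "G", "T"), width = k)))
}

#' Count length-normalized k-mer frequencies
#'
#' For each transcript and each k-mer w of length k, the feature is
#' count(w as overlapping substring) / L with L the full sequence length
#' (not the window count L - k + 1). Windows containing N are skipped from
#' the numerator while L keeps its full value. Columns are ordered
#' lexicographically within each k, with the k values ascending; for
#' ks = \{3, 4\} this yields the 320-dimensional (4^3 + 4^4) feature space.
#'
#' @param seqs Named character vector of sequences over `{A,C,G,T,N}` (a
#'   transcript set from [read_fasta()] or [simulate_transcripts()]).
#' @param ks Integer vector of k values, each in 1..4.
#' @return Gene x k-mer numeric matrix. Sequences shorter than `max(ks)` are
#'   excluded with a warning.
#' @export
count_kmer_frequencies <- function(seqs, ks = c(3L, 4L)) {
  ks <- sort(unique(as.integer(ks)))
  if (length(ks) == 0L || any(ks < 1L) || any(ks > 4L))
    stop("ks must be a non-empty subset of 1..4")
  if (is.null(names(seqs))) stop("sequences must be named by gene id")
  too_short <- nchar(seqs) < max(ks)
  if (any(too_short)) {
    warning(sum(too_short), " sequence(s) shorter than ", max(ks),
            " nt excluded: ",
            paste(utils::head(names(seqs)[too_short], 5), collapse = ", "))
    seqs <- seqs[!too_short]
  }
  if (length(seqs) == 0L) stop("no sequences left after length filtering")
  set <- Biostrings::DNAStringSet(seqs)
  L <- Biostrings::width(set)
  blocks <- lapply(ks, function(k) {
    counts <- Biostrings::oligonucleotideFrequency(set, width = k)
    counts / L
  })
  out <- do.call(cbind, blocks)
  rownames(out) <- names(seqs)
  out
}

#' Rank k-mers by averaged random-forest importance
#'
#' Trains the class-weighted random-forest classifier `repetitions` times
#' with distinct sub-seeds on min-max-scaled frequencies; per-fit
#' impurity-based importances are normalized to sum to 1, averaged across
#' repetitions, and sorted descending (ties broken by lexicographic k-mer
#' order). Deterministic given `seed`.
#'
#' @param table Gene x k-mer frequency matrix covering all labeled genes.
#' @param labels Label set.
#' @param repetitions Number of forest refits to average over (default 10).
#' @param seed Integer seed.
#' @param num_trees Trees per forest.
#' @param importance_type `"impurity"` (default) or `"permutation"`.
#' @return data.frame with columns `kmer`, `mean_importance`, `rank`.
#' @export
rank_kmers_by_rf_importance <- function(table, labels, repetitions = 10L,
                                        seed = 1L, num_trees = 500L,
                                        importance_type = c("impurity",
                                                            "permutation")) {
  importance_type <- match.arg(importance_type)
  assert_label_set(labels)
  if (repetitions < 1L) stop("repetitions must be >= 1")
  y <- label_vector(rownames(table), labels)
  keep <- !is.na(y)
  if (sum(y[keep] == 1L) == 0L || sum(y[keep] == 0L) == 0L)
    stop("both classes must be present among the table rows")
  X <- minmax_normalize(table[keep, , drop = FALSE])$values
  yf <- factor(ifelse(y[keep] == 1L, "pos", "neg"), levels = c("neg", "pos"))
  w <- make_class_weights(labels)
  case_w <- ifelse(yf == "pos", w[["w_pos"]], w[["w_neg"]])
  dat <- data.frame(X, check.names = FALSE)
  dat$.class <- yf
  imp_sum <- numeric(ncol(X))
  for (r in seq_len(repetitions)) {
    fit <- ranger::ranger(
      dependent.variable.name = ".class", data = dat,
      num.trees = num_trees, importance = importance_type,
      case.weights = case_w, seed = derive_seed(seed, r),
      num.threads = 1L)
    imp <- fit$variable.importance[colnames(X)]
    tot <- sum(imp)
    if (tot > 0) imp <- imp / tot
    imp_sum <- imp_sum + imp
  }
  mean_imp <- imp_sum / repetitions
  ord <- order(-mean_imp, colnames(X))
  data.frame(kmer = colnames(X)[ord], mean_importance = unname(mean_imp[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Select the best top-m k-mer subset by repeated cross-validation
#'
#' For each m in the grid, evaluates repeated stratified cross-validation
#' mean ROC AUC on the top-m ranked columns and returns the best m (ties
#' broken toward the smaller subset) with the table restricted to those
#' columns. The full-scale protocol tests m = 10..50 in steps of 5.
#'
#' @param ranked Importance ranking from [rank_kmers_by_rf_importance()].
#' @param table Gene x k-mer frequency matrix.
#' @param labels Label set.
#' @param grid Integer vector of candidate m values.
#' @param model_config Classifier used for scoring (default class-weighted
#'   random forest, mirroring the ranking model).
#' @param folds,repetitions Cross-validation geometry.
#' @param seed Integer seed.
#' @return List with `top_m`, `table` (reduced columns, ranking order) and
#'   `auc_table`.
#' @export
select_top_kmers <- function(ranked, table, labels,
                             grid = seq(10L, 50L, by = 5L),
                             model_config = NULL, folds = 10L,
                             repetitions = 3L, seed = 1L) {
  if (length(grid) == 0L) stop("empty top-m grid")
  if (max(grid) > nrow(ranked))
    stop("grid maximum (", max(grid), ") exceeds the number of ranked k-mers (",
         nrow(ranked), ")")
  if (is.null(model_config))
    model_config <- model_config("RF", seed = derive_seed(seed, 201L))
  aucs <- vapply(grid, function(m) {
    cols <- ranked$kmer[seq_len(m)]
    rep <- repeated_cv(table[, cols, drop = FALSE], labels, model_config,
                       k = folds, repetitions = repetitions,
                       seed = derive_seed(seed, 2000L + m))
    rep$aggregate["roc_auc", "mean"]
  }, numeric(1))
  ord <- order(-aucs, grid)
  best <- grid[ord[1L]]
  list(top_m = best,
       table = table[, ranked$kmer[seq_len(best)], drop = FALSE],
       auc_table = data.frame(top_m = grid, mean_roc_auc = aucs))
}

#' Welch two-sample t-tests on k-mer frequencies between classes
#'
#' Two-sided unequal-variance t-test per k-mer on the raw frequencies, with
#' Welch-Satterthwaite degrees of freedom and no multiplicity correction.
#' K-mers with zero variance in both classes are flagged and reported with
#' p = 1.
#'
#' @param table Gene x k-mer frequency matrix.
#' @param labels Label set (>= 2 genes per class).
#' @param kmers K-mers to test (default all columns).
#' @param alpha Significance level (default 0.05).
#' @return data.frame with columns `kmer`, `t`, `df`, `p`, `significant`,
#'   `degenerate`.
#' @export
welch_ttest_kmers <- function(table, labels, kmers = colnames(table),
                              alpha = 0.05) {
  assert_label_set(labels)
  y <- label_vector(rownames(table), labels)
  pos <- table[!is.na(y) & y == 1L, kmers, drop = FALSE]
  neg <- table[!is.na(y) & y == 0L, kmers, drop = FALSE]
  if (nrow(pos) < 2L || nrow(neg) < 2L)
    stop("both classes need at least 2 genes for the Welch test")
  res <- lapply(kmers, function(w) {
    x <- pos[, w]; z <- neg[, w]
    if (stats::var(x) == 0 && stats::var(z) == 0) {
      data.frame(kmer = w, t = 0, df = NA_real_, p = 1,
                 significant = FALSE, degenerate = TRUE)
    } else {
      tt <- stats::t.test(x, z, var.equal = FALSE)
      data.frame(kmer = w, t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, significant = tt$p.value < alpha,
                 degenerate = FALSE)
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
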