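# Candidate prioritization: score unlabeled lncRNAs with the three trained
# models, form the per-model calls and the three-model consensus, and
# annotate candidates by co-expression and genomic overlap with risk genes.

#' Score and rank candidate lncRNAs with the three models
#'
#' Every candidate gets a probability from each model; it is called by a
#' model when its probability reaches the threshold, and is a consensus
#' candidate when all three models call it. Candidates are ranked by the
#' mean of the three probabilities (ties broken by gene id).
#'
#' @param models Named list with elements `LR`, `SVM` and `RF`, each a
#'   [train_model()] result.
#' @param candidate_features Gene x feature matrix for the candidates, in
#'   the models' shared feature space.
#' @param threshold Probability call threshold (default 0.5).
#' @return data.frame sorted by `mean_prob` descending with columns
#'   `gene_id`, `prob_LR`, `prob_SVM`, `prob_RF`, `called_by`
#'   (comma-separated), `n_models`, `consensus_all`, `mean_prob`.
#' @export
prioritize_candidates <- function(models, candidate_features,
                                  threshold = 0.5) {
  if (!all(c("LR", "SVM", "RF") %in% names(models)))
    stop("models must be a named list with elements LR, SVM and RF")
  probs <- vapply(c("LR", "SVM", "RF"), function(a)
    predict_proba(models[[a]], candidate_features),
    numeric(nrow(candidate_features)))
  if (nrow(candidate_features) == 1L)
    probs <- matrix(probs, nrow = 1L,
                    dimnames = list(rownames(candidate_features),
                                    c("LR", "SVM", "RF")))
  called <- probs >= threshold
  out <- data.frame(
    gene_id = rownames(candidate_features),
    prob_LR = probs[, "LR"], prob_SVM = probs[, "SVM"],
    prob_RF = probs[, "RF"],
    called_by = apply(called, 1L, function(z)
      paste(c("LR", "SVM", "RF")[z], collapse = ",")),
    n_models = rowSums(called),
    consensus_all = rowSums(called) == 3L,
    mean_prob = rowMeans(probs),
    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_prob, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize candidate calls as printed percentages
#'
#' @param result A [prioritize_candidates()] data.frame.
#' @return List with the counts called by at least one model and by all
#'   three, and the any-model share of all candidates as a 2-dp percentage.
#' @export
summarize_calls <- function(result) {
  n_any <- sum(result$n_models >= 1L)
  list(n_candidates = nrow(result), n_any = n_any,
       n_consensus = sum(result$consensus_all),
       pct_any = percent_of(n_any, nrow(result)))
}

#' Co-expressed protein-coding partners of candidate lncRNAs
#'
#' Pearson correlation between each candidate's and each protein-coding
#' gene's expression vector, computed on the log2 scale; partners exceeding
#' the threshold are reported. Pairs where either vector has zero variance
#' are skipped and flagged.
#'
#' @param candidates Character vector of candidate gene ids.
#' @param expression An [expression_matrix()]; raw RPKM input is
#'   log2-transformed internally.
#' @param annotation Annotation data.frame (defines the protein-coding set).
#' @param pcc_threshold Correlation threshold (default 0.95, strictly
#'   exceeded).
#' @return List per candidate of data.frames (`partner`, `pcc`), with the
#'   skipped zero-variance pairs in `attr(, "skipped")`.
#' @export
coexpression_partners <- function(candidates, expression, annotation,
                                  pcc_threshold = 0.95) {
  stopifnot(inherits(expression, "expr_matrix"))
  if (expression$transform_state == "rpkm")
    expression <- log_transform(expression)
  coding <- annotation$gene_id[annotation$biotype == "protein_coding"]
  coding <- intersect(coding, gene_ids(expression))
  missing <- setdiff(candidates, gene_ids(expression))
  if (length(missing) > 0L)
    stop("candidate(s) missing from the expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  X <- t(expression$values[candidates, , drop = FALSE])
  Y <- t(expression$values[coding, , drop = FALSE])
  var0_x <- apply(X, 2L, stats::var) == 0
  var0_y <- apply(Y, 2L, stats::var) == 0
  skipped <- character(0)
  pcc <- matrix(NA_real_, ncol(X), ncol(Y),
                dimnames = list(candidates, coding))
  ok_y <- !var0_y
  for (i in seq_len(ncol(X))) {
    if (var0_x[i]) {
      skipped <- c(skipped, candidates[i])
      next
    }
    if (any(ok_y))
      pcc[i, ok_y] <- as.numeric(stats::cor(X[, i], Y[, ok_y, drop = FALSE]))
  }
  out <- lapply(candidates, function(g) {
    v <- pcc[g, ]
    v <- v[!is.na(v) & names(v) != g & v > pcc_threshold]
    v <- sort(v, decreasing = TRUE)
    data.frame(partner = names(v), pcc = unname(v), stringsAsFactors = FALSE)
  })
  names(out) <- candidates
  attr(out, "skipped") <- unique(c(skipped, coding[var0_y]))
  out
}

#' Genomic-overlap annotation of candidates against risk genes
#'
#' A candidate is `same_locus` when its interval shares at least one base
#' with a risk gene's interval on the same chromosome (1-based inclusive
#' coordinates), `antisense` when additionally on the opposite strand, and
#' `none` otherwise.
#'
#' @param candidates Character vector of candidate gene ids.
#' @param risk_genes Character vector of risk gene ids.
#' @param annotation Annotation data.frame containing all the ids.
#' @return Named character vector over `{none, same_locus, antisense}`.
#' @export
annotate_genomic_overlap <- function(candidates, risk_genes, annotation) {
  missing <- setdiff(c(candidates, risk_genes), annotation$gene_id)
  if (length(missing) > 0L)
    stop("gene(s) missing from annotation: ",
         paste(utils::head(missing, 5), collapse = ", "))
  cand <- annotation[match(candidates, annotation$gene_id), , drop = FALSE]
  risk <- annotation[match(risk_genes, annotation$gene_id), , drop = FALSE]
  chroms <- unique(annotation$chromosome)
  gr_c <- annotation_granges(cand, seqlevels = chroms)
  gr_r <- annotation_granges(risk, seqlevels = chroms)
  hits <- GenomicRanges::findOverlaps(gr_c, gr_r, ignore.strand = TRUE)
  out <- stats::setNames(rep("none", length(candidates)), candidates)
  if (length(hits) > 0L) {
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    self <- cand$gene_id[qi] == risk$gene_id[si]
    qi <- qi[!self]; si <- si[!self]
    anti <- cand$strand[qi] != risk$strand[si]
    out[unique(qi)] <- "same_locus"
    out[unique(qi[anti])] <- "antisense"
  }
  out
}
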