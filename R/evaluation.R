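# Model evaluation: stratified k-fold splitting that preserves the class
# ratio per fold, the confusion-matrix metric suite (accuracy, sensitivity,
# specificity, precision, MCC), threshold-swept ROC and PR curves with their
# areas, and repeated cross-validation.

#' Stratified k-fold split preserving the class ratio
#'
#' Each class is shuffled independently with the seed and dealt round-robin
#' into k folds, so per-class fold sizes differ by at most 1 and every fold
#' keeps (to within one gene) the global positive:negative ratio.
#'
#' @param labels Label set; each class needs at least k members.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return List of k disjoint character vectors of gene ids whose union is
#'   the labeled set.
#' @export
stratified_kfold_split <- function(labels, k = 10L, seed = 1L) {
  assert_label_set(labels)
  if (k < 2L) stop("k must be >= 2")
  if (length(labels$positives) < k || length(labels$negatives) < k)
    stop("each class needs at least k = ", k, " members")
  set.seed(seed)
  pos <- sample(labels$positives)
  neg <- sample(labels$negatives)
  folds <- lapply(seq_len(k), function(i)
    c(pos[seq_along(pos) %% k == (i - 1L)],
      neg[seq_along(neg) %% k == (i - 1L)]))
  folds
}

#' Confusion-matrix metric suite
#'
#' Accuracy, sensitivity, specificity, precision and the Matthews
#' correlation coefficient from raw confusion counts. A metric whose
#' denominator is zero is reported as `NA` and flagged; an MCC with a zero
#' denominator is reported as 0 and flagged.
#'
#' @param tp,tn,fp,fn Non-negative integer confusion counts (total > 0).
#' @return List with the five metrics and a character vector `flags` naming
#'   any degenerate ones.
#' @export
compute_metrics <- function(tp, tn, fp, fn) {
  total <- tp + tn + fp + fn
  if (total <= 0) stop("confusion counts sum to zero")
  flags <- character(0)
  div <- function(num, den, name) {
    if (den == 0) { flags <<- c(flags, name); return(NA_real_) }
    num / den
  }
  accuracy <- (tp + tn) / total
  sensitivity <- div(tp, tp + fn, "sensitivity")
  specificity <- div(tn, tn + fp, "specificity")
  precision <- div(tp, tp + fp, "precision")
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) { flags <- c(flags, "mcc"); 0 }
         else (tp * tn - fp * fn) / mcc_den
  list(accuracy = accuracy, sensitivity = sensitivity,
       specificity = specificity, precision = precision, mcc = mcc,
       flags = flags)
}

# Shared threshold sweep: cumulative TP/FP at each unique score, scores
# descending, tied scores crossed simultaneously.
score_sweep <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  y <- as.integer(labels)
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary 0/1")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- y[ord]
  tp <- cumsum(y); fp <- cumsum(1L - y)
  last <- !duplicated(s, fromLast = TRUE)  # last index of each tie group
  data.frame(threshold = s[last], tp = tp[last], fp = fp[last])
}

#' ROC curve and area under it
#'
#' The true-positive rate is plotted against the false-positive rate over
#' all unique-score thresholds; ties cross a threshold simultaneously and
#' the area is computed by the trapezoidal rule (equivalently, the
#' Mann-Whitney probability with ties counted one half).
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Binary labels (1 = positive); both classes must be present.
#' @return List with `curve` (data.frame of fpr, tpr, threshold) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.integer(labels)
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute a ROC curve")
  sw <- score_sweep(scores, y)
  tpr <- c(0, sw$tp / n_pos)
  fpr <- c(0, sw$fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(curve = data.frame(fpr = fpr, tpr = tpr,
                          threshold = c(Inf, sw$threshold)),
       auc = auc)
}

#' Precision-recall curve and area under it
#'
#' Precision is plotted against recall over all unique-score thresholds
#' and the area uses the step-wise rule (right-continuous precision), the
#' standard convention for PR curves; the recall = 0 endpoint takes the
#' precision at the highest threshold. The random baseline of this area is
#' the positive-class prevalence, not 0.5.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels; positives must be present.
#' @return List with `curve` (recall, precision, threshold) and `auc`.
#' @export
pr_auc <- function(scores, labels) {
  y <- as.integer(labels)
  n_pos <- sum(y == 1L)
  if (n_pos == 0L) stop("positives must be present to compute a PR curve")
  sw <- score_sweep(scores, y)
  recall <- sw$tp / n_pos
  precision <- sw$tp / (sw$tp + sw$fp)
  auc <- sum(diff(c(0, recall)) * precision)
  list(curve = data.frame(recall = recall, precision = precision,
                          threshold = sw$threshold),
       auc = auc)
}

CV_METRICS <- c("accuracy", "sensitivity", "specificity", "precision",
                "mcc", "roc_auc", "pr_auc")

#' Repeated stratified k-fold cross-validation
#'
#' Each repetition draws a fresh stratified split; the model is trained on
#' k-1 folds (min-max scaling fit within the training folds) and the
#' held-out fold is evaluated with count metrics at the fixed probability
#' threshold 0.5 and with threshold-swept ROC/PR areas. Fold values are
#' averaged within a repetition, and the report gives mean and standard
#' deviation across repetitions (the full-scale protocol uses 10 folds and
#' 50 repetitions).
#'
#' @param features Gene x feature matrix covering all labeled genes.
#' @param labels Label set.
#' @param config A [model_config()].
#' @param k Folds per repetition.
#' @param repetitions Number of repetitions.
#' @param seed Integer seed; fold splits and fit seeds derive from it.
#' @param threshold Probability threshold for the count metrics.
#' @return List of class `cv_report`: `per_fold` (data.frame),
#'   `per_repetition` (data.frame of fold-averaged metrics), `aggregate`
#'   (metric x {mean, sd} matrix), plus the fold assignments and seeds.
#' @export
repeated_cv <- function(features, labels, config, k = 10L, repetitions = 3L,
                        seed = 1L, threshold = 0.5) {
  stopifnot(inherits(config, "model_config"))
  if (repetitions < 1L) stop("repetitions must be >= 1")
  per_fold <- list()
  fold_assignments <- list()
  for (r in seq_len(repetitions)) {
    split_seed <- derive_seed(seed, 10000L + r)
    folds <- stratified_kfold_split(labels, k, split_seed)
    fold_assignments[[r]] <- folds
    for (i in seq_len(k)) {
      test_ids <- folds[[i]]
      train_labels <- list(
        positives = setdiff(labels$positives, test_ids),
        negatives = setdiff(labels$negatives, test_ids))
      fit_cfg <- config
      fit_cfg$seed <- derive_seed(seed, 20000L + r * 100L + i)
      model <- train_model(features, train_labels, fit_cfg)
      p <- predict_proba(model, features[test_ids, , drop = FALSE])
      y <- as.integer(test_ids %in% labels$positives)
      pred <- as.integer(p >= threshold)
      m <- compute_metrics(tp = sum(pred == 1L & y == 1L),
                           tn = sum(pred == 0L & y == 0L),
                           fp = sum(pred == 1L & y == 0L),
                           fn = sum(pred == 0L & y == 1L))
      per_fold[[length(per_fold) + 1L]] <- data.frame(
        repetition = r, fold = i,
        accuracy = m$accuracy, sensitivity = m$sensitivity,
        specificity = m$specificity, precision = m$precision, mcc = m$mcc,
        roc_auc = roc_auc(p, y)$auc, pr_auc = pr_auc(p, y)$auc)
    }
  }
  per_fold <- do.call(rbind, per_fold)
  per_rep <- do.call(rbind, lapply(split(per_fold, per_fold$repetition),
    function(d) {
      out <- as.data.frame(lapply(d[CV_METRICS], mean, na.rm = TRUE))
      cbind(repetition = d$repetition[1L], out)
    }))
  rownames(per_rep) <- NULL
  agg <- cbind(mean = vapply(per_rep[CV_METRICS], mean, numeric(1)),
               sd = vapply(per_rep[CV_METRICS], stats::sd, numeric(1)))
  rownames(agg) <- CV_METRICS
  structure(list(per_fold = per_fold, per_repetition = per_rep,
                 aggregate = agg, fold_assignments = fold_assignments,
                 seed = seed, k = k, repetitions = repetitions,
                 threshold = threshold, algorithm = config$algorithm),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %s, %d-fold x %d repetitions (threshold %.2f)\n",
              x$algorithm, x$k, x$repetitions, x$threshold))
  print(round(x$aggregate, 4))
  invisible(x)
}
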