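# Hypothetical-locus validation: leave one known risk gene out of training,
# score the genes of a window centered on it along its chromosome, and record
# the percentile rank of the target (L/N x 100, L = members scored strictly
# below the target).

#' Build a hypothetical locus around a target gene
#'
#' Takes the (N-1)/2 nearest preceding and following genes by start
#' coordinate on the target's chromosome plus the target itself. Near a
#' chromosome end the short side contributes what it has and the window
#' extends on the other side until N members are reached or the chromosome
#' is exhausted (`N_actual <= N`).
#'
#' @param target Gene id present in the annotation.
#' @param annotation Annotation data.frame (as from [read_annotation()]).
#' @param N Odd nominal locus size (the full-scale protocol uses 101, 201,
#'   401).
#' @return List of class `hypothetical_locus` with `target_gene`, `members`
#'   (ordered gene ids, includes the target), `N` and `N_actual`.
#' @export
build_hypothetical_locus <- function(target, annotation, N = 101L) {
  if (N < 1L || N %% 2L == 0L) stop("N must be a positive odd integer")
  row <- annotation[annotation$gene_id == target, , drop = FALSE]
  if (nrow(row) == 0L) stop("target gene not in annotation: ", target)
  chrom <- annotation[annotation$chromosome == row$chromosome, , drop = FALSE]
  chrom <- chrom[order(chrom$start, chrom$gene_id), , drop = FALSE]
  i <- which(chrom$gene_id == target)
  n <- nrow(chrom)
  half <- (N - 1L) %/% 2L
  lo <- i - half
  hi <- i + half
  if (lo < 1L) { hi <- hi + (1L - lo); lo <- 1L }
  if (hi > n) { lo <- lo - (hi - n); hi <- n }
  lo <- max(lo, 1L)
  members <- chrom$gene_id[lo:hi]
  structure(list(target_gene = target, members = members, N = as.integer(N),
                 N_actual = length(members)),
            class = "hypothetical_locus")
}

#' Percentile rank of the target within a scored locus
#'
#' `L` counts the locus members with probability strictly less than the
#' target's (ties do not count toward `L`), and the percentile rank is
#' `L / N_actual * 100`.
#'
#' @param locus A `hypothetical_locus`.
#' @param probabilities Named numeric vector covering all locus members.
#' @return List with `target_gene`, `N_actual`, `L` and `percentile`.
#' @export
percentile_rank <- function(locus, probabilities) {
  stopifnot(inherits(locus, "hypothetical_locus"))
  missing <- setdiff(locus$members, names(probabilities))
  if (length(missing) > 0L)
    stop("probabilities missing for locus member(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  p <- probabilities[locus$members]
  p_target <- p[[locus$target_gene]]
  L <- sum(p < p_target)
  list(target_gene = locus$target_gene, N_actual = locus$N_actual,
       L = L, percentile = L / locus$N_actual * 100)
}

#' Leave-one-out locus validation of a model
#'
#' For every positive (risk) gene: retrain the classifier on the labeled set
#' minus that gene, score every member of its hypothetical locus for each
#' locus size in `N_list` (labeled members are scored like any candidate),
#' and record the percentile rank. Positive genes missing from the feature
#' table or annotation are skipped with a warning.
#'
#' @param features Gene x feature matrix covering the labeled genes and the
#'   locus members.
#' @param labels Label set.
#' @param annotation Annotation data.frame.
#' @param config A [model_config()] (logistic regression is the fast
#'   default for this protocol).
#' @param N_list Integer vector of odd locus sizes.
#' @param seed Integer seed for the per-target refits.
#' @return List of class `locus_report`: `results` (data.frame with gene,
#'   N, N_actual, L, percentile) and `summary` (mean percentile per N).
#' @export
leave_one_out_validate <- function(features, labels, annotation,
                                   config = model_config("LR"),
                                   N_list = c(101L, 201L, 401L), seed = 1L) {
  assert_label_set(labels)
  targets <- labels$positives
  skip <- setdiff(targets, intersect(rownames(features), annotation$gene_id))
  if (length(skip) > 0L) {
    warning(length(skip), " positive gene(s) lacking features or annotation ",
            "skipped: ", paste(utils::head(skip, 5), collapse = ", "))
    targets <- setdiff(targets, skip)
  }
  if (length(targets) == 0L) stop("no usable positive genes")
  rows <- list()
  for (ti in seq_along(targets)) {
    tg <- targets[ti]
    loo_labels <- list(positives = setdiff(labels$positives, tg),
                       negatives = labels$negatives)
    fit_cfg <- config
    fit_cfg$seed <- derive_seed(seed, 30000L + ti)
    model <- train_model(features, loo_labels, fit_cfg)
    for (N in N_list) {
      locus <- build_hypothetical_locus(tg, annotation, N)
      have <- intersect(locus$members, rownames(features))
      if (length(have) < locus$N_actual) {
        locus$members <- have
        locus$N_actual <- length(have)
      }
      p <- predict_proba(model, features[locus$members, , drop = FALSE])
      r <- percentile_rank(locus, p)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = tg, N = N, N_actual = r$N_actual, L = r$L,
        percentile = r$percentile)
    }
  }
  results <- do.call(rbind, rows)
  summary <- stats::aggregate(percentile ~ N, data = results, FUN = mean)
  names(summary)[2L] <- "mean_percentile"
  structure(list(results = results, summary = summary,
                 algorithm = config$algorithm, seed = seed),
            class = "locus_report")
}

#' @export
print.locus_report <- function(x, ...) {
  cat(sprintf("locus_report: %s model, %d targets\n", x$algorithm,
              length(unique(x$results$gene))))
  print(x$summary)
  invisible(x)
}

#' Histogram of percentile ranks
#'
#' Equal-width bins on \[0, 100), plus the uniform reference count
#' (`length(percentiles) / bins`) a random ranker would put in each bin.
#'
#' @param percentiles Numeric vector of percentile ranks in \[0, 100).
#' @param bins Number of bins (default 20).
#' @return List with `counts` (named by bin interval), `breaks` and
#'   `uniform_reference`.
#' @export
percentile_histogram <- function(percentiles, bins = 20L) {
  if (length(percentiles) == 0L) stop("no percentile ranks supplied")
  if (any(percentiles < 0 | percentiles >= 100))
    stop("percentile ranks must lie in [0, 100)")
  breaks <- seq(0, 100, length.out = bins + 1L)
  bin <- pmin(floor(percentiles / (100 / bins)) + 1L, bins)
  counts <- tabulate(bin, nbins = bins)
  names(counts) <- sprintf("[%g,%g)", breaks[-length(breaks)], breaks[-1L])
  list(counts = counts, breaks = breaks,
       uniform_reference = length(percentiles) / bins)
}
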