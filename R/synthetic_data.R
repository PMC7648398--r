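# Synthetic-data generator. Emulates the three real inputs (developmental
# brain RPKM matrix, transcript FASTA, gene annotation) plus label lists, with
# a planted class signal in both the expression and the k-mer feature space so
# every downstream stage is testable without external downloads.

#' Build a validated simulation configuration
#'
#' Defaults mirror the shape of the real study at reduced scale: a 1:2.64
#' positive:negative ratio (150/396), 60 expression samples of which 30 carry
#' the class signal, five informative k-mers planted at 5x background rate.
#' The `"real_shape"` preset restores the full 604/1,594/524 geometry; the
#' `"null"` preset removes all planted signal.
#'
#' @param n_pos,n_neg Counts of positive (risk) and negative (non-disease)
#'   labeled genes.
#' @param n_unlabeled Count of unlabeled candidate lncRNAs.
#' @param n_unlabeled_pos How many unlabeled lncRNAs carry the full planted
#'   positive signal (expression and sequence). When left at its default it
#'   is clamped to `n_unlabeled`; an explicit value larger than
#'   `n_unlabeled` is an error.
#' @param n_samples Number of expression columns.
#' @param n_signal_samples Number of columns in which the class means differ.
#' @param expr_effect Difference of class means on the log2(RPKM+1) scale in
#'   the signal columns.
#' @param expr_noise_sd Standard deviation of the log2-scale noise.
#' @param informative_kmers Character vector of 3-/4-mers enriched in
#'   positive-class transcripts.
#' @param kmer_enrichment Multiplicative planting rate (1 = background).
#' @param seq_len_range Integer pair, min/max transcript length.
#' @param genes_per_chromosome Genes laid out per synthetic chromosome.
#' @param antisense_fraction Fraction of unlabeled lncRNAs placed
#'   antisense-overlapping a positive gene.
#' @param seed Integer seed driving all simulation streams.
#' @param preset Optional shortcut: `"strong"` (the defaults), `"null"`, or
#'   `"real_shape"`.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_pos = 150L, n_neg = 396L, n_unlabeled = 60L,
                              n_unlabeled_pos = 10L,
                              n_samples = 60L, n_signal_samples = 30L,
                              expr_effect = 2.0, expr_noise_sd = 0.5,
                              informative_kmers = c("CGA", "TAT", "CGCG",
                                                    "GGAA", "ATTA"),
                              kmer_enrichment = 5,
                              seq_len_range = c(500L, 2000L),
                              genes_per_chromosome = 50L,
                              antisense_fraction = 0.1,
                              seed = 1L,
                              preset = c("strong", "null", "real_shape")) {
  preset <- match.arg(preset)
  if (missing(n_unlabeled_pos))
    n_unlabeled_pos <- min(n_unlabeled_pos, n_unlabeled)
  if (preset == "null") {
    expr_effect <- 0
    kmer_enrichment <- 0
  } else if (preset == "real_shape") {
    n_pos <- 604L; n_neg <- 1594L; n_samples <- 524L; n_signal_samples <- 262L
  }
  cfg <- list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
              n_unlabeled = as.integer(n_unlabeled),
              n_unlabeled_pos = as.integer(n_unlabeled_pos),
              n_samples = as.integer(n_samples),
              n_signal_samples = as.integer(n_signal_samples),
              expr_effect = expr_effect, expr_noise_sd = expr_noise_sd,
              informative_kmers = toupper(informative_kmers),
              kmer_enrichment = kmer_enrichment,
              seq_len_range = as.integer(seq_len_range),
              genes_per_chromosome = as.integer(genes_per_chromosome),
              antisense_fraction = antisense_fraction,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_pos < 1L || n_neg < 1L) stop("n_pos and n_neg must be >= 1")
    if (n_unlabeled < 0L) stop("n_unlabeled must be >= 0")
    if (n_unlabeled_pos > n_unlabeled)
      stop("n_unlabeled_pos cannot exceed n_unlabeled")
    if (n_samples < 1L || genes_per_chromosome < 1L)
      stop("counts must be >= 1")
    if (n_signal_samples > n_samples)
      stop("n_signal_samples (", n_signal_samples,
           ") exceeds n_samples (", n_samples, ")")
    if (expr_noise_sd <= 0) stop("expr_noise_sd must be > 0")
    if (antisense_fraction < 0 || antisense_fraction > 1)
      stop("antisense_fraction must lie in [0, 1]")
    if (length(seq_len_range) != 2L || seq_len_range[1L] > seq_len_range[2L] ||
        seq_len_range[1L] < 1L)
      stop("seq_len_range must be an increasing positive pair")
    if (kmer_enrichment > 0 && length(informative_kmers) == 0L)
      stop("kmer_enrichment > 0 requires a non-empty informative_kmers list")
    bad <- !grepl("^[ACGT]{3,4}$", informative_kmers)
    if (length(informative_kmers) > 0L && any(bad))
      stop("informative k-mers must be 3- or 4-mers over {A,C,G,T}: ",
           paste(informative_kmers[bad], collapse = ", "))
  })
  invisible(cfg)
}

# Deterministic gene-id scheme shared by all simulate_* stages.
synthetic_gene_ids <- function(config) {
  list(positives = sprintf("pos%04d", seq_len(config$n_pos)),
       negatives = sprintf("neg%04d", seq_len(config$n_neg)),
       unlabeled = if (config$n_unlabeled > 0L)
         sprintf("lnc%04d", seq_len(config$n_unlabeled)) else character(0),
       unlabeled_pos = if (config$n_unlabeled_pos > 0L)
         sprintf("lnc%04d", seq_len(config$n_unlabeled_pos)) else character(0))
}

#' Simulate an RPKM-scale expression matrix with a planted class signal
#'
#' log2(RPKM+1) values are drawn Normal(mu, `expr_noise_sd`): in the first
#' `n_signal_samples` columns the positive-class mean exceeds the
#' negative-class mean by `expr_effect`; elsewhere all classes share the
#' baseline mean. The matrix is returned on the RPKM scale (2^y - 1, clipped
#' at 0). The first `n_unlabeled_pos` unlabeled lncRNAs follow the
#' positive-class distribution; remaining unlabeled genes follow the baseline.
#'
#' @param config A [simulation_config()].
#' @return A list with the `expression` matrix (class `expr_matrix`, state
#'   `"rpkm"`) and the `labels` list (`positives`, `negatives`).
#' @export
simulate_expression <- function(config) {
  validate_sim_config(config)
  ids <- synthetic_gene_ids(config)
  all_ids <- c(ids$positives, ids$negatives, ids$unlabeled)
  signal_genes <- c(ids$positives, ids$unlabeled_pos)
  mu_base <- 3
  set.seed(derive_seed(config$seed, 11L))
  n <- length(all_ids)
  y <- matrix(stats::rnorm(n * config$n_samples, mean = mu_base,
                           sd = config$expr_noise_sd),
              nrow = n, ncol = config$n_samples)
  if (config$n_signal_samples > 0L && config$expr_effect != 0) {
    sig_rows <- all_ids %in% signal_genes
    y[sig_rows, seq_len(config$n_signal_samples)] <-
      y[sig_rows, seq_len(config$n_signal_samples)] + config$expr_effect
  }
  rpkm <- pmax(2^y - 1, 0)
  dimnames(rpkm) <- list(all_ids, sprintf("sample%03d", seq_len(config$n_samples)))
  list(expression = expression_matrix(rpkm, "rpkm"),
       labels = list(positives = ids$positives, negatives = ids$negatives))
}

#' Simulate transcript sequences with planted k-mer enrichment
#'
#' Sequences are i.i.d. uniform over `{A,C,G,T}` with lengths uniform over
#' `seq_len_range`. In positive-class transcripts (and the unlabeled lncRNAs
#' carrying the planted signal) each informative k-mer is additionally
#' inserted at uniformly random positions, replacing the underlying bases, so
#' that its expected count is about `kmer_enrichment` times the background
#' expectation; sequence lengths are unchanged.
#'
#' @param config A [simulation_config()].
#' @param labels Label set; sequences of `labels$positives` receive the
#'   planted k-mers.
#' @return Named character vector of sequences (a transcript set).
#' @export
simulate_transcripts <- function(config, labels) {
  validate_sim_config(config)
  assert_label_set(labels)
  ids <- synthetic_gene_ids(config)
  all_ids <- c(ids$positives, ids$negatives, ids$unlabeled)
  enriched <- c(labels$positives, ids$unlabeled_pos)
  set.seed(derive_seed(config$seed, 23L))
  lens <- sample(config$seq_len_range[1L]:config$seq_len_range[2L],
                 length(all_ids), replace = TRUE)
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(lens, function(L)
    paste(sample(bases, L, replace = TRUE), collapse = ""), character(1))
  names(seqs) <- all_ids
  if (config$kmer_enrichment > 1 && length(config$informative_kmers) > 0L) {
    for (gid in intersect(enriched, all_ids)) {
      s <- strsplit(seqs[[gid]], "", fixed = TRUE)[[1L]]
      L <- length(s)
      for (w in config$informative_kmers) {
        k <- nchar(w)
        background <- (L - k + 1) / 4^k
        n_extra <- stats::rpois(1L, (config$kmer_enrichment - 1) * background)
        if (n_extra > 0L) {
          wchars <- strsplit(w, "", fixed = TRUE)[[1L]]
          pos <- sample.int(L - k + 1L, n_extra, replace = TRUE)
          for (p in pos) s[p:(p + k - 1L)] <- wchars
        }
      }
      seqs[[gid]] <- paste(s, collapse = "")
    }
  }
  seqs
}

#' Simulate a gene annotation with interspersed classes and antisense lncRNAs
#'
#' Genes are shuffled and laid out in non-overlapping intervals along
#' synthetic chromosomes holding `genes_per_chromosome` genes each (the last
#' chromosome may hold fewer), so positives are interspersed among negatives
#' and hypothetical loci are constructible. A fraction of the unlabeled
#' lncRNAs (`round(antisense_fraction * n_unlabeled)`) is placed on top of
#' this layout, each nested inside a distinct positive gene's interval on the
#' opposite strand.
#'
#' @param config A [simulation_config()].
#' @param labels Label set; antisense partners are drawn from
#'   `labels$positives`.
#' @return Annotation data.frame sorted by (chromosome, start, gene_id).
#' @export
simulate_annotation <- function(config, labels) {
  validate_sim_config(config)
  assert_label_set(labels)
  ids <- synthetic_gene_ids(config)
  set.seed(derive_seed(config$seed, 37L))
  n_anti <- round(config$antisense_fraction * config$n_unlabeled)
  anti_ids <- if (n_anti > 0L) sample(ids$unlabeled, n_anti) else character(0)
  if (n_anti > length(labels$positives))
    stop("not enough positive genes to host ", n_anti, " antisense lncRNAs")
  partners <- if (n_anti > 0L) sample(labels$positives, n_anti) else character(0)

  regular <- sample(setdiff(c(ids$positives, ids$negatives, ids$unlabeled),
                            anti_ids))
  gpc <- config$genes_per_chromosome
  chrom_of <- sprintf("chr%d", (seq_along(regular) - 1L) %/% gpc + 1L)
  lens <- sample(config$seq_len_range[1L]:config$seq_len_range[2L],
                 length(regular), replace = TRUE)
  gaps <- sample(1000:10000, length(regular), replace = TRUE)
  start <- integer(length(regular))
  end <- integer(length(regular))
  cursor <- 1L
  for (i in seq_along(regular)) {
    if (i > 1L && chrom_of[i] != chrom_of[i - 1L]) cursor <- 1L
    start[i] <- cursor
    end[i] <- cursor + lens[i] - 1L
    cursor <- end[i] + gaps[i] + 1L
  }
  strand <- sample(c("+", "-"), length(regular), replace = TRUE)
  biotype <- ifelse(regular %in% ids$unlabeled, "lncRNA", "protein_coding")
  df <- data.frame(gene_id = regular, gene_symbol = toupper(regular),
                   chromosome = chrom_of, start = start, end = end,
                   strand = strand, biotype = biotype,
                   stringsAsFactors = FALSE)
  if (n_anti > 0L) {
    pr <- df[match(partners, df$gene_id), ]
    # nested subinterval of the partner so the only overlap is with the partner
    a_start <- pr$start + pmax(1L, (pr$end - pr$start) %/% 4L)
    a_end <- pr$end - pmax(1L, (pr$end - pr$start) %/% 4L)
    a_end <- pmax(a_end, a_start)
    anti <- data.frame(gene_id = anti_ids, gene_symbol = toupper(anti_ids),
                       chromosome = pr$chromosome, start = a_start,
                       end = a_end,
                       strand = ifelse(pr$strand == "+", "-", "+"),
                       biotype = "lncRNA", stringsAsFactors = FALSE)
    df <- rbind(df, anti)
  }
  df <- df[order(df$chromosome, df$start, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Simulate and write a complete dataset bundle
#'
#' Generates the expression matrix, transcripts, annotation and label lists
#' and writes them to `out_dir` in the pipeline's file dialects, together
#' with a `manifest.json` recording the configuration and seed. Re-running
#' with the same configuration reproduces the files byte-identically.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with all in-memory artifacts and file paths.
#' @export
simulate_dataset <- function(config, out_dir) {
  validate_sim_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  expr <- simulate_expression(config)
  seqs <- simulate_transcripts(config, expr$labels)
  ann <- simulate_annotation(config, expr$labels)
  paths <- list(expression = file.path(out_dir, "expression.tsv"),
                transcripts = file.path(out_dir, "transcripts.fa"),
                annotation = file.path(out_dir, "annotation.tsv"),
                positives = file.path(out_dir, "positives.txt"),
                negatives = file.path(out_dir, "negatives.txt"),
                manifest = file.path(out_dir, "manifest.json"))
  write_expression_table(expr$expression, paths$expression)
  write_fasta(seqs, paths$transcripts)
  write_annotation(ann, paths$annotation)
  write_labels(expr$labels, paths$positives, paths$negatives)
  ids <- synthetic_gene_ids(config)
  manifest <- list(config = unclass(config),
                   n_genes = nrow(expr$expression$values),
                   unlabeled_pos = ids$unlabeled_pos,
                   antisense = ann$gene_id[ann$biotype == "lncRNA" &
                                             overlaps_any(ann, expr$labels$positives)])
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(config = config, expression = expr$expression,
                 labels = expr$labels, transcripts = seqs, annotation = ann,
                 paths = paths))
}

# Which annotation rows intersect the interval of any of the given genes
# (same chromosome, >= 1 shared base)?
overlaps_any <- function(annotation, gene_set) {
  targets <- annotation[annotation$gene_id %in% gene_set, , drop = FALSE]
  if (nrow(targets) == 0L) return(rep(FALSE, nrow(annotation)))
  gr_all <- annotation_granges(annotation)
  gr_t <- annotation_granges(targets)
  hits <- GenomicRanges::findOverlaps(gr_all, gr_t, ignore.strand = TRUE)
  out <- rep(FALSE, nrow(annotation))
  keep <- annotation$gene_id[S4Vectors::queryHits(hits)] !=
    targets$gene_id[S4Vectors::subjectHits(hits)]
  out[unique(S4Vectors::queryHits(hits)[keep])] <- TRUE
  out
}

annotation_granges <- function(annotation, seqlevels = NULL) {
  if (is.null(seqlevels)) seqlevels <- unique(annotation$chromosome)
  GenomicRanges::GRanges(
    seqnames = factor(annotation$chromosome, levels = seqlevels),
    ranges = IRanges::IRanges(start = annotation$start, end = annotation$end),
    strand = annotation$strand,
    gene_id = annotation$gene_id)
}
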