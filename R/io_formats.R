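# Readers and writers for the plain-text formats the pipeline touches:
# FASTA transcripts, TSV expression matrices, gene annotation (TSV dialect or
# GTF gene lines), and label lists.

#' Construct an expression matrix container
#'
#' A thin S3 wrapper around a numeric gene x sample matrix that tracks which
#' transform has been applied (`"rpkm"`, `"log2"` after log2(RPKM+1), or
#' `"minmax"`).
#'
#' @param values Numeric matrix with gene ids as rownames and sample ids as
#'   colnames.
#' @param transform_state One of `"rpkm"`, `"log2"`, `"minmax"`.
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, transform_state = c("rpkm", "log2", "minmax")) {
  transform_state <- match.arg(transform_state)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (transform_state %in% c("rpkm", "log2") && any(values < 0))
    stop("negative values are not allowed in state '", transform_state, "'")
  if (transform_state == "minmax" && (any(values < 0) || any(values > 1)))
    stop("minmax-normalized values must lie in [0, 1]")
  structure(list(values = values, transform_state = transform_state),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$transform_state))
  invisible(x)
}

#' @rdname expression_matrix
#' @param m An `expr_matrix`.
#' @export
gene_ids <- function(m) rownames(m$values)

#' @rdname expression_matrix
#' @export
sample_ids <- function(m) colnames(m$values)

#' Read transcript sequences from a FASTA file
#'
#' Sequences are upper-cased and U is mapped to T so RNA and DNA dialects are
#' both accepted. When several records share a gene id (id = the part of the
#' first header token before an optional `|transcript_id` suffix), one
#' representative is kept: the longest transcript, ties broken by the
#' lexicographically smallest transcript id.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @param ambiguous How to treat characters outside `{A,C,G,T,N}`: `"error"`
#'   rejects the record, `"mask"` maps them to `N`.
#' @return Named character vector of sequences, one per gene id, alphabet
#'   restricted to `{A,C,G,T,N}`.
#' @export
read_fasta <- function(path, ambiguous = c("error", "mask")) {
  ambiguous <- match.arg(ambiguous)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in ", path, ": ",
                                           conditionMessage(e)))
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("FASTA record with empty header in ", path)
  if (any(!nzchar(seqs)))
    stop("empty sequence for record(s): ",
         paste(utils::head(ids[!nzchar(seqs)], 5), collapse = ", "))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    if (ambiguous == "error")
      stop("non-ACGTN characters in record(s): ",
           paste(utils::head(ids[bad], 5), collapse = ", "))
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  tx_ids <- ids
  gene <- sub("\\|.*$", "", ids)
  # longest transcript per gene; ties -> lexicographically smallest transcript id
  ord <- order(gene, -nchar(seqs), tx_ids)
  keep <- !duplicated(gene[ord])
  out <- seqs[ord][keep]
  names(out) <- gene[ord][keep]
  out[order(names(out))]
}

#' Write transcript sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a gene x sample expression table
#'
#' Expects a TSV with a header row `gene_id<TAB>sample1<TAB>...` and one row
#' per gene. Values are taken to be raw RPKM. Missing or non-numeric cells and
#' duplicate gene ids are load-time errors; the matrix is expected dense.
#'
#' @param path Path to the TSV file.
#' @return An [expression_matrix()] with `transform_state = "rpkm"`.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("expression table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("expression table needs a gene_id column plus samples")
  gids <- df[[1L]]
  if (anyDuplicated(gids))
    stop("duplicate gene id(s): ",
         paste(unique(gids[duplicated(gids)]), collapse = ", "))
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1L, dimnames = list(NULL, colnames(df)[-1L]))
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at gene '%s', sample '%s' (row %d, column %d)",
                 gids[idx[1L]], colnames(vals)[idx[2L]], idx[1L], idx[2L] + 1L))
  }
  rownames(vals) <- gids
  expression_matrix(vals, "rpkm")
}

#' Write an expression matrix as TSV
#'
#' @param m An [expression_matrix()].
#' @param path Output path.
#' @export
write_expression_table <- function(m, path) {
  stopifnot(inherits(m, "expr_matrix"))
  df <- data.frame(gene_id = gene_ids(m), m$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

VALID_BIOTYPES <- c("protein_coding", "lncRNA", "other")

#' Read a gene annotation table
#'
#' Accepts either the 7-column TSV dialect (`gene_id`, `gene_symbol`,
#' `chromosome`, `start`, `end`, `strand`, `biotype`; 1-based inclusive
#' coordinates, GTF convention) or GTF gene lines (files ending `.gtf` or
#' `.gtf.gz`, read through rtracklayer). Unknown biotypes map to `"other"`
#' with a warning; invalid strand or `start > end` is an error. Records are
#' returned sorted by (chromosome, start, gene_id).
#'
#' @param path Path to the annotation file.
#' @return A data.frame with one row per gene.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (grepl("\\.gtf(\\.gz)?$", path)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GTF requires the rtracklayer package")
    gr <- rtracklayer::import(path, feature.type = "gene")
    md <- S4Vectors::mcols(gr)
    sym <- if ("gene_name" %in% colnames(md)) md$gene_name else md$gene_id
    bty <- if ("gene_type" %in% colnames(md)) md$gene_type else
      if ("gene_biotype" %in% colnames(md)) md$gene_biotype else "other"
    df <- data.frame(gene_id = md$gene_id, gene_symbol = sym,
                     chromosome = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)),
                     biotype = as.character(bty), stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, quote = "",
                            stringsAsFactors = FALSE)
    need <- c("gene_id", "gene_symbol", "chromosome", "start", "end",
              "strand", "biotype")
    if (!all(need %in% colnames(df)))
      stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
    df <- df[need]
    df$start <- as.integer(df$start)
    df$end <- as.integer(df$end)
  }
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene id(s) in annotation: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  if (any(!df$strand %in% c("+", "-")))
    stop("invalid strand for gene(s): ",
         paste(utils::head(df$gene_id[!df$strand %in% c("+", "-")], 5), collapse = ", "))
  if (any(df$start > df$end))
    stop("start > end for gene(s): ",
         paste(utils::head(df$gene_id[df$start > df$end], 5), collapse = ", "))
  unknown <- !df$biotype %in% VALID_BIOTYPES
  if (any(unknown)) {
    warning(sum(unknown), " record(s) with unknown biotype mapped to 'other'")
    df$biotype[unknown] <- "other"
  }
  df <- df[order(df$chromosome, df$start, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a gene annotation table in the 7-column TSV dialect
#'
#' @param annotation Data.frame as returned by [read_annotation()].
#' @param path Output path.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read positive/negative label lists
#'
#' Each file holds one gene id per line. The two sets must be disjoint and
#' non-empty.
#'
#' @param positives_path,negatives_path Paths to the label files.
#' @return A list with character vectors `positives` and `negatives`.
#' @export
read_labels <- function(positives_path, negatives_path) {
  rd <- function(p) {
    if (!file.exists(p)) stop("label file not found: ", p)
    x <- readLines(p)
    x <- trimws(x)
    unique(x[nzchar(x)])
  }
  assert_label_set(list(positives = rd(positives_path),
                        negatives = rd(negatives_path)))
}

#' Write label lists, one gene id per line
#'
#' @param labels A label set (list with `positives` and `negatives`).
#' @param positives_path,negatives_path Output paths.
#' @export
write_labels <- function(labels, positives_path, negatives_path) {
  assert_label_set(labels)
  writeLines(labels$positives, positives_path)
  writeLines(labels$negatives, negatives_path)
  invisible(c(positives_path, negatives_path))
}
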