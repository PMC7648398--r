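#' @keywords internal
"_PACKAGE"

# Sub-seed derivation: every stage draws from a stream split off the single
# user-facing seed. Offsets are fixed per stream; results stay < 2^31.
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483647)
}

#' Format a count as a percentage of a total
#'
#' Report-formatting helper used in prioritization summaries: the share of
#' called candidates is printed to two decimal places (e.g. 1124 of 9463
#' lncRNAs is 11.88%).
#'
#' @param n Numerator count.
#' @param total Denominator count (> 0).
#' @param digits Decimal places (default 2).
#' @return Numeric percentage rounded to `digits` places.
#' @examples
#' percent_of(420, 1124)  # 37.37
#' @export
percent_of <- function(n, total, digits = 2L) {
  stopifnot(total > 0, n >= 0)
  round(100 * n / total, digits)
}

#' @rdname percent_of
#' @return `format_percent()` returns the same quantity as a string with a
#'   trailing percent sign, e.g. `"37.37%"`.
#' @export
format_percent <- function(n, total, digits = 2L) {
  sprintf(paste0("%.", digits, "f%%"), percent_of(n, total, digits))
}

# Shared validation helpers ---------------------------------------------------

assert_label_set <- function(labels) {
  stopifnot(is.list(labels), all(c("positives", "negatives") %in% names(labels)))
  if (length(labels$positives) == 0L || length(labels$negatives) == 0L)
    stop("label set must contain at least one positive and one negative gene")
  if (length(intersect(labels$positives, labels$negatives)) > 0L)
    stop("positives and negatives overlap: ",
         paste(utils::head(intersect(labels$positives, labels$negatives), 5), collapse = ", "))
  invisible(labels)
}

# Binary label vector (1 = positive, 0 = negative) aligned to gene ids.
label_vector <- function(gene_ids, labels) {
  assert_label_set(labels)
  y <- rep(NA_integer_, length(gene_ids))
  y[gene_ids %in% labels$positives] <- 1L
  y[gene_ids %in% labels$negatives] <- 0L
  names(y) <- gene_ids
  y
}
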