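#' Raw UMI count matrix
#'
#' Container for a genes x cells matrix of raw unique molecular identifier
#' (UMI) counts. Gene symbols are case-folded to uppercase at construction so
#' that downstream marker matching is case-insensitive. Counts must be
#' non-negative integers; zeros are later interpreted as dropouts.
#'
#' @param counts numeric matrix, genes in rows, cells in columns. Entries must
#'   be non-negative and integral.
#' @param genes character vector of gene symbols, one per row. Defaults to
#'   `rownames(counts)`.
#' @param barcodes character vector of unique cell identifiers, one per
#'   column. Defaults to `colnames(counts)`.
#' @param duplicates policy for gene symbols that collide after case-folding:
#'   `"error"` (default) refuses the input, `"sum"` collapses colliding rows
#'   by summation. Silent collapsing changes signature-score inputs, hence the
#'   conservative default.
#' @return an object of class `count_matrix`: a list with elements `genes`,
#'   `barcodes` and the integer `counts` matrix (dimnames set).
#' @export
count_matrix <- function(counts, genes = rownames(counts),
                         barcodes = colnames(counts),
                         duplicates = c("error", "sum")) {
  duplicates <- match.arg(duplicates)
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) {
    stop("counts must be numeric")
  }
  if (is.null(genes) || is.null(barcodes)) {
    stop("gene symbols and cell barcodes are required")
  }
  genes <- toupper(as.character(genes))
  barcodes <- as.character(barcodes)
  if (length(genes) != nrow(counts)) {
    stop(sprintf("%d gene symbols for %d rows", length(genes), nrow(counts)))
  }
  if (length(barcodes) != ncol(counts)) {
    stop(sprintf("%d barcodes for %d columns", length(barcodes), ncol(counts)))
  }
  if (anyDuplicated(barcodes)) {
    stop("cell barcodes must be unique")
  }
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    ex <- bad[seq_len(min(5L, nrow(bad))), , drop = FALSE]
    stop(sprintf(
      "counts must be non-negative integers; offending entries (gene,cell): %s",
      paste(sprintf("(%s,%s)", genes[ex[, 1]], barcodes[ex[, 2]]),
            collapse = ", ")))
  }
  if (anyDuplicated(genes)) {
    if (duplicates == "error") {
      dup <- unique(genes[duplicated(genes)])
      stop(sprintf("duplicate gene symbols: %s (use duplicates = \"sum\" to collapse)",
                   paste(head(dup, 5L), collapse = ", ")))
    }
    counts <- rowsum(counts, group = genes, reorder = FALSE)
    genes <- rownames(counts)
  }
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(genes, barcodes)
  structure(list(genes = genes, barcodes = barcodes, counts = counts),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells (%.1f%% zeros)\n",
              nrow(x$counts), ncol(x$counts),
              100 * mean(x$counts == 0)))
  invisible(x)
}

# resolve a gene symbol against a gene index, case-insensitively; errors with
# near-matches so typos are actionable
.resolve_gene <- function(gene, genes) {
  if (length(gene) != 1L || !is.character(gene)) {
    stop("gene must be a single symbol")
  }
  g <- toupper(gene)
  i <- match(g, genes)
  if (is.na(i)) {
    near <- agrep(g, genes, max.distance = 0.25, value = TRUE)
    hint <- if (length(near)) {
      sprintf("; near matches: %s", paste(head(near, 5L), collapse = ", "))
    } else ""
    stop(sprintf("gene '%s' not found%s", gene, hint))
  }
  i
}
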