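#' Trimmed quantile normalization of UMI counts
#'
#' Per-cell scaling in the upper-quartile family: for each cell the given
#' quantile of its nonzero counts is computed after excluding the most
#' abundant genes dataset-wide (the "trim"), and counts are rescaled so that
#' this quantile is equal across cells (to the median of the per-cell
#' quantiles, so the overall scale stays near the raw data). Zeros remain
#' zeros, preserving the dropout pattern.
#'
#' @param counts a [count_matrix()].
#' @param quantile which quantile of each cell's nonzero counts to equalize;
#'   in (0,1), default 0.75 (upper quartile).
#' @param trim_frac fraction of genes, ranked by dataset-wide total count, to
#'   exclude from the quantile computation; in \[0, 0.25), default 0.05.
#'   Trimming keeps a handful of ultra-abundant transcripts from dominating
#'   the per-cell quantile.
#' @return an object of class `normalized_matrix`: list with `genes`,
#'   `barcodes`, `values` (counts x per-cell scale), `scale` (per-cell
#'   factors), `trimmed` (symbols excluded from the quantile), and the
#'   parameters used.
#' @export
trimmed_quantile_normalize <- function(counts, quantile = 0.75,
                                       trim_frac = 0.05) {
  stopifnot(inherits(counts, "count_matrix"))
  if (!is.numeric(quantile) || length(quantile) != 1L ||
      quantile <= 0 || quantile >= 1) {
    stop("parameter error: quantile must be a single value in (0, 1)")
  }
  if (!is.numeric(trim_frac) || length(trim_frac) != 1L ||
      trim_frac < 0 || trim_frac >= 0.25) {
    stop("parameter error: trim_frac must be in [0, 0.25)")
  }
  x <- counts$counts
  n_genes <- nrow(x)
  n_trim <- floor(trim_frac * n_genes)
  trimmed_idx <- integer(0)
  if (n_trim > 0) {
    totals <- rowSums(x)
    trimmed_idx <- order(totals, decreasing = TRUE)[seq_len(n_trim)]
  }
  keep <- setdiff(seq_len(n_genes), trimmed_idx)
  q <- vapply(seq_len(ncol(x)), function(c) {
    v <- x[keep, c]
    v <- v[v > 0]
    if (length(v) == 0L) {
      stop(sprintf(
        "cell '%s' has no nonzero counts among untrimmed genes",
        counts$barcodes[c]))
    }
    stats::quantile(v, probs = quantile, names = FALSE)
  }, numeric(1))
  scale <- median(q) / q
  values <- sweep(x, 2L, scale, `*`)
  structure(list(genes = counts$genes, barcodes = counts$barcodes,
                 values = values, scale = scale,
                 trimmed = counts$genes[trimmed_idx],
                 quantile = quantile, trim_frac = trim_frac),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d genes x %d cells; scale in [%.3g, %.3g]; %d genes trimmed\n",
              nrow(x$values), ncol(x$values), min(x$scale), max(x$scale),
              length(x$trimmed)))
  invisible(x)
}

#' Per-gene z-scoring with dropout mask
#'
#' Converts normalized expression to per-gene z-scores over all cells
#' (dropouts included, population standard deviation), so that z = 0 is
#' literally the gene's population mean and the z-scale is comparable across
#' genes. Genes with zero variance get z identically 0 and are flagged
#' non-informative rather than producing NaN. The dropout mask marks raw zero
#' counts.
#'
#' @param norm a `normalized_matrix` from [trimmed_quantile_normalize()].
#' @param moments which cells define each gene's mean and sd: `"all"`
#'   (default; dropouts included, so z = 0 is the population mean and the
#'   left guide line of the Z-Z plot sits exactly on the Y axis) or
#'   `"expressing"` (moments over nonzero cells only; dropouts then get
#'   negative z). The all-cells convention is the one the rest of the
#'   package assumes for its guide-line geometry.
#' @return an object of class `zscore_matrix`: list with `genes`, `barcodes`,
#'   `z` (the z-score matrix), `dropout` (logical, TRUE where the raw count
#'   was zero), `values` (the normalized values, kept for expression
#'   summaries and co-expression ranking), `scale`, and `gene_stats` (per-gene
#'   mean, population sd, mean over expressing cells, number expressing,
#'   non-informative flag).
#' @export
zscore <- function(norm, moments = c("all", "expressing")) {
  stopifnot(inherits(norm, "normalized_matrix"))
  moments <- match.arg(moments)
  v <- norm$values
  n <- ncol(v)
  if (moments == "all") {
    m <- rowMeans(v)
    s <- sqrt(rowMeans((v - m)^2))  # population sd (divide by n)
  } else {
    expr <- v > 0
    n_e <- rowSums(expr)
    m <- ifelse(n_e > 0, rowSums(v) / pmax(n_e, 1L), 0)
    s <- sqrt(ifelse(n_e > 0,
                     rowSums(((v - m)^2) * expr) / pmax(n_e, 1L), 0))
  }
  noninf <- s == 0
  s_safe <- ifelse(noninf, 1, s)
  z <- (v - m) / s_safe
  z[noninf, ] <- 0
  dropout <- v == 0
  n_expr <- rowSums(!dropout)
  mean_expr <- ifelse(n_expr > 0, rowSums(v) / pmax(n_expr, 1L), 0)
  gene_stats <- data.frame(
    gene = norm$genes,
    mean = m,
    sd = s,
    mean_expressing = mean_expr,
    n_expressing = n_expr,
    noninformative = noninf,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(genes = norm$genes, barcodes = norm$barcodes, z = z,
                 dropout = dropout, values = v, scale = norm$scale,
                 gene_stats = gene_stats),
            class = "zscore_matrix")
}

#' @export
print.zscore_matrix <- function(x, ...) {
  cat(sprintf("zscore_matrix: %d genes x %d cells; %.1f%% dropouts; %d non-informative genes\n",
              nrow(x$z), ncol(x$z), 100 * mean(x$dropout),
              sum(x$gene_stats$noninformative)))
  invisible(x)
}

#' Dropout-aware expression summaries for one gene
#'
#' Summaries are computed on normalized values (not z-scores): the mean over
#' all cells (dropouts counted as zero), the mean over expressing cells only,
#' the percentage and number of expressing cells, and the total summed
#' expression. A gene with no expressing cells reports a zero
#' mean-without-dropouts and is flagged.
#'
#' @param z a `zscore_matrix`.
#' @param gene gene symbol (case-insensitive).
#' @return a list with `gene`, `mean_with_dropouts`, `mean_without_dropouts`,
#'   `pct_expressing` (0-100), `n_expressing`, `total_expression`, and
#'   `no_expressing_cells` flag.
#' @export
expression_summaries <- function(z, gene) {
  stopifnot(inherits(z, "zscore_matrix"))
  i <- .resolve_gene(gene, z$genes)
  v <- z$values[i, ]
  n <- length(v)
  n_expr <- sum(v > 0)
  list(gene = z$genes[i],
       mean_with_dropouts = mean(v),
       mean_without_dropouts = if (n_expr > 0) sum(v) / n_expr else 0,
       pct_expressing = 100 * n_expr / n,
       n_expressing = n_expr,
       total_expression = sum(v),
       no_expressing_cells = n_expr == 0L)
}

# ---- z-score cache (columnar text serialization with a version stamp) ------

.ZCACHE_VERSION <- "1"

#' Save or load a z-score matrix cache
#'
#' The cache is a directory of TSV files plus a `meta.json` version
#' stamp; loading a cache written by an incompatible package version fails
#' explicitly rather than mis-parsing.
#'
#' @param z a `zscore_matrix`.
#' @param directory cache directory (created if absent).
#' @export
save_zscore_cache <- function(z, directory) {
  stopifnot(inherits(z, "zscore_matrix"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(version = .ZCACHE_VERSION, n_genes = nrow(z$z), n_cells = ncol(z$z)),
    file.path(directory, "meta.json"), auto_unbox = TRUE)
  data.table::fwrite(data.frame(barcode = z$barcodes, scale = z$scale),
                     file.path(directory, "cells.tsv"), sep = "\t")
  data.table::fwrite(z$gene_stats, file.path(directory, "gene_stats.tsv"),
                     sep = "\t")
  data.table::fwrite(as.data.frame(z$values),
                     file.path(directory, "values.tsv"), sep = "\t")
  invisible(NULL)
}

#' @rdname save_zscore_cache
#' @return `load_zscore_cache` returns the reconstructed `zscore_matrix`.
#' @export
load_zscore_cache <- function(directory) {
  meta_path <- file.path(directory, "meta.json")
  if (!file.exists(meta_path)) {
    stop(sprintf("not a z-score cache (missing meta.json): %s", directory))
  }
  meta <- jsonlite::fromJSON(meta_path)
  if (!identical(as.character(meta$version), .ZCACHE_VERSION)) {
    stop(sprintf("stale cache version '%s' in %s (expected '%s'); regenerate it",
                 meta$version, directory, .ZCACHE_VERSION))
  }
  cells <- data.table::fread(file.path(directory, "cells.tsv"),
                             sep = "\t", data.table = FALSE)
  gene_stats <- data.table::fread(file.path(directory, "gene_stats.tsv"),
                                  sep = "\t", data.table = FALSE)
  values <- as.matrix(data.table::fread(file.path(directory, "values.tsv"),
                                        sep = "\t", data.table = FALSE))
  dimnames(values) <- list(gene_stats$gene, cells$barcode)
  norm <- structure(list(genes = gene_stats$gene, barcodes = cells$barcode,
                         values = values, scale = cells$scale,
                         trimmed = character(0), quantile = NA_real_,
                         trim_frac = NA_real_),
                    class = "normalized_matrix")
  zscore(norm)
}
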