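#' Sentinel-gene Spearman co-expression discovery
#'
#' Ranks genes by the magnitude of their Spearman rank correlation with a
#' sentinel gene over a cell subset. Correlations are computed on normalized
#' values with average-rank tie handling (per-gene z-scoring is a monotone
#' transform, so ranks — and hence rho — are identical either way). Two-sided
#' p-values use the t approximation; q-values are Benjamini-Hochberg adjusted
#' across the tested candidates. Candidates expressed in fewer than
#' `min_expressing_frac` of the subset are skipped to filter
#' dropout-dominated genes; a secondary `co_pos_frac` column reports the
#' fraction of subset cells expressing both genes, for count-based sorting.
#'
#' @param z a `zscore_matrix`.
#' @param sentinel sentinel gene symbol; must be expressed somewhere in the
#'   subset.
#' @param subset cells to use: `NULL` for all cells, a [select_cells()]
#'   selection, or a character vector of barcodes. At least 10 cells.
#' @param min_expressing_frac minimum expressing fraction for a candidate to
#'   be tested (default 0.1).
#' @return a data frame (class `coexpression_ranking`) with columns `gene`,
#'   `rho`, `p`, `q`, `n`, `co_pos_frac`, ordered by `|rho|` descending; the
#'   sentinel and subset are attached as attributes.
#' @export
spearman_discovery <- function(z, sentinel, subset = NULL,
                               min_expressing_frac = 0.1) {
  stopifnot(inherits(z, "zscore_matrix"))
  barcodes <- if (is.null(subset)) {
    z$barcodes
  } else if (inherits(subset, "cell_selection")) {
    subset$barcodes
  } else {
    as.character(subset)
  }
  idx <- match(barcodes, z$barcodes)
  if (anyNA(idx)) {
    stop("subset contains barcodes absent from the matrix")
  }
  n <- length(idx)
  if (n < 10L) {
    stop(sprintf("parameter error: subset has %d cells; at least 10 required", n))
  }
  si <- .resolve_gene(sentinel, z$genes)
  sv <- z$values[si, idx]
  if (!any(sv > 0)) {
    stop(sprintf("sentinel %s is not expressed in the subset", z$genes[si]))
  }
  vals <- z$values[, idx, drop = FALSE]
  expr_frac <- rowMeans(vals > 0)
  cand <- which(expr_frac >= min_expressing_frac & seq_len(nrow(vals)) != si)
  if (length(cand) == 0L) {
    out <- data.frame(gene = character(0), rho = numeric(0), p = numeric(0),
                      q = numeric(0), n = integer(0), co_pos_frac = numeric(0),
                      stringsAsFactors = FALSE)
  } else {
    rho <- suppressWarnings(
      as.numeric(cor(sv, t(vals[cand, , drop = FALSE]), method = "spearman")))
    keep <- is.finite(rho)
    cand <- cand[keep]
    rho <- rho[keep]
    p <- .spearman_p(rho, n)
    q <- p.adjust(p, method = "BH")
    pos_s <- sv > 0
    co_pos <- apply(vals[cand, , drop = FALSE] > 0, 1,
                    function(r) mean(r & pos_s))
    out <- data.frame(gene = z$genes[cand], rho = rho, p = p, q = q, n = n,
                      co_pos_frac = co_pos, stringsAsFactors = FALSE)
    ord <- order(-abs(out$rho), out$gene)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "sentinel") <- z$genes[si]
  attr(out, "barcodes") <- barcodes
  class(out) <- c("coexpression_ranking", "data.frame")
  out
}

# two-sided p from the t approximation to the null distribution of rho
.spearman_p <- function(rho, n) {
  p <- rep(0, length(rho))
  inner <- abs(rho) < 1
  t_stat <- rho[inner] * sqrt((n - 2) / (1 - rho[inner]^2))
  p[inner] <- 2 * pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
  p
}

#' Multi-gene strong-expression mask
#'
#' TRUE for cells whose z-score exceeds `threshold` for every listed gene
#' (conjunction). The default threshold of 1 is the conventional cutoff for
#' "strong expression" on the z scale; composing the mask with a sentinel
#' positivity requirement yields the iterative multi-gene cluster masks.
#'
#' @param z a `zscore_matrix`.
#' @param genes character vector of gene symbols (non-empty).
#' @param threshold finite z-score cutoff, default 1.
#' @return named logical vector over cells.
#' @export
multi_gene_mask <- function(z, genes, threshold = 1) {
  stopifnot(inherits(z, "zscore_matrix"))
  if (length(genes) == 0L) {
    stop("parameter error: empty gene list")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold)) {
    stop("parameter error: threshold must be a single finite number")
  }
  idx <- vapply(genes, .resolve_gene, integer(1), genes = z$genes)
  zz <- z$z[idx, , drop = FALSE]
  mask <- colSums(zz > threshold) == length(idx)
  names(mask) <- z$barcodes
  mask
}

#' Iterative cluster refinement
#'
#' Runs [spearman_discovery()] restricted to the cells of a mask (typically
#' produced by [multi_gene_mask()] after a previous round of discovery), and
#' records the chain of masks applied so multi-round explorations keep their
#' provenance.
#'
#' @param z a `zscore_matrix`.
#' @param mask logical vector over the matrix's cells (or a character vector
#'   of barcodes) defining the current cluster.
#' @param sentinel sentinel gene for the new round.
#' @param min_expressing_frac passed to [spearman_discovery()].
#' @param provenance optional list of prior mask records to extend.
#' @return a `coexpression_ranking` with attribute `provenance`: a list of
#'   records (each with `n_cells` and the defining barcodes).
#' @export
refine_cluster <- function(z, mask, sentinel, min_expressing_frac = 0.1,
                           provenance = NULL) {
  stopifnot(inherits(z, "zscore_matrix"))
  barcodes <- if (is.logical(mask)) {
    if (length(mask) != length(z$barcodes)) {
      stop("logical mask length must match the number of cells")
    }
    z$barcodes[mask]
  } else {
    as.character(mask)
  }
  out <- spearman_discovery(z, sentinel, subset = barcodes,
                            min_expressing_frac = min_expressing_frac)
  attr(out, "provenance") <- c(provenance,
                               list(list(n_cells = length(barcodes),
                                         barcodes = barcodes)))
  out
}
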