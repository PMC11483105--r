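#' Zonal dot count table
#'
#' Tallies every cell into one of nine compartments: zone (superficial,
#' middle, deep) crossed with expression category (non-expressing, expressing
#' with z below 0, expressing with z above 0). Expressing cells with z
#' exactly 0 (possible for degenerate genes) go to the z-above-0 column so
#' the table keeps exactly nine categories.
#'
#' @param z a `zscore_matrix`.
#' @param zones a `zonal_scores` on the same cells.
#' @param gene gene symbol.
#' @return an object of class `zonal_dot_count`: list with `gene`, `counts`
#'   (3x3 integer matrix, zones x categories) and `n_cells`.
#' @export
zonal_dot_count <- function(z, zones, gene) {
  stopifnot(inherits(z, "zscore_matrix"), inherits(zones, "zonal_scores"))
  if (!identical(z$barcodes, zones$barcodes)) {
    stop("z-score matrix and zonal scores refer to different cells")
  }
  i <- .resolve_gene(gene, z$genes)
  category <- factor(ifelse(z$dropout[i, ], "non_expressing",
                            ifelse(z$z[i, ] < 0, "z_below_0", "z_above_0")),
                     levels = c("non_expressing", "z_below_0", "z_above_0"))
  tab <- table(zones$zone, category)
  counts <- matrix(as.integer(tab), nrow = 3, ncol = 3,
                   dimnames = list(rownames(tab), colnames(tab)))
  structure(list(gene = z$genes[i], counts = counts,
                 n_cells = length(zones$zone)),
            class = "zonal_dot_count")
}

#' @export
print.zonal_dot_count <- function(x, ...) {
  cat(sprintf("Zonal dot counts for %s (%d cells)\n", x$gene, x$n_cells))
  print(x$counts)
  invisible(x)
}

#' @export
as.data.frame.zonal_dot_count <- function(x, ...) {
  data.frame(gene = x$gene, zone = rownames(x$counts),
             non_expressing = x$counts[, "non_expressing"],
             z_below_0 = x$counts[, "z_below_0"],
             z_above_0 = x$counts[, "z_above_0"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Zonal dot percentage table
#'
#' From a [zonal_dot_count()] table: the percentage of each zone's cells that
#' express the gene (dropouts excluded from the numerator), the total summed
#' expression of the gene over all cells, and the mean expression per total
#' cell and per expressing cell — all on normalized values. An empty zone
#' reports 0% and is flagged.
#'
#' @param count_table a `zonal_dot_count`.
#' @param mat a `zscore_matrix` or `normalized_matrix` for the same dataset
#'   (supplies the normalized values).
#' @return an object of class `zonal_dot_percentage`: list with `gene`,
#'   `pct_expressing` (named per-zone percentages), `empty_zones`,
#'   `total_expression`, `mean_per_total_cell`, `mean_per_expressing_cell`.
#' @export
zonal_dot_percentage <- function(count_table, mat) {
  stopifnot(inherits(count_table, "zonal_dot_count"))
  if (!inherits(mat, c("zscore_matrix", "normalized_matrix"))) {
    stop("mat must be a zscore_matrix or normalized_matrix")
  }
  i <- .resolve_gene(count_table$gene, mat$genes)
  v <- mat$values[i, ]
  if (length(v) != count_table$n_cells) {
    stop("count table and matrix refer to different datasets")
  }
  cnt <- count_table$counts
  zone_n <- rowSums(cnt)
  expressing <- cnt[, "z_below_0"] + cnt[, "z_above_0"]
  pct <- ifelse(zone_n > 0, 100 * expressing / zone_n, 0)
  total <- sum(v)
  n_expr <- sum(v > 0)
  structure(list(gene = count_table$gene,
                 pct_expressing = setNames(pct, rownames(cnt)),
                 empty_zones = rownames(cnt)[zone_n == 0],
                 total_expression = total,
                 mean_per_total_cell = total / count_table$n_cells,
                 mean_per_expressing_cell = if (n_expr > 0) total / n_expr else 0),
            class = "zonal_dot_percentage")
}

#' @export
print.zonal_dot_percentage <- function(x, ...) {
  cat(sprintf("Zonal dot percentages for %s\n", x$gene))
  for (zn in names(x$pct_expressing)) {
    cat(sprintf("  %-11s %5.1f%% expressing%s\n", zn, x$pct_expressing[[zn]],
                if (zn %in% x$empty_zones) " (empty zone)" else ""))
  }
  cat(sprintf("  total expression %.4g; mean/cell %.4g; mean/expressing %.4g\n",
              x$total_expression, x$mean_per_total_cell,
              x$mean_per_expressing_cell))
  invisible(x)
}

#' @export
as.data.frame.zonal_dot_percentage <- function(x, ...) {
  data.frame(gene = x$gene, zone = names(x$pct_expressing),
             pct_expressing = unname(x$pct_expressing),
             total_expression = x$total_expression,
             mean_per_total_cell = x$mean_per_total_cell,
             mean_per_expressing_cell = x$mean_per_expressing_cell,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Zonal enrichment of a cell selection
#'
#' For each zone, compares the zone share within a selection to the zone
#' share in the whole population: an enrichment ratio of 3 means the
#' selection is three times as concentrated in that zone as cells overall. A
#' zone with no cells has an undefined ratio (NA, flagged).
#'
#' @param selection a `cell_selection`.
#' @param zones a `zonal_scores` covering all cells.
#' @return data frame (class `cluster_enrichment`) with per-zone selection
#'   counts, selection and population percentages, and the enrichment ratio.
#' @export
cluster_enrichment <- function(selection, zones) {
  stopifnot(inherits(selection, "cell_selection"),
            inherits(zones, "zonal_scores"))
  if (length(selection$barcodes) == 0L) {
    stop("parameter error: empty selection")
  }
  idx <- match(selection$barcodes, zones$barcodes)
  if (anyNA(idx)) {
    stop(sprintf("selection contains unknown barcodes: %s",
                 paste(head(selection$barcodes[is.na(idx)], 5L),
                       collapse = ", ")))
  }
  sel_tab <- table(factor(zones$zone[idx],
                          levels = levels(zones$zone)))
  all_tab <- table(zones$zone)
  pct_sel <- 100 * as.numeric(sel_tab) / length(idx)
  pct_all <- 100 * as.numeric(all_tab) / length(zones$zone)
  ratio <- ifelse(as.numeric(all_tab) > 0, pct_sel / pct_all, NA_real_)
  out <- data.frame(zone = names(all_tab),
                    n_selection = as.integer(sel_tab),
                    pct_selection = pct_sel,
                    pct_population = pct_all,
                    enrichment = ratio,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("cluster_enrichment", "data.frame")
  out
}
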