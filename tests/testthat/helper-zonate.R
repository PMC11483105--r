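# shared fixtures and independent oracles

rand_counts <- function(n_genes, n_cells, seed, lambda = 5) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, lambda), n_genes, n_cells)
  count_matrix(m, genes = sprintf("G%03d", seq_len(n_genes)),
               barcodes = sprintf("C%03d", seq_len(n_cells)))
}

# a zscore_matrix with prescribed z values (for score arithmetic tests that
# do not touch normalized values or dropouts)
manual_zmat <- function(z, values = NULL) {
  if (is.null(values)) values <- abs(z)
  structure(list(genes = rownames(z), barcodes = colnames(z), z = z,
                 dropout = values == 0, values = values,
                 scale = rep(1, ncol(z)),
                 gene_stats = data.frame(gene = rownames(z),
                                         mean = rowMeans(values),
                                         sd = apply(values, 1, function(v)
                                           sqrt(mean((v - mean(v))^2))),
                                         mean_expressing = rowMeans(values),
                                         n_expressing = rowSums(values > 0),
                                         noninformative = FALSE)),
            class = "zscore_matrix")
}

# independent brute-force evaluation of the zonal signature score: explicit
# per-cell loop over the marker lists
oracle_zonal <- function(z, S, D, w = NULL) {
  if (is.null(w)) w <- setNames(rep(1, length(c(S, D))), c(S, D))
  out <- numeric(ncol(z))
  for (c in seq_len(ncol(z))) {
    s_num <- 0; s_den <- 0
    for (g in S) { s_num <- s_num + w[[g]] * z[g, c]; s_den <- s_den + w[[g]] }
    d_num <- 0; d_den <- 0
    for (g in D) { d_num <- d_num + w[[g]] * z[g, c]; d_den <- d_den + w[[g]] }
    out[c] <- s_num / s_den - d_num / d_den
  }
  out
}

# independent Spearman oracle: average ranks, then hand-rolled Pearson
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  cx <- rx - mean(rx)
  cy <- ry - mean(ry)
  sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
}

# brute-force nine-compartment tally by explicit per-cell loop
oracle_dot_count <- function(zrow, dropout_row, zone) {
  zones <- c("superficial", "middle", "deep")
  cats <- c("non_expressing", "z_below_0", "z_above_0")
  grid <- matrix(0L, 3, 3, dimnames = list(zones, cats))
  for (c in seq_along(zrow)) {
    cat_c <- if (dropout_row[c]) "non_expressing"
             else if (zrow[c] < 0) "z_below_0" else "z_above_0"
    grid[as.character(zone[c]), cat_c] <- grid[as.character(zone[c]), cat_c] + 1L
  }
  grid
}

run_cli <- function(...) {
  script <- system.file("cli", "zonate", package = "zonate")
  rscript <- file.path(R.home("bin"), "Rscript")
  libs <- paste(.libPaths(), collapse = .Platform$path.sep)
  out <- suppressWarnings(
    system2(rscript, c(script, unlist(list(...))),
            env = paste0("R_LIBS=", libs),
            stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}
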