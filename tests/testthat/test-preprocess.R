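test_that("normalization leaves identical-quantile data unchanged and tracks cell scaling", {
  # all cells share the same nonzero-count quantile -> unit scale factors
  m <- matrix(c(2, 4, 0, 2, 4, 0, 4, 2, 0), 3, 3)
  cm <- count_matrix(m, genes = c("GA", "GB", "GC"),
                     barcodes = c("c1", "c2", "c3"))
  norm <- trimmed_quantile_normalize(cm, quantile = 0.5, trim_frac = 0)
  expect_equal(norm$scale, rep(1, 3))
  expect_equal(norm$values, cm$counts)

  # doubling a cell's counts halves its scale factor: duplicated cell equals
  # the original after normalization
  cm2 <- rand_counts(30, 10, seed = 5)
  doubled <- cbind(cm2$counts, 2 * cm2$counts[, 3])
  cmd <- count_matrix(doubled, genes = cm2$genes,
                      barcodes = c(cm2$barcodes, "dup"))
  nd <- trimmed_quantile_normalize(cmd, trim_frac = 0)
  expect_equal(nd$values[, "dup"], nd$values[, 3], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("per-cell quantiles of nonzero normalized counts equalize", {
  set.seed(11)
  m <- matrix(rnbinom(50 * 20, mu = 8, size = 2), 50, 20)
  m[m < 0] <- 0
  cm <- count_matrix(m, genes = sprintf("G%02d", 1:50),
                     barcodes = sprintf("C%02d", 1:20))
  norm <- trimmed_quantile_normalize(cm)
  untrimmed <- setdiff(norm$genes, norm$trimmed)
  q <- vapply(seq_len(20), function(c) {
    v <- norm$values[untrimmed, c]
    quantile(v[v > 0], 0.75, names = FALSE)
  }, numeric(1))
  expect_lt(diff(range(q)), 1e-9)
  expect_true(all(norm$values[cm$counts == 0] == 0))  # zeros stay zeros
})

test_that("normalization rejects cells with no usable counts and bad parameters", {
  m <- matrix(c(1, 2, 0, 0), 2, 2)
  cm <- count_matrix(m, genes = c("GA", "GB"), barcodes = c("ok", "empty"))
  expect_error(trimmed_quantile_normalize(cm, trim_frac = 0), "empty")
  expect_error(trimmed_quantile_normalize(rand_counts(5, 5, 1), quantile = 1.5),
               "parameter error")
  expect_error(trimmed_quantile_normalize(rand_counts(5, 5, 1), trim_frac = 0.5),
               "parameter error")
})

test_that("z-scores match the population-moment definition by hand", {
  # values (0, 0, 3, 3): mean 1.5, population sd 1.5 -> z = (-1, -1, 1, 1)
  m <- matrix(c(0, 0, 3, 3, 1, 1, 1, 1), 2, 4, byrow = TRUE)
  norm <- structure(list(genes = c("GA", "GB"), barcodes = paste0("c", 1:4),
                         values = m, scale = rep(1, 4),
                         trimmed = character(0), quantile = 0.75,
                         trim_frac = 0), class = "normalized_matrix")
  z <- zscore(norm)
  expect_equal(unname(z$z[1, ]), c(-1, -1, 1, 1))
  # constant gene: z identically zero, flagged non-informative
  expect_equal(unname(z$z[2, ]), rep(0, 4))
  expect_true(z$gene_stats$noninformative[2])
  expect_false(z$gene_stats$noninformative[1])
  # dropout mask tracks raw zeros
  expect_equal(unname(z$dropout[1, ]), c(TRUE, TRUE, FALSE, FALSE))
})

test_that("z-score contract holds on random data: mean 0, population sd 1", {
  for (seed in 1:3) {
    norm <- trimmed_quantile_normalize(rand_counts(40, 25, seed))
    z <- zscore(norm)
    informative <- !z$gene_stats$noninformative
    expect_true(any(informative))
    expect_lt(max(abs(rowMeans(z$z[informative, , drop = FALSE]))), 1e-9)
    sds <- sqrt(rowMeans(z$z[informative, , drop = FALSE]^2))
    expect_lt(max(abs(sds - 1)), 1e-9)
  }
})

test_that("z-scoring after normalization ignores per-cell count rescaling", {
  # two dominant genes keep the trim set stable when a cell is rescaled
  set.seed(21)
  m <- rbind(matrix(rpois(2 * 30, 200), 2, 30),
             matrix(rpois(38 * 30, 5), 38, 30))
  cm <- count_matrix(m, genes = sprintf("G%02d", 1:40),
                     barcodes = sprintf("C%02d", 1:30))
  z1 <- zscore(trimmed_quantile_normalize(cm))
  m2 <- m
  m2[, 7] <- 3 * m2[, 7]
  cm2 <- count_matrix(m2, genes = cm$genes, barcodes = cm$barcodes)
  z2 <- zscore(trimmed_quantile_normalize(cm2))
  expect_lt(max(abs(z1$z - z2$z)), 1e-9)
})

test_that("cell order permutation permutes outputs identically", {
  cm <- rand_counts(30, 12, seed = 9)
  perm <- sample(seq_len(12))
  cmp <- count_matrix(cm$counts[, perm], genes = cm$genes,
                      barcodes = cm$barcodes[perm])
  z1 <- zscore(trimmed_quantile_normalize(cm))
  z2 <- zscore(trimmed_quantile_normalize(cmp))
  expect_equal(z2$z, z1$z[, perm])
  expect_equal(z2$dropout, z1$dropout[, perm])
})

test_that("expression summaries follow the dropout-aware arithmetic", {
  norm <- structure(list(genes = c("GA", "GB", "GC"),
                         barcodes = paste0("c", 1:3),
                         values = rbind(c(0, 0, 4), c(1, 2, 3), c(0, 0, 0)),
                         scale = rep(1, 3), trimmed = character(0),
                         quantile = 0.75, trim_frac = 0),
                    class = "normalized_matrix")
  z <- zscore(norm)
  s <- expression_summaries(z, "GA")
  expect_equal(s$mean_with_dropouts, 4 / 3)
  expect_equal(s$mean_without_dropouts, 4)
  expect_equal(s$pct_expressing, 100 / 3)
  expect_equal(s$n_expressing, 1L)
  expect_equal(s$total_expression, 4)

  # no dropouts: both means coincide
  s2 <- expression_summaries(z, "gb")  # case-insensitive lookup
  expect_equal(s2$mean_with_dropouts, s2$mean_without_dropouts)

  # never expressed: reported as zero and flagged
  s3 <- expression_summaries(z, "GC")
  expect_equal(s3$mean_without_dropouts, 0)
  expect_true(s3$no_expressing_cells)

  expect_error(expression_summaries(z, "GX"), "not found")
})

test_that("mean with dropouts never exceeds mean without dropouts", {
  z <- zscore(trimmed_quantile_normalize(rand_counts(40, 20, seed = 13,
                                                     lambda = 2)))
  for (g in z$genes) {
    s <- expression_summaries(z, g)
    if (s$n_expressing > 0 && s$n_expressing < 20) {
      expect_lte(s$mean_with_dropouts, s$mean_without_dropouts)
    }
  }
})

test_that("z-score cache round trips and rejects stale versions", {
  z <- zscore(trimmed_quantile_normalize(rand_counts(20, 15, seed = 3)))
  dir <- withr::local_tempdir()
  save_zscore_cache(z, dir)
  back <- load_zscore_cache(dir)
  expect_equal(back$z, z$z, tolerance = 1e-12)
  expect_equal(back$genes, z$genes)
  expect_equal(back$dropout, z$dropout)

  meta <- file.path(dir, "meta.json")
  jsonlite::write_json(list(version = "0", n_genes = 20, n_cells = 15), meta,
                       auto_unbox = TRUE)
  expect_error(load_zscore_cache(dir), "stale cache")
})

test_that("the expressing-cells moment convention centers z on expressing cells", {
  m <- matrix(c(0, 0, 3, 5, 2, 2, 2, 2), 2, 4, byrow = TRUE,
              dimnames = list(c("GA", "GB"), paste0("c", 1:4)))
  norm <- structure(list(genes = rownames(m), barcodes = colnames(m),
                         values = m, scale = rep(1, 4),
                         trimmed = character(0), quantile = 0.75,
                         trim_frac = 0), class = "normalized_matrix")
  z <- zscore(norm, moments = "expressing")
  # GA expressing values (3, 5): mean 4, population sd 1 -> z = (-4, -4, -1, 1)
  expect_equal(unname(z$z[1, ]), c(-4, -4, -1, 1))
  # dropouts now sit below zero instead of at the gene mean
  expect_true(all(z$z[1, z$dropout[1, ]] < 0))
  # constant-on-expressing gene is non-informative under this convention too
  expect_true(z$gene_stats$noninformative[2])
})
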