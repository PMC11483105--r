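# small fitted dataset shared across the rendering tests
zz_fit <- local({
  sim <- simulate_zonal_counts(n_cells = 120, n_genes = 40, seed = 17)
  zonate(sim$counts)
})

test_that("Z-Z coordinates match independent recomputation and dropouts sit on the Y axis", {
  zm <- zz_fit$zmat
  zones <- zz_fit$scores
  pd <- build_zzplot(zm, zones, "PRG4")
  i <- match("PRG4", zm$genes)
  expect_equal(nrow(pd$cells), length(zones$Zc))
  expect_equal(pd$cells$y, zones$Zc)
  expr <- !zm$dropout[i, ]
  expect_equal(pd$cells$x[expr], unname(zm$z[i, expr]))
  expect_true(all(pd$cells$x[!expr] == 0))
  expect_equal(pd$cells$dropout, unname(zm$dropout[i, ]))
  expect_equal(sum(pd$cells$dropout) + sum(!pd$cells$dropout), 120)
  expect_equal(unname(pd$hlines), c(zones$tau, -zones$tau))
})

test_that("vertical guide lines carry the dropout-aware mean intensities", {
  pd <- build_zzplot(zz_fit$zmat, zz_fit$scores, "PRG4")
  sm <- expression_summaries(zz_fit$zmat, "PRG4")
  expect_equal(pd$vlines$x[1], 0)  # all-cells mean sits at z = 0
  expect_equal(pd$vlines$value, c(sm$mean_with_dropouts,
                                  sm$mean_without_dropouts))
  if (sum(pd$cells$dropout) > 0) {
    expect_gte(pd$vlines$x[2], pd$vlines$x[1])
  }

  # a gene expressed everywhere yields no dropout lane and equal means
  m <- matrix(c(5, 6, 7, 8, 1, 0, 2, 0), 2, 4, byrow = TRUE,
              dimnames = list(c("GA", "GB"), paste0("c", 1:4)))
  norm <- structure(list(genes = rownames(m), barcodes = colnames(m),
                         values = m, scale = rep(1, 4),
                         trimmed = character(0), quantile = 0.75,
                         trim_frac = 0), class = "normalized_matrix")
  zm2 <- zscore(norm)
  zones2 <- assign_zones(setNames(rnorm(4), colnames(m)), 0.5)
  pd2 <- build_zzplot(zm2, zones2, "GA")
  expect_equal(sum(pd2$cells$dropout), 0)
  expect_equal(pd2$vlines$value[1], pd2$vlines$value[2])
})

test_that("y-coordinates are identical across genes of the same fit", {
  pd1 <- build_zzplot(zz_fit$zmat, zz_fit$scores, "PRG4")
  pd2 <- build_zzplot(zz_fit$zmat, zz_fit$scores, "IBSP")
  expect_identical(pd1$cells$y, pd2$cells$y)
})

test_that("overlay colors are the second gene's z-scores, with identities", {
  pd <- build_zzplot(zz_fit$zmat, zz_fit$scores, "PRG4")
  self <- overlay_coexpression(pd, zz_fit$zmat, "PRG4")
  expr <- !self$cells$dropout
  expect_equal(self$cells$color[expr], self$cells$x[expr])
  expect_true(all(is.na(self$cells$color[!expr])))
  expect_equal(self$mode, "overlay")

  # constant second gene -> uniform zero color
  m <- rbind(PRG4 = zz_fit$zmat$values[1, ], FLAT = rep(2, 120))
  colnames(m) <- zz_fit$zmat$barcodes
  norm <- structure(list(genes = rownames(m), barcodes = colnames(m),
                         values = m, scale = rep(1, 120),
                         trimmed = character(0), quantile = 0.75,
                         trim_frac = 0), class = "normalized_matrix")
  zm2 <- zscore(norm)
  pd2 <- build_zzplot(zm2, zz_fit$scores, "PRG4")
  ov <- overlay_coexpression(pd2, zm2, "FLAT")
  expect_true(all(ov$cells$color[!ov$cells$dropout] == 0))

  expect_error(overlay_coexpression(self, zz_fit$zmat, "IBSP"),
               "single-mode")
})

test_that("double-strong cell counts match the brute-force mask recount", {
  zm <- zz_fit$zmat
  pd <- overlay_coexpression(build_zzplot(zm, zz_fit$scores, "PRG4"),
                             zm, "IGFBP5")
  plotted <- sum(!pd$cells$dropout & pd$cells$x > 1 & pd$cells$color > 1,
                 na.rm = TRUE)
  i <- match("PRG4", zm$genes)
  j <- match("IGFBP5", zm$genes)
  brute <- sum(!zm$dropout[i, ] & zm$z[i, ] > 1 & zm$z[j, ] > 1)
  expect_equal(plotted, brute)
})

test_that("cell selection is a conjunction, reproducible and order-independent", {
  pd <- build_zzplot(zz_fit$zmat, zz_fit$scores, "PRG4")
  sup <- select_cells(pd, list(zones = "superficial"))
  expect_setequal(sup$barcodes,
                  pd$cells$barcode[pd$cells$zone == "superficial"])

  # x-range AND a second-gene threshold equals the brute-force intersection
  sel <- select_cells(pd, list(x_range = c(1, 100), gene_z = c(IGFBP5 = 1)),
                      z = zz_fit$zmat)
  j <- match("IGFBP5", zz_fit$zmat$genes)
  brute <- pd$cells$barcode[pd$cells$x >= 1 & pd$cells$x <= 100 &
                              zz_fit$zmat$z[j, ] > 1]
  expect_setequal(sel$barcodes, brute)

  # idempotent: selecting again with the same criteria gives the same set
  sel2 <- select_cells(pd, sel$criteria, z = zz_fit$zmat)
  expect_identical(sel2$barcodes, sel$barcodes)

  expect_error(select_cells(pd, list()), "parameter error")
  expect_error(select_cells(pd, list(exclude_dropouts = FALSE)),
               "parameter error")
  expect_error(select_cells(pd, list(gene_z = c(IGFBP5 = 1))),
               "require the z-score matrix")
})

test_that("selection files carry barcodes plus a criteria sidecar", {
  pd <- build_zzplot(zz_fit$zmat, zz_fit$scores, "PRG4")
  sel <- select_cells(pd, list(zones = c("superficial", "middle")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_selection(sel, path)
  got <- readLines(path)
  expect_equal(got[1], "barcode")
  expect_equal(got[-1], sel$barcodes)
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_equal(side$gene, "PRG4")
  expect_equal(side$n_cells, length(sel$barcodes))
})

test_that("svg rendering is deterministic and contains every cell", {
  pd <- build_zzplot(zz_fit$zmat, zz_fit$scores, "PRG4")
  f1 <- withr::local_tempfile(fileext = ".svg")
  f2 <- withr::local_tempfile(fileext = ".svg")
  render_zzplot(pd, f1, "svg")
  render_zzplot(pd, f2, "svg")
  expect_identical(readLines(f1), readLines(f2))
  svg <- readLines(f1)
  expect_equal(sum(grepl("<circle class=\"cell\"", svg, fixed = TRUE)), 120)
  expect_equal(sum(grepl("stroke-dasharray=\"6,4\"", svg)), 2)  # hlines
  expect_equal(sum(grepl("stroke-dasharray=\"2,3\"", svg)), 2)  # vlines
  expect_true(any(grepl(">PRG4<", svg)))

  f3 <- withr::local_tempfile(fileext = ".html")
  render_zzplot(pd, f3, "html")
  expect_true(any(grepl("<svg", readLines(f3))))
  f4 <- withr::local_tempfile(fileext = ".png")
  render_zzplot(pd, f4, "png")
  expect_gt(file.size(f4), 0)
  expect_error(render_zzplot(pd, f1, "pdf"), "unsupported format")
})
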