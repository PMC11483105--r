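# zonate

Virtual zonal positioning of articular cartilage chondrocytes from
single-cell RNA-seq.

Articular cartilage has three histological zones — superficial, middle and
deep — but dissociated scRNA-seq loses that spatial organization, and
cluster embeddings (tSNE/UMAP) do not recover it. `zonate` positions each
cell along a virtual superficial→deep axis using a zone-marker-gene (ZMG)
signature score, and builds the analyses that live on that axis: the
"Z-Z plot" (zone score versus a gene's z-score, with an explicit dropout
lane), zonal dot count/percentage tables, and sentinel-gene Spearman
co-expression discovery with iterative multi-gene cluster masks.

## The score

After trimmed quantile normalization of raw UMI counts and per-gene
z-scoring over all cells (population moments, so z = 0 is each gene's
population mean), the zonal score of cell *c* is

    Z_c = mean_{g in S} E_{g,c}  -  mean_{g in D} E_{g,c}

where `E_{g,c}` is the z-score of gene *g* in cell *c*, `S` the superficial
markers (default PRG4, IGFBP5, CHI3L1, OGN) and `D` the deep markers
(default COL10A1, IBSP, CLEC3A, F13A1); optional per-gene weights turn the
means into weighted means. Cells with `Z_c > τ` are superficial, below
`-τ` deep, in between middle; `τ` defaults to half the standard deviation
of the scores. A ground-truth synthetic generator (depth-dependent
negative-binomial marker gradients, uniform background genes, independent
dropout, optional planted co-expression cluster) makes every stage
testable without external accessions.

## Worked example

```r
library(zonate)

sim <- simulate_zonal_counts(n_cells = 500, n_genes = 100, seed = 42)
fit <- zonate(sim$counts)        # normalize -> z-score -> zonal score -> zones
fit
#> Virtual zonal positioning fit
#>   100 genes x 500 cells
#>   markers: PRG4, IGFBP5, CHI3L1, OGN | COL10A1, IBSP, CLEC3A, F13A1
#>   tau = 0.5591 (relative); zones: superficial 153, middle 206, deep 141
```

The fit partitions the 500 cells around the symmetric middle band
(`tau = 0.5591` on the score scale); `coef(fit)` returns the per-cell
scores and `plot(fit, "PRG4")` draws the Z-Z plot. The zonal tables for a
gene:

```r
ct <- zonal_dot_count(fit$zmat, fit$scores, "PRG4")
ct
#> Zonal dot counts for PRG4 (500 cells)
#>             non_expressing z_below_0 z_above_0
#> superficial             41         5       107
#> middle                  76        63        67
#> deep                    50        72        19
zonal_dot_percentage(ct, fit$zmat)
#> Zonal dot percentages for PRG4
#>   superficial  73.2% expressing
#>   middle       63.1% expressing
#>   deep         64.5% expressing
#>   total expression 6905; mean/cell 13.81; mean/expressing 20.74
```

PRG4, a superficial marker, is most often expressed — and most often above
its population mean (107 of 153 cells) — in the superficial zone. Because
the simulation carries ground truth, recovery is measurable:

```r
rec <- evaluate_recovery(sim$truth, fit$scores)
#> depth Spearman 0.850, zone accuracy 0.726
```

the score correlates 0.85 with (negative) latent depth and 72.6% of cells
land in their true depth tertile. Co-expression discovery on the
PRG4-high cells (z > 1):

```r
high <- multi_gene_mask(fit$zmat, "PRG4")   # z > 1 by default
spearman_discovery(fit$zmat, "PRG4", subset = fit$zmat$barcodes[high])
```

returns a ranking of genes by |Spearman rho| with BH-adjusted q-values and
a co-positivity column; `refine_cluster()` iterates the search inside a
multi-gene mask.

A command-line interface chains the same steps from files
(`simulate`, `preprocess`, `zzplot`, `tables`, `coexpress`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "zonate", package = "zonate"))')
Rscript $CLI simulate   --out sim --seed 11 --n-cells 500 --n-genes 100
Rscript $CLI preprocess --input sim --out cache
Rscript $CLI zzplot     --input cache --gene PRG4 --overlay IGFBP5 --out zz
Rscript $CLI coexpress  --input cache --sentinel PRG4 --out co
```

Every command writes a resolved `config.json` next to its outputs, logs to
stderr, and exits non-zero on error.

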