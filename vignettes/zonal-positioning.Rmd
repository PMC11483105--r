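---
title: "Virtual zonal positioning of chondrocytes: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual zonal positioning of chondrocytes: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zonate)
```

## The problem

Articular cartilage is organized into superficial, middle and deep
histological zones with distinct mechanical roles and expression programs,
but droplet single-cell RNA-seq dissociates the tissue and discards that
spatial axis. Unsupervised embeddings (tSNE/UMAP over principal components)
recover *clusters*, not *positions*: two chondrocytes at the same depth can
land in different clusters and vice versa. `zonate` instead places every
cell on an interpretable one-dimensional axis built from prior biological
knowledge — zone marker genes (ZMGs) identified by serial-section bulk
RNA-seq and proteomics — and layers the rest of its analyses (Z-Z plots,
zonal tables, co-expression discovery) on that axis.

## The model

### Normalization

Raw UMI counts are scaled per cell so that a fixed quantile of each cell's
*nonzero* counts is equal across cells ("trimmed quantile normalization",
an upper-quartile-family method):

1. rank genes by dataset-wide total count and set aside the top `trim_frac`
   fraction (default 0.05) — a few ultra-abundant transcripts otherwise
   dominate the per-cell quantile;
2. for each cell \(c\), let \(q_c\) be the `quantile` (default 0.75)
   of its nonzero counts among the remaining genes;
3. scale cell \(c\) by \(\mathrm{median}_c(q)/q_c\).

Zeros stay zeros, so the dropout pattern is preserved exactly. A cell with
no nonzero untrimmed counts is an error (it cannot be scaled), named by
barcode. Both parameters are exposed so users can substitute a different
member of the family; the quantile must lie in (0,1), the trim fraction in
[0, 0.25).

### Per-gene z-scores

Each gene's normalized values are standardized with moments taken over
**all** cells, dropouts included, using the population (divide-by-\(n\))
standard deviation:

\[ E_{g,c} = \frac{v_{g,c} - \mu_g}{\sigma_g}. \]

This convention makes \(z = 0\) literally the gene's population mean, which
fixes the geometry of the Z-Z plot: the "mean with dropouts" guide line sits
exactly on the Y axis. Whether the original tool standardized over all
cells or expressing cells only is not observable from its outputs; the
all-cells convention is the default here and the alternative is available
via `zscore(..., moments = "expressing")`, under which dropouts receive
negative z rather than sitting at the gene mean. Genes with zero variance
get \(z \equiv 0\) and a `noninformative` flag instead of propagating NaN
into the signature score.

### The zonal signature score

With superficial markers \(S\) (defaults PRG4, IGFBP5, CHI3L1, OGN) and
deep markers \(D\) (COL10A1, IBSP, CLEC3A, F13A1), each cell's zonal score
is the difference of weighted mean marker z-scores:

\[ Z_c \;=\; \frac{\sum_{g \in S} w_g E_{g,c}}{\sum_{g \in S} w_g}
        \;-\; \frac{\sum_{g \in D} w_g E_{g,c}}{\sum_{g \in D} w_g}. \]

Weights default to 1, reducing each term to the plain mean over the list —
the uniform \(1/|S|\), \(1/|D|\) form. The score is exactly antisymmetric
under exchanging the lists and linear in the expression matrix; both
properties are enforced by tests against a brute-force per-cell loop.
Markers absent from a dataset are dropped with a warning and the divisor
shrinks with the list — zero-filling absent markers would bias every score
toward zero. An empty effective list is an error.

### Zone assignment

Cells with \(Z_c > \tau\) are called superficial, \(Z_c < -\tau\) deep, the
rest middle; the middle band is symmetric about zero and boundary ties go
inward (conservative calls). No published value of \(\tau\) exists, so the
default is *relative*: \(\tau = 0.5 \cdot \mathrm{sd}(Z_c)\), which adapts
the band to the signature strength of the dataset; an absolute \(\tau\) can
be supplied instead (`tau_mode = "absolute"`). This data-driven default is
a declared choice of this package, not a reconstruction of the original
tool's constants.

## The Z-Z plot and its tables

A Z-Z plot for gene \(g\) places each cell at \((E_{g,c}, Z_c)\). Cells
with zero raw count form the dropout lane at \(x = 0\) on the Y axis; they
are excluded from expressing-cell statistics. In rendered output only, the
lane is jittered horizontally by a deterministic ±0.02 per cell for
visibility — the underlying data keep \(x = 0\) exactly, and the jitter is
a pure function of the cell index so renders stay byte-identical. Two
horizontal lines at \(\pm\tau\) mark the zone boundaries; two vertical
lines mark the mean expression with dropouts (at \(x = 0\) under the
all-cells convention) and without dropouts, each annotated with the mean
*normalized intensity* (not the z value). The co-expression overlay colors
each expressing cell by a second gene's z-score on a diverging scale
centered at 0 and clipped at ±3 so color is comparable across genes.

The zonal dot count table tallies all cells into nine compartments — three
zones crossed with non-expressing / expressing with \(z < 0\) / expressing
with \(z > 0\). Expressing cells with \(z\) exactly 0 (possible only for
degenerate genes) go to the \(z > 0\) column, keeping exactly nine
categories rather than inventing a tenth "at the mean" bucket. The
percentage table derives per-zone percent expressing and the total/mean
expression statistics from normalized values; raw counts would make the
means depend on sequencing depth per cell.

## Co-expression discovery

`spearman_discovery()` ranks candidate genes by \(|\rho|\) of their
Spearman correlation with a sentinel gene over a cell subset (typically the
sentinel-high cells, \(z > 1\), reusing the conventional strong-expression
cutoff). Correlations are computed on normalized values with average-rank
ties; since per-gene z-scoring is monotone, ranks — hence \(\rho\) — are
identical either way. Two-sided p-values use the t approximation
\(t = \rho\sqrt{(n-2)/(1-\rho^2)}\); Benjamini–Hochberg q-values are
attached because a ranked exploratory list without an error-rate column
invites over-reading. Candidates expressed in fewer than
`min_expressing_frac` (default 0.1) of the subset are skipped: their ranks
are dominated by tied zeros. A `co_pos_frac` column (fraction of subset
cells expressing both genes) is provided as a secondary, count-based sort
key for users who read "most frequently co-expressed" as a frequency rather
than a correlation criterion; \(|\rho|\) stays the primary order.
`multi_gene_mask()` composes strong-expression conjunctions across genes,
and `refine_cluster()` re-runs discovery inside a mask while recording the
chain of masks applied.

## The synthetic generator

`simulate_zonal_counts()` provides ground truth the real accessions cannot:
each cell has a latent depth \(d \sim U(0,1)\) (0 = most superficial), true
zones are the depth tertiles, superficial markers have negative binomial
mean \(\mu_0 e^{-kd}\), deep markers \(\mu_0 e^{-k(1-d)}\), and other genes
a depth-independent baseline drawn once per gene from a lognormal; every
entry is then independently zeroed with the dropout probability. Defaults:
2000 cells, 200 genes, \(k = 2\), dropout 0.3, marker \(\mu_0 = 50\),
negative binomial size 6, baselines lognormal(1, 1) — chosen once as a
realistic regime for abundant zonal markers in droplet data (high home-zone
expression, moderate overdispersion). Under these defaults the pipeline
recovers depth with Spearman \(\ge 0.85\) and zone accuracy ≈ 0.71–0.73
across seeds; the accuracy margin over chance is bounded mainly by the
\(\tau = 0.5\,\mathrm{sd}\) band's imperfect alignment with exact tertiles,
not by the score itself.

The optional planted co-expression cluster uses a *multiplicative* shared
activity: cluster cells draw \(a_c = \text{fold} \times
\mathrm{lognormal}(0, 0.6)\) and every planted gene's mean is
\(\text{base} \times a_c\) there (base 3, fold 8, 30% of cells, NB size 50
— a tight, strongly induced program). The multiplicative form matters:
conditioning on one planted gene being high (the sentinel-high subset)
truncates the activity distribution, and an additive bump leaves too little
shared variation to recover partners from within the subset; proportional
scaling preserves rank correlation after conditioning.

What the generator does **not** emulate: expression-dependent dropout,
batch effects, doublets, ambient RNA, gene–gene correlation beyond the
planted module, or a realistic cartilage transcriptome. Passing recovery
tests on this generator therefore demonstrates that the estimator works
when its assumptions hold — monotone marker gradients and independent
technical noise — not that any particular tissue satisfies them.

A dropout rate of 1 is rejected rather than accepted-and-broken: it would
produce all-zero cells that violate the normalization precondition.

## Numerical and interface choices

- All randomness in the generator flows from one user-supplied seed through
  a private RNG stream; the caller's `.Random.seed` is restored afterwards.
- Quantiles use R's default type-7 definition; the trim picks the top
  `floor(trim_frac * n_genes)` genes with a stable order, so trimming is
  deterministic under ties.
- Gene symbols are case-folded to uppercase at ingestion; marker matching
  and lookups are case-insensitive, and failed lookups list near-matches.
  Duplicate symbols after case-folding are an error by default; an explicit
  `duplicates = "sum"` collapses them, because silent collapsing changes
  the signature-score inputs.
- MatrixMarket indices are 1-based on disk (per the standard) and handled
  by the Matrix package; all in-memory structures are ordinary R matrices.
- SVG output is written by the package's own serializer with fixed-format
  numbers, so two renders of the same plot data are byte-identical — a
  property the test suite asserts and the CLI relies on for reproducible
  pipelines. PNG output goes through the base graphics device.
- The preprocessing cache is a directory of plain TSVs plus a `meta.json`
  version stamp; a stale version is an explicit error, never a silent
  re-parse.
- The processed-data serialization is this package's own format; the
  original tool's internal storage layout is not described anywhere and no
  attempt is made to guess it.

## Problem sizes in the test suite

The suite exercises the oracle equivalences on 100 random matrices (up to
50 genes × 30 cells) for the score kernel, 1000 random instances for the
nine-compartment tally, and 25 tied-data instances for the Spearman kernel;
recovery checks use the full default generator (2000 × 200) at fixed seeds,
20 flat-gradient replicates for the null envelope, and 10 seeds for the
marker-zonation direction check. These sizes were chosen to make the
brute-force oracles exhaustive at desk scale while keeping the default
suite comfortably under a minute.

## Known limitations

- Three zones only; the middle/transitional zone is defined by exclusion,
  not by its own markers.
- ZMGs are consumed as configuration; learning better marker sets from data
  is out of scope.
- The zonal axis is relative within a dataset (z-scores and a relative
  \(\tau\)); scores are not comparable across datasets without a shared
  normalization.
- No statistical tests are attached to the zonal tables — they are raw
  tallies by design.
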