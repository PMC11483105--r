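Package: zonate
Title: Virtual Zonal Positioning of Articular Cartilage Chondrocytes from
    Single-Cell RNA-Seq
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Positions dissociated chondrocytes from single-cell RNA-seq of
    articular cartilage along a virtual superficial-to-deep zonal axis using a
    marker-gene signature score computed on z-scored, trimmed
    quantile-normalized UMI counts. Provides the zone-versus-z-score ("Z-Z")
    scatter representation with an explicit dropout lane, zonal dot count and
    percentage tables, sentinel-gene Spearman co-expression discovery with
    iterative multi-gene cluster masks, a ground-truth synthetic data
    generator for zonally stratified counts, and a command-line interface
    chaining the steps into a batch workflow.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    data.table,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
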