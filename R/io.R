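#' Read a 10x-style MatrixMarket count triplet
#'
#' Ingests the standard 10x Genomics directory layout: `matrix.mtx`,
#' `barcodes.tsv` and `features.tsv` (or `genes.tsv`), each optionally
#' gzipped. Genes are rows in the MatrixMarket file; entries absent from the
#' coordinate triplet are zeros.
#'
#' @param directory path to the triplet directory.
#' @param duplicates duplicate-gene-symbol policy, see [count_matrix()].
#' @return a [count_matrix()].
#' @export
read_counts_mtx <- function(directory, duplicates = c("error", "sum")) {
  duplicates <- match.arg(duplicates)
  if (!dir.exists(directory)) {
    stop(sprintf("input directory not found: %s", directory))
  }
  find1 <- function(stems) {
    for (stem in stems) for (ext in c("", ".gz")) {
      p <- file.path(directory, paste0(stem, ext))
      if (file.exists(p)) return(p)
    }
    stop(sprintf("missing file: %s (or .gz) in %s", stems[1L], directory))
  }
  mtx_path <- find1("matrix.mtx")
  bc_path <- find1("barcodes.tsv")
  ft_path <- find1(c("features.tsv", "genes.tsv"))

  m <- tryCatch({
    con <- if (grepl("\\.gz$", mtx_path)) gzfile(mtx_path) else file(mtx_path)
    Matrix::readMM(con)
  }, error = function(e) {
    stop(sprintf("failed to parse MatrixMarket file %s: %s",
                 mtx_path, conditionMessage(e)))
  })

  read_col <- function(path) {
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
                            colClasses = "character", data.table = FALSE)
    dt
  }
  bc <- read_col(bc_path)
  ft <- read_col(ft_path)
  # 10x features files carry (id, symbol[, type]); bare symbol lists have one
  # column
  symbols <- if (ncol(ft) >= 2L) ft[[2L]] else ft[[1L]]
  if (nrow(ft) != nrow(m)) {
    stop(sprintf("format error: %d features for %d matrix rows in %s",
                 nrow(ft), nrow(m), directory))
  }
  if (nrow(bc) != ncol(m)) {
    stop(sprintf("format error: %d barcodes for %d matrix columns in %s",
                 nrow(bc), ncol(m), directory))
  }
  count_matrix(as.matrix(m), genes = symbols, barcodes = bc[[1L]],
               duplicates = duplicates)
}

#' Write a count matrix as a MatrixMarket triplet
#'
#' Inverse of [read_counts_mtx()]: emits `matrix.mtx`, `barcodes.tsv` and
#' `features.tsv` (two columns, id and symbol) into `directory`.
#'
#' @param cm a [count_matrix()].
#' @param directory output directory (created if absent).
#' @export
write_counts_mtx <- function(cm, directory) {
  stopifnot(inherits(cm, "count_matrix"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  sm <- Matrix::Matrix(cm$counts, sparse = TRUE)
  Matrix::writeMM(sm, file.path(directory, "matrix.mtx"))
  writeLines(cm$barcodes, file.path(directory, "barcodes.tsv"))
  writeLines(paste(cm$genes, cm$genes, sep = "\t"),
             file.path(directory, "features.tsv"))
  invisible(NULL)
}

#' Read a dense TSV/CSV count matrix
#'
#' @param path file path; delimiter inferred from the extension (`.csv` is
#'   comma-separated, anything else tab-separated). A header row and a first
#'   column of labels are required.
#' @param genes_in whether genes are on-disk rows or columns; the returned
#'   matrix is always oriented genes x cells.
#' @param duplicates duplicate-gene-symbol policy, see [count_matrix()].
#' @return a [count_matrix()].
#' @export
read_counts_dense <- function(path, genes_in = c("rows", "columns"),
                              duplicates = c("error", "sum")) {
  genes_in <- match.arg(genes_in)
  duplicates <- match.arg(duplicates)
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path))
  }
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  dt <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE)
  labels <- as.character(dt[[1L]])
  body <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(body)) {
    stop(sprintf("format error in %s: non-numeric entries", path))
  }
  bad <- which(body < 0 | body != round(body), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    ex <- bad[seq_len(min(5L, nrow(bad))), , drop = FALSE]
    stop(sprintf(
      "format error in %s: non-integer or negative entries at (row,col): %s",
      path, paste(sprintf("(%d,%d)", ex[, 1L], ex[, 2L]), collapse = ", ")))
  }
  if (genes_in == "rows") {
    count_matrix(body, genes = labels, barcodes = colnames(body),
                 duplicates = duplicates)
  } else {
    count_matrix(t(body), genes = colnames(body), barcodes = labels,
                 duplicates = duplicates)
  }
}

#' Zone marker gene set
#'
#' Holds the superficial and deep zone marker gene (ZMG) lists used by the
#' zonal signature score, with optional positive per-gene weights (default 1,
#' which reduces the weighted mean to the plain arithmetic mean over each
#' list).
#'
#' @param superficial,deep character vectors of gene symbols; case-folded to
#'   uppercase, must be non-empty and disjoint.
#' @param weights optional named numeric vector of positive weights; genes not
#'   named default to 1.
#' @return an object of class `zmg_set`.
#' @export
zmg_set <- function(superficial, deep, weights = NULL) {
  superficial <- toupper(as.character(superficial))
  deep <- toupper(as.character(deep))
  if (length(superficial) == 0L || length(deep) == 0L) {
    stop("config error: superficial and deep marker lists must be non-empty")
  }
  if (anyDuplicated(superficial) || anyDuplicated(deep)) {
    stop("config error: duplicated symbols within a marker list")
  }
  both <- intersect(superficial, deep)
  if (length(both) > 0) {
    stop(sprintf("config error: genes in both zones: %s",
                 paste(both, collapse = ", ")))
  }
  all_genes <- c(superficial, deep)
  w <- setNames(rep(1, length(all_genes)), all_genes)
  if (!is.null(weights)) {
    if (is.null(names(weights))) stop("config error: weights must be named")
    names(weights) <- toupper(names(weights))
    unknown <- setdiff(names(weights), all_genes)
    if (length(unknown) > 0) {
      stop(sprintf("config error: weights for genes not in either list: %s",
                   paste(unknown, collapse = ", ")))
    }
    if (any(!is.finite(weights) | weights <= 0)) {
      stop("config error: weights must be positive and finite")
    }
    w[names(weights)] <- weights
  }
  structure(list(superficial = superficial, deep = deep, weights = w),
            class = "zmg_set")
}

#' @export
print.zmg_set <- function(x, ...) {
  cat(sprintf("zmg_set: %d superficial (%s), %d deep (%s)\n",
              length(x$superficial), paste(x$superficial, collapse = ", "),
              length(x$deep), paste(x$deep, collapse = ", ")))
  if (any(x$weights != 1)) {
    nz <- x$weights[x$weights != 1]
    cat("  non-unit weights:",
        paste(sprintf("%s=%g", names(nz), nz), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a zone-marker configuration file
#'
#' Accepts JSON (`.json`) or YAML (`.yml`/`.yaml`) with keys `superficial`,
#' `deep` and optionally `weights` (a gene-to-weight map).
#'
#' @param path config file path.
#' @return a [zmg_set()].
#' @export
read_zmg_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path))
  }
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  if (is.null(cfg$superficial) || is.null(cfg$deep)) {
    stop(sprintf("config error in %s: keys 'superficial' and 'deep' required",
                 path))
  }
  w <- cfg$weights
  if (!is.null(w)) w <- unlist(w)
  zmg_set(cfg$superficial, cfg$deep, weights = w)
}

#' Default articular-cartilage zone markers
#'
#' The packaged default marker configuration: PRG4, IGFBP5, CHI3L1 and OGN for
#' the superficial zone; COL10A1, IBSP, CLEC3A and F13A1 for the deep zone.
#' These are the canonical chondrocyte zonation markers derived from
#' serial-section bulk transcriptomic and proteomic profiling of articular
#' cartilage.
#'
#' @return a [zmg_set()].
#' @export
zmg_default <- function() {
  read_zmg_config(system.file("extdata", "zmg_default.json",
                              package = "zonate", mustWork = TRUE))
}

#' Write a tabular result to CSV or JSON
#'
#' Serializes any of the package's tabular results (zonal dot tables,
#' co-expression rankings, enrichment tables, plain data frames). Numbers are
#' written at full precision so a read-back reproduces integers exactly and
#' reals to at least six significant digits.
#'
#' @param table a data frame or a package table object with an
#'   `as.data.frame` method.
#' @param path output file path.
#' @param format `"csv"` (RFC 4180) or `"json"`.
#' @export
write_table <- function(table, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(table)
  if (format == "csv") {
    ok <- tryCatch({
      write.csv(df, path, row.names = FALSE, quote = TRUE)
      TRUE
    }, error = function(e) e, warning = function(w) w)
    if (!isTRUE(ok)) {
      stop(sprintf("I/O error writing %s: %s", path, conditionMessage(ok)))
    }
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA,
                         auto_unbox = FALSE)
  }
  invisible(NULL)
}
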