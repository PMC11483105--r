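#' Build the Z-Z plot data for a gene
#'
#' The Z-Z plot places every cell at (x = the gene's z-score, y = the cell's
#' zonal score). Cells not expressing the gene (raw count zero) form the
#' dropout lane on the Y axis at x = 0 and are excluded from expressing-cell
#' statistics. Two horizontal guide lines at +tau and -tau separate the
#' superficial, middle and deep bands; two vertical guide lines mark the mean
#' expression with dropouts (x = 0 under the all-cells z convention) and the
#' mean over expressing cells only, each annotated with the corresponding
#' mean normalized intensity.
#'
#' @param z a `zscore_matrix`.
#' @param zones a `zonal_scores` on the same cells.
#' @param gene gene symbol for the X axis.
#' @return an object of class `zzplot_data`: list with `gene`, `cells` (data
#'   frame barcode/x/y/dropout/zone/color), `hlines`, `vlines` (positions and
#'   mean-intensity annotations), `mode` (`"single"`) and `overlay_gene`
#'   (`NA`).
#' @export
build_zzplot <- function(z, zones, gene) {
  stopifnot(inherits(z, "zscore_matrix"), inherits(zones, "zonal_scores"))
  if (!identical(z$barcodes, zones$barcodes)) {
    stop("z-score matrix and zonal scores refer to different cells")
  }
  i <- .resolve_gene(gene, z$genes)
  gene <- z$genes[i]
  dropout <- z$dropout[i, ]
  x <- ifelse(dropout, 0, z$z[i, ])
  cells <- data.frame(barcode = z$barcodes, x = x, y = zones$Zc,
                      dropout = dropout, zone = zones$zone,
                      color = NA_real_,
                      row.names = NULL, stringsAsFactors = FALSE)
  sm <- expression_summaries(z, gene)
  gs <- z$gene_stats[i, ]
  # expressing-cell mean on the z scale; degenerate genes pin both lines at 0
  x_right <- if (sm$n_expressing > 0 && gs$sd > 0) {
    (sm$mean_without_dropouts - gs$mean) / gs$sd
  } else 0
  vlines <- data.frame(
    which = c("with_dropouts", "without_dropouts"),
    x = c(0, x_right),
    value = c(sm$mean_with_dropouts, sm$mean_without_dropouts),
    stringsAsFactors = FALSE)
  structure(list(gene = gene, cells = cells,
                 hlines = c(upper = zones$tau, lower = -zones$tau),
                 vlines = vlines, mode = "single",
                 overlay_gene = NA_character_),
            class = "zzplot_data")
}

#' @export
print.zzplot_data <- function(x, ...) {
  cat(sprintf("zzplot_data: gene %s, %d cells (%d dropouts), mode %s%s\n",
              x$gene, nrow(x$cells), sum(x$cells$dropout), x$mode,
              if (x$mode == "overlay") paste0(" (", x$overlay_gene, ")") else ""))
  invisible(x)
}

#' Overlay a second gene as a heat color
#'
#' Co-expression mode: each cell expressing the primary gene is colored by
#' the z-score of `second_gene` (diverging scale, centered at 0, clipped at
#' +/-3 when rendered); dropout-lane cells keep no color value. Cells with
#' high z in both genes stand out in the top-right of the plot.
#'
#' @param plot a `zzplot_data` built in single mode.
#' @param z the `zscore_matrix` the plot came from.
#' @param second_gene gene symbol supplying the heat values.
#' @return the `zzplot_data` with `color` filled, `mode = "overlay"`.
#' @export
overlay_coexpression <- function(plot, z, second_gene) {
  stopifnot(inherits(plot, "zzplot_data"), inherits(z, "zscore_matrix"))
  if (plot$mode != "single") {
    stop("overlay must start from a single-mode plot")
  }
  i <- .resolve_gene(second_gene, z$genes)
  if (!identical(plot$cells$barcode, z$barcodes)) {
    stop("plot and z-score matrix refer to different cells")
  }
  col <- z$z[i, ]
  col[plot$cells$dropout] <- NA_real_
  plot$cells$color <- col
  plot$mode <- "overlay"
  plot$overlay_gene <- z$genes[i]
  plot
}

#' Select cells from a Z-Z plot
#'
#' Conjunction of criteria over the plotted cells: zone membership, x and y
#' ranges, dropout exclusion, and z-score thresholds on further genes
#' (`gene_z`, a named vector meaning z\[gene\] > threshold for every listed
#' gene — the multi-gene strong-expression mask, default convention z > 1).
#' At least one criterion must be supplied. The returned selection records
#' its criteria for provenance and is reproducible from the same plot.
#'
#' @param plot a `zzplot_data`.
#' @param criteria list with any of: `zones` (character subset of
#'   superficial/middle/deep), `x_range` (length-2 numeric), `y_range`
#'   (length-2 numeric), `exclude_dropouts` (TRUE to drop the dropout lane),
#'   `gene_z` (named numeric thresholds).
#' @param z a `zscore_matrix`, required when `gene_z` is used.
#' @return an object of class `cell_selection`: list with `barcodes`,
#'   `criteria` and the source `gene`.
#' @export
select_cells <- function(plot, criteria, z = NULL) {
  stopifnot(inherits(plot, "zzplot_data"))
  if (!is.list(criteria)) stop("criteria must be a list")
  known <- c("zones", "x_range", "y_range", "exclude_dropouts", "gene_z")
  unknown <- setdiff(names(criteria), known)
  if (length(unknown) > 0) {
    stop(sprintf("unknown criteria: %s", paste(unknown, collapse = ", ")))
  }
  active <- !vapply(criteria, is.null, logical(1))
  # exclude_dropouts = FALSE selects nothing by itself
  if (isFALSE(criteria$exclude_dropouts)) active[["exclude_dropouts"]] <- FALSE
  if (!any(active)) {
    stop("parameter error: criteria must select on something")
  }
  keep <- rep(TRUE, nrow(plot$cells))
  if (!is.null(criteria$zones)) {
    zs <- match.arg(criteria$zones, c("superficial", "middle", "deep"),
                    several.ok = TRUE)
    keep <- keep & plot$cells$zone %in% zs
  }
  if (!is.null(criteria$x_range)) {
    r <- criteria$x_range
    if (length(r) != 2L || !all(is.finite(r))) {
      stop("x_range must be two finite numbers")
    }
    keep <- keep & plot$cells$x >= min(r) & plot$cells$x <= max(r)
  }
  if (!is.null(criteria$y_range)) {
    r <- criteria$y_range
    if (length(r) != 2L || !all(is.finite(r))) {
      stop("y_range must be two finite numbers")
    }
    keep <- keep & plot$cells$y >= min(r) & plot$cells$y <= max(r)
  }
  if (isTRUE(criteria$exclude_dropouts)) {
    keep <- keep & !plot$cells$dropout
  }
  if (!is.null(criteria$gene_z)) {
    thr <- criteria$gene_z
    if (is.null(names(thr)) || !is.numeric(thr) || !all(is.finite(thr))) {
      stop("gene_z must be a named vector of finite thresholds")
    }
    if (is.null(z)) {
      stop("gene_z criteria require the z-score matrix (argument z)")
    }
    for (g in names(thr)) {
      i <- .resolve_gene(g, z$genes)
      keep <- keep & z$z[i, ] > thr[[g]]
    }
  }
  structure(list(barcodes = plot$cells$barcode[keep],
                 criteria = criteria[active],
                 gene = plot$gene),
            class = "cell_selection")
}

#' @export
print.cell_selection <- function(x, ...) {
  cat(sprintf("cell_selection: %d cells (from %s plot; criteria: %s)\n",
              length(x$barcodes), x$gene,
              paste(names(x$criteria), collapse = ", ")))
  invisible(x)
}

#' Write a cell selection to disk
#'
#' Writes a single-column barcode TSV plus a JSON sidecar (`<path>.json`)
#' recording the selection criteria for provenance.
#'
#' @param selection a `cell_selection`.
#' @param path output TSV path.
#' @export
write_selection <- function(selection, path) {
  stopifnot(inherits(selection, "cell_selection"))
  writeLines(c("barcode", selection$barcodes), path)
  jsonlite::write_json(list(gene = selection$gene,
                            n_cells = length(selection$barcodes),
                            criteria = selection$criteria),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

# ---- rendering -------------------------------------------------------------

.ZONE_COLORS <- c(superficial = "#d62728", middle = "#7f7f7f",
                  deep = "#1f77b4")

# diverging heat color for overlay values, centered at 0, clipped at +/-3
.heat_color <- function(v) {
  out <- rep("#bbbbbb", length(v))
  ok <- is.finite(v)
  x <- pmin(pmax(v[ok], -3), 3) / 3
  lerp <- function(a, b, t) round(a + (b - a) * t)
  lo <- c(33, 102, 172)    # blue
  mid <- c(247, 247, 247)  # near-white
  hi <- c(230, 97, 1)      # orange
  cols <- vapply(x, function(t) {
    rgb_ <- if (t < 0) {
      c(lerp(mid[1], lo[1], -t), lerp(mid[2], lo[2], -t), lerp(mid[3], lo[3], -t))
    } else {
      c(lerp(mid[1], hi[1], t), lerp(mid[2], hi[2], t), lerp(mid[3], hi[3], t))
    }
    sprintf("#%02x%02x%02x", rgb_[1], rgb_[2], rgb_[3])
  }, character(1))
  out[ok] <- cols
  out
}

# deterministic per-cell horizontal jitter for the dropout lane (render only;
# the data keep x = 0 exactly)
.lane_jitter <- function(idx) {
  (((idx * 7919) %% 1000) / 1000) * 0.04 - 0.02
}

.zz_point_colors <- function(pd) {
  if (pd$mode == "overlay") {
    .heat_color(pd$cells$color)
  } else {
    unname(.ZONE_COLORS[as.character(pd$cells$zone)])
  }
}

.zz_limits <- function(pd) {
  xs <- c(pd$cells$x, pd$vlines$x)
  ys <- c(pd$cells$y, pd$hlines)
  pad <- function(r) {
    span <- diff(r)
    if (span == 0) span <- 1
    c(r[1] - 0.05 * span, r[2] + 0.05 * span)
  }
  list(x = pad(range(xs)), y = pad(range(ys)))
}

# base-graphics drawing shared by plot.zonate and the png render
.zz_draw <- function(pd, cex = 0.5, ...) {
  lim <- .zz_limits(pd)
  cols <- .zz_point_colors(pd)
  x <- pd$cells$x
  x[pd$cells$dropout] <- x[pd$cells$dropout] +
    .lane_jitter(which(pd$cells$dropout))
  graphics::plot(x, pd$cells$y, col = cols, pch = 16, cex = cex,
                 xlim = lim$x, ylim = lim$y,
                 xlab = "", ylab = "zonal score", ...)
  abline(h = pd$hlines, lty = 2, col = "#444444")
  abline(v = pd$vlines$x, lty = 3, col = "#444444")
  text(pd$vlines$x, lim$y[2], sprintf("%.3f", pd$vlines$value),
       pos = 4, cex = 0.8, col = "#444444")
  mtext(pd$gene, side = 1, line = 2.5)
  if (pd$mode == "overlay") {
    title(main = sprintf("%s (heat: %s)", pd$gene, pd$overlay_gene))
  } else {
    legend("topright", legend = names(.ZONE_COLORS), col = .ZONE_COLORS,
           pch = 16, cex = 0.8, bty = "n")
  }
  invisible(NULL)
}

# deterministic hand-written SVG serialization of the plot specification;
# identical zzplot_data always yields byte-identical output
.zz_svg <- function(pd) {
  W <- 720; H <- 560
  ml <- 70; mr <- 150; mt <- 40; mb <- 70
  pw <- W - ml - mr; ph <- H - mt - mb
  lim <- .zz_limits(pd)
  sx <- function(x) ml + (x - lim$x[1]) / diff(lim$x) * pw
  sy <- function(y) mt + (lim$y[2] - y) / diff(lim$y) * ph
  num <- function(v) sprintf("%.4f", v)
  cols <- .zz_point_colors(pd)
  x <- pd$cells$x
  x[pd$cells$dropout] <- x[pd$cells$dropout] +
    .lane_jitter(which(pd$cells$dropout))
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            W, H, W, H),
    sprintf('<rect x="0" y="0" width="%d" height="%d" fill="white"/>', W, H),
    sprintf('<rect x="%d" y="%d" width="%d" height="%d" fill="none" stroke="#000000"/>',
            ml, mt, pw, ph))
  # horizontal zone boundaries
  for (h in pd$hlines) {
    out <- c(out, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#444444" stroke-dasharray="6,4"/>',
      num(sx(lim$x[1])), num(sy(h)), num(sx(lim$x[2])), num(sy(h))))
  }
  # vertical mean lines with intensity annotations
  for (i in seq_len(nrow(pd$vlines))) {
    vx <- pd$vlines$x[i]
    out <- c(out,
      sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#444444" stroke-dasharray="2,3"/>',
              num(sx(vx)), num(sy(lim$y[1])), num(sx(vx)), num(sy(lim$y[2]))),
      sprintf('<text x="%s" y="%s" font-size="11" fill="#444444">%s</text>',
              num(sx(vx) + 3), num(mt + 12 + 14 * (i - 1)),
              sprintf("%.3f", pd$vlines$value[i])))
  }
  out <- c(out, vapply(seq_len(nrow(pd$cells)), function(i) {
    sprintf('<circle class="cell" cx="%s" cy="%s" r="2.5" fill="%s" fill-opacity="0.8"/>',
            num(sx(x[i])), num(sy(pd$cells$y[i])), cols[i])
  }, character(1)))
  # axes labels, gene symbol below the X axis, legend
  out <- c(out,
    sprintf('<text x="%s" y="%s" font-size="14" text-anchor="middle">%s</text>',
            num(ml + pw / 2), num(H - 20), pd$gene),
    sprintf('<text x="18" y="%s" font-size="13" transform="rotate(-90 18 %s)" text-anchor="middle">zonal score</text>',
            num(mt + ph / 2), num(mt + ph / 2)))
  if (pd$mode == "overlay") {
    out <- c(out, sprintf(
      '<text x="%d" y="24" font-size="13">heat: %s z-score (clipped at +/-3)</text>',
      ml, pd$overlay_gene))
  } else {
    zn <- names(.ZONE_COLORS)
    for (i in seq_along(zn)) {
      yy <- mt + 20 * i
      out <- c(out,
        sprintf('<circle cx="%d" cy="%d" r="5" fill="%s"/>',
                W - mr + 20, yy, .ZONE_COLORS[[zn[i]]]),
        sprintf('<text x="%d" y="%d" font-size="12">%s</text>',
                W - mr + 32, yy + 4, zn[i]))
    }
  }
  c(out, "</svg>")
}

#' Render a Z-Z plot to a static file
#'
#' `svg` output is written by the package's own plot serializer and is
#' byte-identical across renders of the same plot data; `png` goes through
#' the base graphics device; `html` embeds the svg in a minimal page.
#'
#' @param plot a `zzplot_data`.
#' @param path output file path.
#' @param format `"svg"`, `"png"` or `"html"`.
#' @export
render_zzplot <- function(plot, path, format = c("svg", "png", "html")) {
  stopifnot(inherits(plot, "zzplot_data"))
  if (length(format) == 1L && !format %in% c("svg", "png", "html")) {
    stop(sprintf("parameter error: unsupported format '%s'", format))
  }
  format <- match.arg(format)
  if (format == "svg") {
    writeLines(.zz_svg(plot), path)
  } else if (format == "png") {
    png(path, width = 720, height = 560)
    on.exit(dev.off())
    .zz_draw(plot)
  } else {
    html <- c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\"/>",
              sprintf("<title>Z-Z plot: %s</title></head><body>", plot$gene),
              .zz_svg(plot)[-1L],  # drop the xml prolog inside html
              "</body></html>")
    writeLines(html, path)
  }
  invisible(NULL)
}
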