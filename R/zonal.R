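#' Per-cell zonal signature score
#'
#' The zonal score of a cell is the weighted mean z-score of the superficial
#' zone markers minus the weighted mean z-score of the deep zone markers:
#' \deqn{Z_c = \frac{\sum_{g \in S} w_g E_{g,c}}{\sum_{g \in S} w_g} -
#'             \frac{\sum_{g \in D} w_g E_{g,c}}{\sum_{g \in D} w_g}}
#' where \eqn{E_{g,c}} is the z-score expression of gene g in cell c. With
#' unit weights (the default) each term is the plain mean over the marker
#' list. Positive scores indicate superficial-like cells, negative deep-like.
#'
#' Marker genes absent from the matrix are dropped with a warning and the
#' divisor shrinks accordingly; a list left empty is an error, since the score
#' is then undefined.
#'
#' @param z a `zscore_matrix` from [zscore()].
#' @param zmg a [zmg_set()].
#' @return named numeric vector of per-cell zonal scores, with the effective
#'   marker set attached as attribute `zmg_used`.
#' @export
zonal_score <- function(z, zmg) {
  stopifnot(inherits(z, "zscore_matrix"), inherits(zmg, "zmg_set"))
  use <- function(lst, side) {
    present <- lst[lst %in% z$genes]
    absent <- setdiff(lst, present)
    if (length(absent) > 0) {
      warning(sprintf("%s markers absent from matrix, dropped: %s",
                      side, paste(absent, collapse = ", ")))
    }
    if (length(present) == 0L) {
      stop(sprintf("all %s markers absent from matrix", side))
    }
    present
  }
  s_genes <- use(zmg$superficial, "superficial")
  d_genes <- use(zmg$deep, "deep")
  wmean <- function(genes) {
    w <- zmg$weights[genes]
    zz <- z$z[match(genes, z$genes), , drop = FALSE]
    colSums(w * zz) / sum(w)
  }
  Zc <- wmean(s_genes) - wmean(d_genes)
  if (anyNA(Zc)) {
    stop("NaN in marker z-scores; zonal score undefined")
  }
  names(Zc) <- z$barcodes
  attr(Zc, "zmg_used") <- zmg_set(s_genes, d_genes,
                                  weights = zmg$weights[c(s_genes, d_genes)])
  Zc
}

#' Assign zone labels from zonal scores
#'
#' Cells with score above `tau` are called superficial, below `-tau` deep,
#' and everything in between (boundaries inclusive) middle — the middle band
#' spreads symmetrically around zero, and ties on the boundary go inward
#' (conservative zonal calls).
#'
#' @param Zc named numeric vector of zonal scores (names are barcodes).
#' @param tau positive boundary threshold (absolute value on the score
#'   scale).
#' @return an object of class `zonal_scores`: list with `barcodes`, `Zc`,
#'   `zone` (factor with levels superficial/middle/deep), `tau`, and
#'   `zmg_used` (carried over from [zonal_score()] when present).
#' @export
assign_zones <- function(Zc, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    stop("parameter error: tau must be a single positive number")
  }
  zone <- factor(ifelse(Zc > tau, "superficial",
                        ifelse(Zc < -tau, "deep", "middle")),
                 levels = c("superficial", "middle", "deep"))
  structure(list(barcodes = names(Zc), Zc = as.numeric(Zc), zone = zone,
                 tau = tau, zmg_used = attr(Zc, "zmg_used")),
            class = "zonal_scores")
}

#' @export
print.zonal_scores <- function(x, ...) {
  comp <- table(x$zone)
  cat(sprintf("zonal_scores: %d cells; tau = %.4g\n", length(x$Zc), x$tau))
  cat(sprintf("  superficial %d | middle %d | deep %d\n",
              comp[["superficial"]], comp[["middle"]], comp[["deep"]]))
  invisible(x)
}

#' Zone composition
#'
#' @param zones a `zonal_scores` object.
#' @return data frame with per-zone cell counts and fractions (counts sum to
#'   the number of cells, fractions to 1).
#' @export
zone_composition <- function(zones) {
  stopifnot(inherits(zones, "zonal_scores"))
  tab <- table(zones$zone)
  data.frame(zone = names(tab), n = as.integer(tab),
             fraction = as.numeric(tab) / length(zones$zone),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit the virtual zonal positioning model
#'
#' The central entry point: takes raw UMI counts and a zone-marker
#' configuration and runs the full pipeline — trimmed quantile normalization,
#' per-gene z-scoring with dropout mask, the zonal signature score, and zone
#' assignment. The result is a fitted object from which Z-Z plots, zonal
#' tables and co-expression rankings are derived.
#'
#' @param counts a [count_matrix()].
#' @param zmg a [zmg_set()]; defaults to the packaged articular-cartilage
#'   markers ([zmg_default()]).
#' @param quantile,trim_frac normalization parameters, see
#'   [trimmed_quantile_normalize()].
#' @param tau zone boundary. In `"relative"` mode (default) the boundary is
#'   `tau * sd(Zc)` so the middle band adapts to the signature strength
#'   (default 0.5 standard deviations); in `"absolute"` mode `tau` is used
#'   directly on the score scale.
#' @param tau_mode `"relative"` or `"absolute"`.
#' @return an object of class `zonate`: list with `zmat` (the
#'   `zscore_matrix`), `scores` (the `zonal_scores`), `zmg`, the resolved
#'   parameters, and the matched call. Methods: [print.zonate()],
#'   [summary.zonate()], [coef.zonate()] (the per-cell scores) and
#'   [plot.zonate()] (the Z-Z plot).
#' @examples
#' sim <- simulate_zonal_counts(n_cells = 120, n_genes = 60, seed = 7)
#' fit <- zonate(sim$counts)
#' fit
#' head(coef(fit))
#' @export
zonate <- function(counts, zmg = zmg_default(), quantile = 0.75,
                   trim_frac = 0.05, tau = 0.5,
                   tau_mode = c("relative", "absolute")) {
  tau_mode <- match.arg(tau_mode)
  stopifnot(inherits(counts, "count_matrix"))
  norm <- trimmed_quantile_normalize(counts, quantile = quantile,
                                     trim_frac = trim_frac)
  zmat <- zscore(norm)
  Zc <- zonal_score(zmat, zmg)
  tau_abs <- if (tau_mode == "relative") tau * sd(Zc) else tau
  if (!is.finite(tau_abs) || tau_abs <= 0) {
    stop("resolved tau is not positive; the zonal score may be degenerate")
  }
  scores <- assign_zones(Zc, tau_abs)
  structure(list(zmat = zmat, scores = scores,
                 zmg = attr(Zc, "zmg_used"),
                 params = list(quantile = quantile, trim_frac = trim_frac,
                               tau = tau, tau_mode = tau_mode,
                               tau_abs = tau_abs),
                 call = match.call()),
            class = "zonate")
}

#' @export
print.zonate <- function(x, ...) {
  comp <- table(x$scores$zone)
  cat("Virtual zonal positioning fit\n")
  cat(sprintf("  %d genes x %d cells\n", nrow(x$zmat$z), ncol(x$zmat$z)))
  cat(sprintf("  markers: %s | %s\n",
              paste(x$zmg$superficial, collapse = ", "),
              paste(x$zmg$deep, collapse = ", ")))
  cat(sprintf("  tau = %.4g (%s); zones: superficial %d, middle %d, deep %d\n",
              x$params$tau_abs, x$params$tau_mode,
              comp[["superficial"]], comp[["middle"]], comp[["deep"]]))
  invisible(x)
}

#' @describeIn zonate per-cell zonal scores as a named vector.
#' @param object,... method arguments.
#' @export
coef.zonate <- function(object, ...) {
  setNames(object$scores$Zc, object$scores$barcodes)
}

#' @export
summary.zonate <- function(object, ...) {
  structure(list(
    n_genes = nrow(object$zmat$z),
    n_cells = ncol(object$zmat$z),
    composition = zone_composition(object$scores),
    score_quantiles = quantile(object$scores$Zc,
                               c(0, 0.25, 0.5, 0.75, 1)),
    tau = object$params$tau_abs,
    tau_mode = object$params$tau_mode,
    zmg = object$zmg,
    pct_dropout = 100 * mean(object$zmat$dropout),
    n_noninformative = sum(object$zmat$gene_stats$noninformative)),
    class = "summary.zonate")
}

#' @export
print.summary.zonate <- function(x, ...) {
  cat("Virtual zonal positioning fit\n")
  cat(sprintf("  %d genes x %d cells; %.1f%% dropouts; %d non-informative genes\n",
              x$n_genes, x$n_cells, x$pct_dropout, x$n_noninformative))
  cat(sprintf("  tau = %.4g (%s)\n", x$tau, x$tau_mode))
  cat("  zone composition:\n")
  for (i in seq_len(nrow(x$composition))) {
    cat(sprintf("    %-11s %6d  (%.1f%%)\n", x$composition$zone[i],
                x$composition$n[i], 100 * x$composition$fraction[i]))
  }
  q <- x$score_quantiles
  cat(sprintf("  zonal score: min %.3f, median %.3f, max %.3f\n",
              q[[1]], q[[3]], q[[5]]))
  invisible(x)
}

#' @describeIn zonate Z-Z plot of a gene (base graphics); `gene` picks the
#'   X-axis gene, `overlay` an optional second gene drawn as a heat color on
#'   the first gene's expressing cells.
#' @param x a `zonate` fit.
#' @param gene gene symbol for the X axis.
#' @param overlay optional second gene symbol.
#' @export
plot.zonate <- function(x, gene, overlay = NULL, ...) {
  pd <- build_zzplot(x$zmat, x$scores, gene)
  if (!is.null(overlay)) {
    pd <- overlay_coexpression(pd, x$zmat, overlay)
  }
  .zz_draw(pd, ...)
  invisible(pd)
}
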