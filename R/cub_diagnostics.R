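# Inferential codon-usage diagnostics: the ENC-GC3s plot with its expected
# curve, Parity Rule 2 (PR2) bias coordinates, and the neutrality regression
# of P12 on P3.

#' Expected ENC under mutation pressure alone
#'
#' The reference curve for the ENC-GC3s plot: for third-position
#' synonymous GC content s, ENC = 2 + s + 29 / (s^2 + (1 - s)^2). Genes on or
#' near this curve are compatible with codon usage driven only by
#' compositional (mutational) bias; genes falling well below it indicate
#' selection among synonymous codons.
#'
#' @param gc3s third-position synonymous GC content, in [0, 1] (vectorized)
#' @return expected ENC value(s)
#' @export
expected_enc <- function(gc3s) {
  if (any(gc3s < 0 | gc3s > 1, na.rm = TRUE)) {
    stop("gc3s must lie in [0, 1]")
  }
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' ENC-GC3s analysis
#'
#' Per-gene observed vs expected ENC and the relative deviation
#' (expected - observed) / expected. Genes with undefined ENC or GC3s are
#' skipped and counted.
#'
#' @param metrics data.frame from [cub_metrics_table()]
#' @return list with `points` (gene_name, gc3s, enc_observed, enc_expected,
#'   deviation), `mean_deviation`, `frac_below_curve`, `n_skipped`
#' @export
enc_gc3s_analysis <- function(metrics) {
  if (nrow(metrics) == 0L) {
    return(list(points = data.frame(), mean_deviation = NA_real_,
                frac_below_curve = NA_real_, n_skipped = 0L))
  }
  ok <- !is.na(metrics$ENC) & !is.na(metrics$GC3s)
  pts <- data.frame(
    gene_name = metrics$gene_name[ok],
    gc3s = metrics$GC3s[ok],
    enc_observed = metrics$ENC[ok])
  pts$enc_expected <- expected_enc(pts$gc3s)
  pts$deviation <- (pts$enc_expected - pts$enc_observed) / pts$enc_expected
  list(points = pts,
       mean_deviation = mean(pts$deviation),
       frac_below_curve = mean(pts$deviation > 0),
       n_skipped = sum(!ok))
}

#' PR2 (Parity Rule 2) analysis
#'
#' Plots each gene at x = G3s/(G3s+C3s), y = A3s/(A3s+T3s). At the central
#' point (0.5, 0.5) the third-position composition satisfies A = T and G = C,
#' as expected under strand-symmetric mutation with no selection; quadrants
#' are assigned relative to it (ties labeled "center"). Genes with a zero
#' denominator are skipped and counted.
#'
#' The default axes use the A3s/T3s/G3s/C3s quantities (ATG, ATT, ATC, ATA,
#' TGG and stops excluded). Because the Trp and stop exclusions remove G- and
#' A-ending codons asymmetrically, these axes sit below-left of center even
#' under perfectly symmetric mutation; `fourfold_only = TRUE` restricts the
#' composition to fourfold-degenerate sites, which are free of that artifact.
#'
#' @param metrics data.frame from [cub_metrics_table()]
#' @param fourfold_only use third bases of fourfold-degenerate codons only
#' @return list with `points` (gene_name, x, y, quadrant), `quadrant_counts`,
#'   `n_skipped`
#' @export
pr2_analysis <- function(metrics, fourfold_only = FALSE) {
  cols <- if (fourfold_only) c("A3f", "T3f", "G3f", "C3f")
          else c("A3s", "T3s", "G3s", "C3s")
  a3 <- metrics[[cols[1]]]; t3 <- metrics[[cols[2]]]
  g3 <- metrics[[cols[3]]]; c3 <- metrics[[cols[4]]]
  at <- a3 + t3
  gc <- g3 + c3
  ok <- !is.na(at) & !is.na(gc) & at > 0 & gc > 0
  y <- a3[ok] / at[ok]
  x <- g3[ok] / gc[ok]
  quadrant <- ifelse(x == 0.5 | y == 0.5, "center",
              ifelse(x < 0.5 & y < 0.5, "lower-left",
              ifelse(x >= 0.5 & y < 0.5, "lower-right",
              ifelse(x < 0.5, "upper-left", "upper-right"))))
  qlevels <- c("lower-left", "lower-right", "upper-left", "upper-right", "center")
  list(points = data.frame(gene_name = metrics$gene_name[ok],
                           x = x, y = y, quadrant = quadrant),
       quadrant_counts = table(factor(quadrant, levels = qlevels)),
       n_skipped = sum(!ok))
}

#' Neutrality regression of P12 on P3
#'
#' Ordinary least squares of P12 (mean GC at codon positions 1-2) on P3 (GC
#' at position 3), with Pearson's r and its two-sided p-value from the exact
#' t-transform on n - 2 degrees of freedom. A slope near 1 indicates codon
#' usage tracking mutational GC pressure at all positions; a slope near 0
#' indicates selective constraint on positions 1-2. The slope times 100 is
#' reported as the percent contribution of mutation pressure.
#'
#' @param metrics data.frame from [cub_metrics_table()] (needs >= 3 genes with
#'   defined P12 and P3 and non-degenerate var(P3))
#' @return list of class `neutrality_regression` with slope, intercept,
#'   pearson_r, p_value, n_genes, mutation_share
#' @export
neutrality_regression <- function(metrics) {
  ok <- !is.na(metrics$P12) & !is.na(metrics$P3)
  p3 <- metrics$P3[ok]; p12 <- metrics$P12[ok]
  if (length(p3) < 3L) stop("neutrality regression needs >= 3 genes with defined P12 and P3")
  if (stats::var(p3) == 0) stop("degenerate input: var(P3) is zero")
  fit <- stats::lm(p12 ~ p3)
  ct <- suppressWarnings(stats::cor.test(p3, p12, method = "pearson"))
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         pearson_r = unname(ct$estimate),
         p_value = ct$p.value,
         n_genes = length(p3),
         mutation_share = 100 * unname(stats::coef(fit)[2])),
    class = "neutrality_regression")
}

#' @export
print.neutrality_regression <- function(x, ...) {
  cat(sprintf(paste0("<neutrality_regression> n = %d genes\n",
                     "  P12 = %.4f + %.4f * P3   (r = %.3f, p = %.3g)\n",
                     "  mutation pressure share: %.2f%%\n"),
              x$n_genes, x$intercept, x$slope, x$pearson_r, x$p_value,
              x$mutation_share))
  invisible(x)
}
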