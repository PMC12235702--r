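# Per-contrast differential expression on the TMT quantification table:
# log2 transform, per-sample median centering, two-sample Student t-test,
# log2 fold change, and the two filter rules used to call differentially
# expressed proteins (DEPs).

#' Log2-transform and normalize a quantification table
#'
#' Intensities are log2-transformed (missing stays missing); with
#' `method = "median_center"` each sample's median log2 intensity is then
#' subtracted, aligning the per-sample distributions.
#'
#' @param x a `protein_quant` with linear-scale intensities
#' @param method `"median_center"` (default) or `"none"`
#' @return `x` with log2-scale (optionally centered) intensities
#' @export
normalize_quant <- function(x, method = c("median_center", "none")) {
  method <- match.arg(method)
  if (!inherits(x, "protein_quant")) stop_input("x must be a protein_quant")
  if (x$log2) stop_input("table is already on the log2 scale")
  all_na <- colSums(!is.na(x$intensities)) == 0
  if (any(all_na))
    stop_input("sample(s) with all values missing: ",
               paste(colnames(x$intensities)[all_na], collapse = ", "))
  m <- log2(x$intensities)
  if (method == "median_center") {
    med <- apply(m, 2, stats::median, na.rm = TRUE)
    m <- sweep(m, 2, med)
  }
  x$intensities <- m
  x$log2 <- TRUE
  x$normalization <- method
  x
}

#' Two-group Student t-test comparison on a quantification table
#'
#' For each protein group, tests numerator vs denominator condition with
#' a two-sided two-sample t-test (equal-variance Student by default) and
#' computes the log2 fold change as the difference of group means on the
#' log2 scale. A protein needs at least two non-missing values per group;
#' proteins failing this (or with zero pooled variance and a nonzero mean
#' difference) are flagged, not dropped. The DEP call is
#' `p < p_threshold` and `|log2FC| > fc_threshold`.
#'
#' @param x a log2-scale `protein_quant` with an attached design
#' @param numerator,denominator condition labels (e.g. `"PS"`, `"CTL"`)
#' @param batch restrict to one batch (integer), or `NULL` to pool all
#'   batches containing both conditions
#' @param p_threshold p-value cutoff for the DEP call; default 0.05
#' @param fc_threshold absolute log2-fold-change cutoff; default 0.58
#' @param var_equal `TRUE` (Student, default) or `FALSE` (Welch)
#' @return object of class `dep_result`: a data.frame with columns
#'   `protein_id`, `gene`, `log2_fc`, `t_stat`, `p_value`, `n_num`,
#'   `n_den`, `flagged`, `is_dep`, `direction`, carrying the contrast
#'   and thresholds as attributes
#' @export
dep_compare <- function(x, numerator, denominator, batch = NULL,
                        p_threshold = 0.05, fc_threshold = 0.58,
                        var_equal = TRUE) {
  if (!inherits(x, "protein_quant")) stop_input("x must be a protein_quant")
  if (is.null(x$design)) stop_input("no design attached; see attach_design()")
  if (!x$log2)
    stop_input("intensities must be log2-transformed first; ",
               "see normalize_quant()")
  if (numerator == denominator)
    stop_input("numerator and denominator conditions must differ")
  contrast <- paste0(numerator, "/", denominator)
  des <- x$design
  in_scope <- if (is.null(batch)) rep(TRUE, nrow(des)) else des$batch == batch
  num_idx <- which(in_scope & des$condition == numerator)
  den_idx <- which(in_scope & des$condition == denominator)
  if (!length(num_idx) || !length(den_idx))
    stop_input("contrast ", contrast,
               if (!is.null(batch)) paste0(" (batch ", batch, ")") else "",
               ": empty ", if (!length(num_idx)) "numerator" else "denominator",
               " group")
  a <- x$intensities[, num_idx, drop = FALSE]
  b <- x$intensities[, den_idx, drop = FALSE]

  n1 <- rowSums(!is.na(a)); n2 <- rowSums(!is.na(b))
  m1 <- rowMeans(a, na.rm = TRUE); m2 <- rowMeans(b, na.rm = TRUE)
  v1 <- apply(a, 1, stats::var, na.rm = TRUE)
  v2 <- apply(b, 1, stats::var, na.rm = TRUE)
  lfc <- m1 - m2

  enough <- n1 >= 2 & n2 >= 2
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- lfc / se
  # zero mean difference is a clean null regardless of variance
  tstat[enough & lfc == 0] <- 0
  p <- 2 * stats::pt(-abs(tstat), df)
  p[enough & lfc == 0] <- 1

  degenerate <- enough & se == 0 & lfc != 0
  flagged <- !enough | degenerate
  tstat[!enough | degenerate] <- NA_real_
  p[!enough | degenerate] <- NA_real_
  lfc[!enough] <- ifelse(n1 >= 1 & n2 >= 1, lfc, NA_real_)[!enough]

  is_dep <- !is.na(p) & p < p_threshold & abs(lfc) > fc_threshold
  res <- data.frame(protein_id = x$protein_ids,
                    gene = x$gene_symbols,
                    log2_fc = lfc, t_stat = tstat, p_value = p,
                    n_num = n1, n_den = n2,
                    flagged = flagged, is_dep = is_dep,
                    direction = ifelse(is.na(lfc), NA_character_,
                                       ifelse(lfc > 0, "up",
                                              ifelse(lfc < 0, "down", "none"))),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(res, class = c("dep_result", "data.frame"),
            contrast = contrast, numerator = numerator,
            denominator = denominator, batch = batch,
            p_threshold = p_threshold, fc_threshold = fc_threshold,
            var_equal = var_equal)
}

#' @export
print.dep_result <- function(x, ...) {
  cat(sprintf("Differential expression: %s%s\n", attr(x, "contrast"),
              if (!is.null(attr(x, "batch")))
                sprintf(" (batch %d)", attr(x, "batch")) else ""))
  cat(sprintf("  %d proteins, %d DEPs (p < %.3g & |log2FC| > %.3g), %d flagged\n",
              nrow(x), sum(x$is_dep), attr(x, "p_threshold"),
              attr(x, "fc_threshold"), sum(x$flagged)))
  NextMethod()
}

#' @export
summary.dep_result <- function(object, ...) {
  dep <- filter_deps(object)
  cat(sprintf("Contrast %s: %d up, %d down of %d tested (p < %.3g, |log2FC| > %.3g)\n",
              attr(object, "contrast"), length(dep$up), length(dep$down),
              sum(!object$flagged), attr(object, "p_threshold"),
              attr(object, "fc_threshold")))
  invisible(object)
}

#' Extract the DEP lists from a comparison
#'
#' Proteins passing both the p-value and fold-change thresholds recorded
#' in the result, split by fold-change sign.
#'
#' @param result a `dep_result`
#' @param use_genes return gene symbols (default) rather than protein IDs
#' @return list with character vectors `up` and `down`
#' @export
filter_deps <- function(result, use_genes = TRUE) {
  id <- if (use_genes) result$gene else result$protein_id
  list(up = id[result$is_dep & result$log2_fc > 0],
       down = id[result$is_dep & result$log2_fc < 0])
}

#' Down-regulated subset by the standard-deviation rule
#'
#' Selects proteins with `p < p_threshold` whose log2 fold change lies
#' more than `sd_multiplier` standard deviations below the mean log2 fold
#' change of the contrast (z-score rule used to feed over-representation
#' analysis of down-regulated functions).
#'
#' @param result a `dep_result`
#' @param sd_multiplier z-score cutoff; default 1.96
#' @param p_threshold p-value cutoff; default the result's own threshold
#' @param use_genes return gene symbols (default) or protein IDs
#' @return character vector of selected identifiers
#' @export
filter_sd_down <- function(result, sd_multiplier = 1.96, p_threshold = NULL,
                           use_genes = TRUE) {
  p_threshold <- p_threshold %||% attr(result, "p_threshold")
  lfc <- result$log2_fc
  ok <- is.finite(lfc)
  if (sum(ok) < 2) stop_input("need >=2 finite log2 fold changes")
  s <- stats::sd(lfc[ok])
  if (s == 0) stop_input("zero standard deviation of log2 fold changes")
  z <- (lfc - mean(lfc[ok])) / s
  sel <- !is.na(result$p_value) & result$p_value < p_threshold &
    !is.na(z) & z < -sd_multiplier
  id <- if (use_genes) result$gene else result$protein_id
  id[sel]
}

#' Volcano-plot table
#'
#' Long-format export with the log2 fold change on x and `-log10(p)` on
#' y. Zero p-values (not produced by the t-test, but possible in
#' imported tables) are floored at the smallest positive double and
#' flagged.
#'
#' @param result a `dep_result`
#' @return data.frame with `protein_id`, `gene`, `log2_fc`,
#'   `neg_log10_p`, `is_dep`, `p_floored`
#' @export
volcano_table <- function(result) {
  p <- result$p_value
  floored <- !is.na(p) & p == 0
  p[floored] <- .Machine$double.xmin
  data.frame(protein_id = result$protein_id, gene = result$gene,
             log2_fc = result$log2_fc, neg_log10_p = -log10(p),
             is_dep = result$is_dep, p_floored = floored,
             stringsAsFactors = FALSE)
}

#' Volcano plot of a comparison
#' @param x a `dep_result`
#' @param ... passed to [graphics::plot()]
#' @export
plot.dep_result <- function(x, ...) {
  v <- volcano_table(x)
  col <- ifelse(v$is_dep, ifelse(v$log2_fc > 0, "#E66101", "#2166AC"),
                "grey60")
  graphics::plot(v$log2_fc, v$neg_log10_p, col = col, pch = 16, cex = 0.6,
                 xlab = "log2 fold change", ylab = "-log10 p-value",
                 main = attr(x, "contrast"), ...)
  graphics::abline(h = -log10(attr(x, "p_threshold")), lty = 2)
  graphics::abline(v = c(-1, 1) * attr(x, "fc_threshold"), lty = 2)
  invisible(x)
}

#' Ranked gene list from a comparison
#'
#' Genes ranked by log2 fold change (descending), suitable for preranked
#' enrichment. Proteins without a gene symbol or without a finite fold
#' change are dropped; a duplicated symbol keeps its most significant row.
#'
#' @param result a `dep_result`
#' @return named numeric vector sorted by decreasing score
#' @export
dep_ranking <- function(result) {
  ok <- is.finite(result$log2_fc) & nzchar(result$gene)
  d <- result[ok, , drop = FALSE]
  d <- d[order(d$p_value, na.last = TRUE), , drop = FALSE]
  d <- d[!duplicated(d$gene), , drop = FALSE]
  ord <- order(-d$log2_fc)
  stats::setNames(d$log2_fc[ord], d$gene[ord])
}
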