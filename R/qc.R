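# Principal-component QC of the quantification table: within-group
# similarity of samples should be visible in the first three components.

#' Principal-component analysis of samples
#'
#' PCA over samples using proteins quantified in every sample
#' (complete-case restriction; the number of proteins used is recorded).
#' Data are centered but not scaled to unit variance, matching the usual
#' default of [stats::prcomp()]. Component signs are fixed
#' deterministically: within each component, the loading of largest
#' magnitude is made positive, so repeated runs give identical outputs.
#'
#' @param x a `protein_quant` (log2 scale recommended)
#' @param n_components number of components to report; default 3 (for a
#'   3-D plot), capped at the available rank
#' @return object of class `pca_qc` with `coordinates` (samples x
#'   components), `variance_explained` (fraction per reported
#'   component), `loadings` (proteins x components), `n_proteins_used`,
#'   and the sample `design` if attached
#' @export
pca_samples <- function(x, n_components = 3) {
  if (!inherits(x, "protein_quant")) stop_input("x must be a protein_quant")
  m <- x$intensities
  if (ncol(m) < 2) stop_input("need at least 2 samples for PCA")
  complete <- stats::complete.cases(m)
  m <- m[complete, , drop = FALSE]
  if (!nrow(m)) stop_input("no protein is quantified in every sample")
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  # deterministic sign: largest-|loading| entry positive per component
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  structure(list(coordinates = pc$x[, seq_len(k), drop = FALSE],
                 variance_explained = varfrac[seq_len(k)],
                 variance_explained_all = varfrac,
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 rotation_full = pc$rotation,
                 scores_full = pc$x,
                 center = pc$center,
                 n_proteins_used = nrow(m),
                 design = x$design),
            class = "pca_qc")
}

#' @export
print.pca_qc <- function(x, ...) {
  cat(sprintf("Sample PCA on %d complete-case proteins, %d samples\n",
              x$n_proteins_used, nrow(x$coordinates)))
  ve <- x$variance_explained
  cat("  variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_along(ve), 100 * ve),
            collapse = ", "), "\n")
  invisible(x)
}

#' Coordinates table for a 3-D (or 2-D) sample plot
#'
#' @param x a `pca_qc`
#' @return data.frame with `sample`, `PC1`..`PCk`, and `condition`,
#'   `batch` when a design is attached
#' @export
pca_table <- function(x) {
  out <- data.frame(sample = rownames(x$coordinates), x$coordinates,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(x$design)) {
    idx <- match(out$sample, x$design$sample)
    out$condition <- x$design$condition[idx]
    out$batch <- x$design$batch[idx]
  }
  out
}

#' Pairwise component plot of samples colored by condition
#' @param x a `pca_qc`
#' @param components which two components to plot; default `c(1, 2)`
#' @param ... passed to [graphics::plot()]
#' @export
plot.pca_qc <- function(x, components = c(1, 2), ...) {
  co <- x$coordinates[, components, drop = FALSE]
  grp <- if (!is.null(x$design)) factor(x$design$condition) else factor(rep(1, nrow(co)))
  graphics::plot(co[, 1], co[, 2], col = as.integer(grp), pch = 16,
                 xlab = sprintf("PC%d (%.1f%%)", components[1],
                                100 * x$variance_explained[components[1]]),
                 ylab = sprintf("PC%d (%.1f%%)", components[2],
                                100 * x$variance_explained[components[2]]),
                 ...)
  if (nlevels(grp) > 1)
    graphics::legend("topright", legend = levels(grp), col = seq_len(nlevels(grp)),
                     pch = 16, cex = 0.8)
  invisible(x)
}
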