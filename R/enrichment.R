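# Gene-set enrichment: hypergeometric over-representation on DEP lists
# and preranked GSEA (weighted Kolmogorov-Smirnov running sum) with a
# gene-label permutation null, normalized enrichment scores and FDR.

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the query list overlaps the set more
#' than expected by chance given the universe, with the one-sided
#' upper-tail hypergeometric test `P[X >= overlap]`. A
#' Benjamini-Hochberg q-value is reported alongside; the significance
#' call is on the nominal p (`p < p_threshold`).
#'
#' @param query character vector of gene symbols (must be contained in
#'   the universe)
#' @param sets a [gene_set_collection()]
#' @param universe background gene list; defaults to the collection's own
#'   universe if set
#' @param p_threshold nominal significance cutoff; default 0.05
#' @param min_size drop sets with fewer in-universe members; default 1
#' @return object of class `ora_result`: data.frame with `set`,
#'   `size_in_universe`, `overlap`, `odds_ratio`, `p_value`, `fdr_q`,
#'   `significant`
#' @export
ora_test <- function(query, sets, universe = NULL, p_threshold = 0.05,
                     min_size = 1) {
  universe <- universe %||% sets$universe
  if (is.null(universe) || !length(universe))
    stop_input("an explicit universe (background gene list) is required")
  universe <- unique(toupper(universe))
  query <- unique(toupper(query))
  if (!length(query)) stop_input("empty query gene list")
  outside <- setdiff(query, universe)
  if (length(outside))
    stop_input("query gene(s) not in the universe: ",
               paste(utils::head(outside, 5), collapse = ", "))
  N <- length(universe); n <- length(query)
  rows <- lapply(names(sets$sets), function(nm) {
    members <- intersect(sets$sets[[nm]], universe)
    K <- length(members)
    if (K < min_size) return(NULL)
    k <- length(intersect(members, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    or <- (k * (N - K - n + k)) / max((K - k) * (n - k), 1e-300)
    data.frame(set = nm, size_in_universe = K, overlap = k,
               odds_ratio = or, p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop_input("no gene set passes the size filter")
  res$fdr_q <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- res$p_value < p_threshold
  res <- res[order(res$p_value), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("ora_result", "data.frame"),
            universe_size = N, query_size = n, p_threshold = p_threshold)
}

#' @export
print.ora_result <- function(x, ...) {
  cat(sprintf("Over-representation: query %d genes vs universe %d; %d/%d sets significant (p < %.3g)\n",
              attr(x, "query_size"), attr(x, "universe_size"),
              sum(x$significant), nrow(x), attr(x, "p_threshold")))
  NextMethod()
}

# Running-sum enrichment score from hit positions only.
# pos: sorted positions of the set's genes in the ranking (1-based);
# w_incr: positive increments at hits, already normalized to sum 1;
# N: ranking length. Extrema of the running sum occur immediately after
# a hit (peaks) or immediately before one (troughs).
es_from_positions <- function(pos, w_incr, N) {
  Nh <- length(pos)
  if (Nh == N) return(1)
  md <- 1 / (N - Nh)
  cum <- cumsum(w_incr)
  k <- seq_len(Nh)
  after <- cum - (pos - k) * md            # just after each hit
  before <- c(0, cum[-Nh]) - (pos - k) * md  # just before each hit
  hi <- max(after, 0)
  lo <- min(before, 0)
  if (hi >= -lo) hi else lo
}

#' GSEA enrichment score and running sum
#'
#' Weighted Kolmogorov-Smirnov-style statistic on a ranked gene list: the
#' running sum increases by `|score|^w / sum(|score_hits|^w)` at each gene
#' in the set and decreases by `1/(N - Nh)` at each gene outside it; the
#' enrichment score (ES) is the signed extremum. Positive ES means the
#' set concentrates at the top of the ranking, negative at the bottom.
#'
#' @param ranked named numeric vector sorted by decreasing score (as from
#'   [read_rnk()] or [dep_ranking()]); gene names must be unique
#' @param gene_set character vector of member gene symbols
#' @param weight_exponent weighting exponent `w`; 1 is the classic
#'   weighted statistic, 0 the unweighted Kolmogorov-Smirnov form
#' @return list with `es`, `running` (running sum after each gene) and
#'   `hit_idx` (positions of the set in the ranking)
#' @export
gsea_enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  if (anyDuplicated(names(ranked)))
    stop_input("ranked list contains duplicated genes")
  genes <- toupper(names(ranked))
  hit <- genes %in% toupper(gene_set)
  Nh <- sum(hit); N <- length(ranked)
  if (Nh == 0) stop_input("gene set has no member in the ranked list")
  if (Nh == N) {
    return(list(es = 1, running = cumsum(abs(ranked)^weight_exponent) /
                  sum(abs(ranked)^weight_exponent), hit_idx = seq_len(N)))
  }
  w <- abs(ranked)^weight_exponent
  incr <- ifelse(hit, w / sum(w[hit]), -1 / (N - Nh))
  running <- cumsum(incr)
  pos <- which(hit)
  es <- es_from_positions(pos, w[pos] / sum(w[pos]), N)
  list(es = es, running = running, hit_idx = pos)
}

# ES for many position draws (matrix: draws x set size), shared weights.
perm_es <- function(pos_mat, w_all, weight_exponent, N) {
  apply(pos_mat, 1, function(pos) {
    pos <- sort(pos)
    wh <- w_all[pos]
    es_from_positions(pos, wh / sum(wh), N)
  })
}

#' Preranked GSEA with gene-label permutation significance
#'
#' Computes the enrichment score of each set on the ranking, builds a
#' null by repeatedly drawing random gene labels of the same set size,
#' and reports a same-sign permutation p-value (with add-one
#' pseudocount), a normalized enrichment score (NES = ES divided by the
#' mean same-sign null |ES|), and an FDR q-value from the pooled null NES
#' distribution. A set is called significant when `fdr_q < fdr_threshold`
#' and `p_value < p_threshold`.
#'
#' @param ranked named numeric vector sorted by decreasing score
#' @param sets a [gene_set_collection()]
#' @param n_perm number of gene-label permutations; default 1000
#' @param weight_exponent see [gsea_enrichment_score()]; default 1
#' @param seed integer seed for the permutation draws (recorded in the
#'   result); `NULL` leaves the RNG state alone
#' @param min_size,max_size set-size bounds after intersection with the
#'   ranking; defaults 5 and 500
#' @param fdr_threshold,p_threshold significance criteria; defaults 0.25
#'   and 0.05
#' @param exhaustive if `TRUE`, enumerate all `choose(N, Nh)` label
#'   placements instead of sampling (tiny problems only)
#' @return object of class `gsea_result`: data.frame with `set`, `size`,
#'   `es`, `nes`, `p_value`, `fdr_q`, `significant`, `flagged`, plus
#'   attributes recording the parameters; sets with no gene in the
#'   ranking are skipped and listed in the `skipped` attribute
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 1000, weight_exponent = 1,
                           seed = NULL, min_size = 5, max_size = 500,
                           fdr_threshold = 0.25, p_threshold = 0.05,
                           exhaustive = FALSE) {
  if (n_perm < 1) stop_input("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  N <- length(ranked)
  w_all <- abs(ranked)^weight_exponent
  skipped <- character()

  keep <- list()
  for (nm in names(sets$sets)) {
    nh <- sum(toupper(names(ranked)) %in% sets$sets[[nm]])
    if (nh == 0) { skipped <- c(skipped, nm); next }
    if (nh < min_size || nh > max_size) { skipped <- c(skipped, nm); next }
    keep[[nm]] <- nh
  }
  if (!length(keep))
    stop_input("no gene set overlaps the ranking within the size bounds")

  es_obs <- vapply(names(keep), function(nm)
    gsea_enrichment_score(ranked, sets$sets[[nm]], weight_exponent)$es, 0)

  # one permutation block per distinct set size
  sizes <- unique(unlist(keep))
  perm_by_size <- list()
  for (nh in sizes) {
    if (exhaustive) {
      pos_mat <- t(utils::combn(N, nh))
    } else {
      draws <- vapply(seq_len(n_perm), function(i) sample.int(N, nh),
                      integer(nh))
      pos_mat <- if (nh == 1) matrix(draws, ncol = 1) else t(draws)
    }
    perm_by_size[[as.character(nh)]] <-
      perm_es(pos_mat, w_all, weight_exponent, N)
  }

  p <- nes <- numeric(length(keep))
  flagged <- logical(length(keep))
  nes_perm_pool <- numeric()
  for (i in seq_along(keep)) {
    nh <- keep[[i]]
    null_es <- perm_by_size[[as.character(nh)]]
    same_sign <- if (es_obs[i] >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    if (!length(same_sign)) {
      p[i] <- 1 / (length(null_es) + 1)
      nes[i] <- NA_real_
      flagged[i] <- TRUE
    } else {
      extreme <- sum(abs(same_sign) >= abs(es_obs[i]))
      p[i] <- (1 + extreme) / (1 + length(same_sign))
      nes[i] <- es_obs[i] / mean(abs(same_sign))
    }
  }
  # pooled null NES: each set's null ES normalized by its same-sign means
  for (i in seq_along(keep)) {
    null_es <- perm_by_size[[as.character(keep[[i]])]]
    mp <- mean(null_es[null_es >= 0]); mn <- mean(abs(null_es[null_es < 0]))
    np <- ifelse(null_es >= 0,
                 if (is.nan(mp)) NA_real_ else null_es / mp,
                 if (is.nan(mn)) NA_real_ else null_es / mn)
    nes_perm_pool <- c(nes_perm_pool, np[!is.na(np)])
  }
  fdr <- vapply(seq_along(keep), function(i) {
    if (is.na(nes[i])) return(NA_real_)
    if (nes[i] >= 0) {
      null_frac <- sum(nes_perm_pool >= nes[i]) / max(sum(nes_perm_pool >= 0), 1)
      obs_frac <- sum(nes >= nes[i], na.rm = TRUE) /
        max(sum(nes >= 0, na.rm = TRUE), 1)
    } else {
      null_frac <- sum(nes_perm_pool <= nes[i]) / max(sum(nes_perm_pool < 0), 1)
      obs_frac <- sum(nes <= nes[i], na.rm = TRUE) /
        max(sum(nes < 0, na.rm = TRUE), 1)
    }
    min(null_frac / max(obs_frac, 1e-300), 1)
  }, 0)

  res <- data.frame(set = names(keep), size = unlist(keep),
                    es = es_obs, nes = nes, p_value = p, fdr_q = fdr,
                    significant = !is.na(fdr) & fdr < fdr_threshold &
                      p < p_threshold,
                    flagged = flagged,
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[order(res$p_value), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("gsea_result", "data.frame"),
            n_perm = if (exhaustive) length(perm_by_size[[1]]) else n_perm,
            weight_exponent = weight_exponent, seed = seed,
            min_size = min_size, max_size = max_size,
            fdr_threshold = fdr_threshold, p_threshold = p_threshold,
            exhaustive = exhaustive, skipped = skipped)
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("Preranked GSEA: %d sets, %d significant (FDR < %.2g & p < %.2g), %d permutations\n",
              nrow(x), sum(x$significant), attr(x, "fdr_threshold"),
              attr(x, "p_threshold"), attr(x, "n_perm")))
  if (length(attr(x, "skipped")))
    cat("  skipped (no overlap or size bounds):",
        paste(attr(x, "skipped"), collapse = ", "), "\n")
  NextMethod()
}

#' Running-sum plot for one gene set
#' @param x a `gsea_result` (used for parameters) or `NULL`
#' @param ranked the ranking used
#' @param sets the gene-set collection
#' @param set name of the set to plot
#' @param ... passed to [graphics::plot()]
#' @export
plot_gsea_running <- function(x = NULL, ranked, sets, set, ...) {
  w <- if (is.null(x)) 1 else attr(x, "weight_exponent")
  sc <- gsea_enrichment_score(ranked, sets$sets[[set]], w)
  graphics::plot(seq_along(sc$running), sc$running, type = "l",
                 xlab = "rank", ylab = "running enrichment score",
                 main = set, ...)
  graphics::abline(h = 0, lty = 3)
  graphics::rug(sc$hit_idx)
  invisible(sc)
}
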