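# Fixture builders shared across the test files. Everything is generated
# in code; no binary fixtures.

# A toy MaxQuant-style protein-groups file. `markers` is a named list of
# character vectors ("+" / "") per marker column to include.
write_toy_protein_groups <- function(path, n = 5, samples = c("s1", "s2"),
                                     markers = list(), zero_cells = NULL,
                                     prefix = "Reporter intensity corrected") {
  df <- data.frame(`Protein IDs` = sprintf("P%02d", seq_len(n)),
                   `Gene names` = sprintf("g%02d", seq_len(n)),
                   check.names = FALSE)
  set.seed(42)
  for (s in samples)
    df[[paste(prefix, s)]] <- round(runif(n, 1e5, 1e7))
  if (!is.null(zero_cells))
    for (cell in zero_cells)
      df[cell[1], paste(prefix, samples[cell[2]])] <- 0
  for (nm in names(markers)) df[[nm]] <- markers[[nm]]
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  df
}

# A small quant table with explicit values: proteins x samples matrix,
# 3 vs 3 design in one batch. Values are taken as already log2-scale.
toy_quant_3v3 <- function(mat, conditions = c(rep("CTL", 3), rep("PS", 3)),
                          log2 = TRUE) {
  n <- nrow(mat)
  samp <- sprintf("x%d", seq_len(ncol(mat)))
  colnames(mat) <- samp
  design <- data.frame(sample = samp, condition = conditions,
                       batch = 1L, stringsAsFactors = FALSE)
  protein_quant(sprintf("P%03d", seq_len(n)),
                sprintf("G%03d", seq_len(n)),
                mat, design = design, log2 = log2)
}

# Independent scalar-loop recomputation of the delta pipeline for a
# matrix with explicit single-agent margins (every cell a combination).
scalar_delta_oracle <- function(viability, Ii0, I0j) {
  d <- matrix(NA_real_, nrow(viability), ncol(viability))
  for (i in seq_len(nrow(viability))) {
    for (j in seq_len(ncol(viability))) {
      obs <- 100 - viability[i, j]
      zip <- Ii0[i] * I0j[j] / 100
      d[i, j] <- obs - zip
    }
  }
  d
}

# Direct running-sum walk over the whole ranked list (the O(N) textbook
# form), independent of the position-based implementation.
walk_es_oracle <- function(ranked, gene_set, w = 1) {
  hit <- toupper(names(ranked)) %in% toupper(gene_set)
  N <- length(ranked); Nh <- sum(hit)
  wts <- unname(abs(ranked)^w)
  run <- 0; best <- 0
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) wts[i] / sum(wts[hit]) else -1 / (N - Nh)
    if (abs(run) > abs(best)) best <- run
  }
  best
}
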