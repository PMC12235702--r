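# Synthetic-data generators: dose-response matrices with a known
# interaction surface, TMT quantification tables with planted fold
# changes, and gene-set collections with planted enrichment. Every
# generator is a pure function of its configuration (seed included) and
# emits its ground truth alongside the data, so each pipeline stage can
# be checked against what was planted.

#' Configuration for the synthetic-data generators
#'
#' Defaults emulate the study conditions the pipeline targets: a
#' colony-formation dose-response grid with a zero-dose margin for each
#' drug, and a two-batch TMT experiment with four treatment conditions
#' (CTL, P, S, PS) in triplicate.
#'
#' @param seed integer seed (mandatory; every generator is deterministic
#'   given the config)
#' @param dose_s,dose_p concentration ladders (micromolar), first entry 0
#' @param ec50_s,hill_s,imax_s single-agent potency of drug S: Hill
#'   midpoint, slope, maximal inhibition (%)
#' @param ec50_p,hill_p,imax_p same for drug P
#' @param delta_surface matrix of true interaction deltas (percentage
#'   points) for the combination cells, `length(dose_s)` x
#'   `length(dose_p)` with zero margins, or `NULL` for no interaction
#' @param viability_noise_sd multiplicative viability noise SD
#'   (fraction); default 0.05
#' @param n_proteins number of protein groups; default 2000
#' @param fraction_dep fraction of proteins with a planted effect;
#'   default 0.1
#' @param planted_lfc magnitude of planted log2 fold changes; default 1
#' @param batch_sd SD of per-protein batch offsets (log2); default 0.3
#' @param noise_sd replicate noise SD (log2); default 0.25
#' @param missing_rate fraction of missing quantifications; default 0.05
#' @param missing_mode `"mcar"` (default) or `"intensity"` (low-intensity
#'   proteins more likely missing)
#' @param n_reps replicates per condition per batch; default 3
#' @param n_sets number of decoy gene sets; default 20
#' @param n_planted_sets number of planted (enriched) sets; default 2
#' @param set_size genes per set; default 25
#' @param signal_strength odds of a planted set drawing a planted-effect
#'   gene relative to a null gene; default 20
#' @return validated list of class `synth_config`
#' @export
synth_config <- function(seed,
                         dose_s = c(0, 2, 4, 8, 16),
                         dose_p = c(0, 0.25, 0.5, 1),
                         ec50_s = 6, hill_s = 1.2, imax_s = 85,
                         ec50_p = 0.4, hill_p = 1.5, imax_p = 90,
                         delta_surface = NULL,
                         viability_noise_sd = 0.05,
                         n_proteins = 2000, fraction_dep = 0.1,
                         planted_lfc = 1, batch_sd = 0.3, noise_sd = 0.25,
                         missing_rate = 0.05, missing_mode = c("mcar", "intensity"),
                         n_reps = 3, n_sets = 20, n_planted_sets = 2,
                         set_size = 25, signal_strength = 20) {
  if (missing(seed) || is.null(seed))
    stop_input("seed is mandatory in a synth_config")
  missing_mode <- match.arg(missing_mode)
  rates <- c(viability_noise_sd = viability_noise_sd,
             fraction_dep = fraction_dep, missing_rate = missing_rate)
  bad <- rates < 0 | rates > 1
  if (any(bad))
    stop_input("rate(s) outside [0,1]: ", paste(names(rates)[bad], collapse = ", "))
  if (!is.null(delta_surface)) {
    delta_surface <- as.matrix(delta_surface)
    if (!identical(dim(delta_surface), c(length(dose_s), length(dose_p))))
      stop_input("delta_surface must be ", length(dose_s), " x ", length(dose_p))
  }
  cfg <- list(seed = as.integer(seed), dose_s = dose_s, dose_p = dose_p,
              ec50_s = ec50_s, hill_s = hill_s, imax_s = imax_s,
              ec50_p = ec50_p, hill_p = hill_p, imax_p = imax_p,
              delta_surface = delta_surface,
              viability_noise_sd = viability_noise_sd,
              n_proteins = n_proteins, fraction_dep = fraction_dep,
              planted_lfc = planted_lfc, batch_sd = batch_sd,
              noise_sd = noise_sd, missing_rate = missing_rate,
              missing_mode = missing_mode, n_reps = n_reps,
              n_sets = n_sets, n_planted_sets = n_planted_sets,
              set_size = set_size, signal_strength = signal_strength)
  structure(cfg, class = "synth_config")
}

hill_inhibition <- function(conc, ec50, hill, imax) {
  ifelse(conc == 0, 0, imax * conc^hill / (ec50^hill + conc^hill))
}

#' Simulate a dose-response matrix with known interaction
#'
#' Single-agent inhibitions follow monotone Hill curves; each combination
#' cell's inhibition is the independent-action product expectation plus
#' the configured true delta; multiplicative noise is applied to the
#' resulting viability. The zero-dose margins carry the single-agent
#' measurements themselves.
#'
#' @param config a [synth_config()]
#' @return list with `dose_response` (a [dose_response()] object),
#'   `true_delta` (matrix of planted deltas), and `config`
#' @export
synth_dose_response <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  Ii0 <- hill_inhibition(config$dose_s, config$ec50_s, config$hill_s,
                         config$imax_s)
  I0j <- hill_inhibition(config$dose_p, config$ec50_p, config$hill_p,
                         config$imax_p)
  true_delta <- config$delta_surface %||%
    matrix(0, length(config$dose_s), length(config$dose_p))
  inh <- outer(Ii0, I0j) / 100 + true_delta
  inh[, 1] <- Ii0 + true_delta[, 1]
  inh[1, ] <- I0j + true_delta[1, ]
  inh[1, 1] <- 0 + true_delta[1, 1]
  viab <- 100 - inh
  if (config$viability_noise_sd > 0)
    viab <- viab * (1 + stats::rnorm(length(viab), 0,
                                     config$viability_noise_sd))
  dr <- dose_response(viab, config$dose_s, config$dose_p,
                      drug_s_name = "drug_S", drug_p_name = "drug_P")
  list(dose_response = dr, true_delta = true_delta, config = config)
}

#' Simulate a two-batch TMT quantification table with planted effects
#'
#' Log2 intensities are baseline + condition effect + per-protein batch
#' offset + replicate noise, exponentiated to the linear reporter scale.
#' A `fraction_dep` subset of proteins receives a log2 fold change of
#' magnitude `planted_lfc` (random sign) in one target condition drawn
#' from P, S, PS; the remainder are null. Missing values are injected at
#' `missing_rate` (MCAR by default).
#'
#' @param config a [synth_config()]
#' @return list with `quant` (a `protein_quant`, linear scale, design
#'   attached), `truth` (data.frame: `protein_id`, `gene`, `condition`,
#'   `true_lfc` for planted proteins), `design`, and `config`
#' @export
synth_tmt <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 1L)
  np <- config$n_proteins
  conditions <- c("CTL", "P", "S", "PS")
  design <- expand.grid(rep = seq_len(config$n_reps),
                        condition = conditions, batch = 1:2,
                        stringsAsFactors = FALSE)
  design$sample <- sprintf("b%d_%s_%d", design$batch, design$condition,
                           design$rep)
  design <- design[, c("sample", "condition", "batch")]

  ids <- sprintf("PROT%04d", seq_len(np))
  genes <- sprintf("GENE%04d", seq_len(np))
  n_dep <- round(config$fraction_dep * np)
  if (config$fraction_dep > 0 && n_dep < 1)
    warning("fraction_dep * n_proteins < 1; no effect planted")
  planted_idx <- if (n_dep >= 1) sample.int(np, n_dep) else integer()
  target <- sample(c("P", "S", "PS"), length(planted_idx), replace = TRUE)
  sign <- sample(c(-1, 1), length(planted_idx), replace = TRUE)
  true_lfc <- sign * config$planted_lfc

  baseline <- stats::rnorm(np, mean = 20, sd = 2)
  batch_off <- matrix(stats::rnorm(np * 2, 0, config$batch_sd), np, 2)
  effect <- matrix(0, np, length(conditions),
                   dimnames = list(NULL, conditions))
  if (length(planted_idx))
    effect[cbind(planted_idx, match(target, conditions))] <- true_lfc

  m <- matrix(0, np, nrow(design), dimnames = list(ids, design$sample))
  for (j in seq_len(nrow(design))) {
    m[, j] <- baseline + effect[, design$condition[j]] +
      batch_off[, design$batch[j]] +
      stats::rnorm(np, 0, config$noise_sd)
  }
  lin <- 2^m
  if (config$missing_rate > 0) {
    if (config$missing_mode == "mcar") {
      miss <- matrix(stats::runif(length(lin)) < config$missing_rate,
                     nrow(lin), ncol(lin))
    } else {
      # lower-intensity proteins are more likely to drop out
      pr <- stats::plogis(-(m - mean(m)) / stats::sd(m))
      pr <- pr * config$missing_rate / mean(pr)
      miss <- matrix(stats::runif(length(lin)) < pr, nrow(lin), ncol(lin))
    }
    lin[miss] <- NA_real_
  }
  quant <- protein_quant(ids, genes, lin, design = design)
  truth <- data.frame(protein_id = ids[planted_idx],
                      gene = genes[planted_idx],
                      condition = target, true_lfc = true_lfc,
                      stringsAsFactors = FALSE)
  list(quant = quant, truth = truth, design = design, config = config)
}

#' Simulate gene sets with planted enrichment
#'
#' Planted sets draw their members with odds `signal_strength` : 1 in
#' favour of planted-effect genes (so an infinitely strong signal makes
#' the set a subset of the perturbed genes); decoy sets draw uniformly
#' from the universe.
#'
#' @param config a [synth_config()]
#' @param truth truth table from [synth_tmt()] (identifies the
#'   planted-effect genes)
#' @param universe character vector of all gene symbols
#' @return list with `collection` (a [gene_set_collection()]) and
#'   `truth` (data.frame: `set`, `planted`)
#' @export
synth_gene_sets <- function(config, truth, universe) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 2L)
  universe <- toupper(universe)
  if (config$set_size > length(universe))
    stop_input("set_size exceeds the universe size")
  de_genes <- toupper(truth$gene)
  wts <- ifelse(universe %in% de_genes, config$signal_strength, 1)
  sets <- list()
  for (i in seq_len(config$n_planted_sets))
    sets[[sprintf("PLANTED_SET_%02d", i)]] <-
      sample(universe, config$set_size, prob = wts)
  for (i in seq_len(config$n_sets))
    sets[[sprintf("DECOY_SET_%02d", i)]] <-
      sample(universe, config$set_size)
  coll <- gene_set_collection(sets, universe = universe)
  list(collection = coll,
       truth = data.frame(set = names(sets),
                          planted = grepl("^PLANTED", names(sets)),
                          stringsAsFactors = FALSE))
}
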