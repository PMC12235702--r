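# End-to-end orchestration: one YAML (or list) configuration drives the
# synergy arm, the proteomics arm (normalization, all contrasts, DEP
# lists, ORA, GSEA, PCA QC), and writes a manifest of parameters, input
# digests and row counts for reproducibility.

DEFAULT_CONTRASTS <- list(
  list(numerator = "P",  denominator = "CTL", batch = 1),
  list(numerator = "S",  denominator = "CTL", batch = 1),
  list(numerator = "PS", denominator = "CTL", batch = 1),
  list(numerator = "PS", denominator = "CTL", batch = 2),
  list(numerator = "PS", denominator = "P",   batch = 2),
  list(numerator = "PS", denominator = "S",   batch = 2))

#' Run the full analysis pipeline
#'
#' Stages, in order: synergy scoring on the dose-response matrix;
#' normalization of the quantification table; PCA QC; differential
#' expression for every configured contrast with DEP lists; ORA on each
#' contrast's standard-deviation-filtered down-regulated list; preranked
#' GSEA on each contrast's fold-change ranking. Inputs come either from
#' files named in the config or from the synthetic generators (a
#' `simulate` block). A failing stage aborts with the stage name; the
#' manifest records the stages completed.
#'
#' @param config path to a YAML file or an equivalent nested list. Keys
#'   (all optional, defaults in parentheses): `seed`; `simulate: true`;
#'   `inputs: {dose_matrix, protein_groups, design, gene_sets}`;
#'   `synergy: {band (5), mode ("product")}`;
#'   `dep: {p_threshold (0.05), fc_threshold (0.58),
#'   normalization ("median_center"), sd_multiplier (1.96), contrasts}`;
#'   `gsea: {n_perm (1000), weight_exponent (1), fdr_threshold (0.25),
#'   p_threshold (0.05), min_size (5), max_size (500)}`;
#'   `ora: {p_threshold (0.05)}`
#' @param out_dir output directory (created)
#' @return the run manifest, invisibly
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_input("no such config file: ", config)
    config <- yaml::read_yaml(config)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    msg <- sprintf("[%s] %s", "pipeline", paste0(...))
    message(msg)
    cat(msg, "\n", file = log_path, append = TRUE)
  }
  seed <- as.integer(config$seed %||% 1L)
  completed <- character()
  manifest <- list(pipeline_version = as.character(utils::packageVersion("synprot")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   config = config, seed = seed,
                   input_digests = list(), stages = list())
  fail <- function(stage, e) {
    manifest$stages_completed <- completed
    manifest$failed_stage <- stage
    jsonlite_write_manifest(manifest, out_dir)
    stop_input("stage '", stage, "' failed: ", conditionMessage(e))
  }

  simulate <- isTRUE(config$simulate) || is.null(config$inputs)
  syn_cfg <- do.call(synth_config,
                     c(list(seed = seed), config$simulate_params %||% list()))

  # --- inputs ------------------------------------------------------------
  stage <- "inputs"
  tr <- tryCatch({
    if (simulate) {
      dr_sim <- synth_dose_response(syn_cfg)
      tmt <- synth_tmt(syn_cfg)
      gs <- synth_gene_sets(syn_cfg, tmt$truth, tmt$quant$gene_symbols)
      write_result_csv(tmt$truth, file.path(out_dir, "truth_proteins.csv"))
      write_result_csv(gs$truth, file.path(out_dir, "truth_sets.csv"))
      utils::write.csv(data.frame(drug_s_conc = dr_sim$config$dose_s,
                                  dr_sim$true_delta, check.names = FALSE),
                       file.path(out_dir, "truth_delta.csv"),
                       row.names = FALSE)
      list(dr = dr_sim$dose_response, quant = tmt$quant,
           sets = gs$collection)
    } else {
      inp <- config$inputs
      for (f in unlist(inp))
        if (!file.exists(f)) stop_input("missing input path: ", f)
      manifest$input_digests <- as.list(tools::md5sum(unlist(inp)))
      quant <- read_protein_groups(inp$protein_groups)
      quant <- attach_design(quant, read_design(inp$design))
      list(dr = read_dose_matrix(inp$dose_matrix), quant = quant,
           sets = read_gmt(inp$gene_sets))
    }
  }, error = function(e) fail(stage, e))
  completed <- c(completed, stage)
  logf("inputs ready: ", nrow(tr$quant$intensities), " protein groups, ",
       length(tr$sets$sets), " gene sets")

  # --- synergy -----------------------------------------------------------
  stage <- "synergy"
  syn_conf <- config$synergy %||% list()
  fit <- tryCatch(
    synergy_fit(tr$dr, additivity_band = syn_conf$band %||% 5,
                mode = syn_conf$mode %||% "product"),
    error = function(e) fail(stage, e))
  write_synergy(fit, out_dir)
  manifest$stages$synergy <- list(cells = length(fit$delta),
                                  band = fit$additivity_band,
                                  mode = fit$mode)
  completed <- c(completed, stage)
  logf("synergy: ", sum(fit$labels == "synergy"), " synergistic cells of ",
       length(fit$delta))

  # --- normalize + PCA QC ------------------------------------------------
  stage <- "qc"
  dep_conf <- config$dep %||% list()
  res <- tryCatch({
    norm <- normalize_quant(tr$quant,
                            method = dep_conf$normalization %||% "median_center")
    pca <- pca_samples(norm, n_components = 3)
    write_result_csv(pca_table(pca), file.path(out_dir, "pca_coordinates.csv"),
                     params = list(n_proteins_used = pca$n_proteins_used))
    list(norm = norm, pca = pca)
  }, error = function(e) fail(stage, e))
  norm <- res$norm
  manifest$stages$qc <- list(n_proteins_used = res$pca$n_proteins_used,
                             variance_explained = unname(res$pca$variance_explained))
  completed <- c(completed, stage)
  logf("qc: PCA on ", res$pca$n_proteins_used, " complete-case proteins")

  # --- differential expression, ORA, GSEA per contrast -------------------
  contrasts <- dep_conf$contrasts %||% DEFAULT_CONTRASTS
  gsea_conf <- config$gsea %||% list()
  ora_conf <- config$ora %||% list()
  universe <- unique(norm$gene_symbols[nzchar(norm$gene_symbols)])
  for (ct in contrasts) {
    tag <- sprintf("%s_vs_%s_b%s", ct$numerator, ct$denominator,
                   ct$batch %||% "all")
    stage <- paste0("dep:", tag)
    cmp <- tryCatch(
      dep_compare(norm, ct$numerator, ct$denominator, batch = ct$batch,
                  p_threshold = dep_conf$p_threshold %||% 0.05,
                  fc_threshold = dep_conf$fc_threshold %||% 0.58),
      error = function(e) fail(stage, e))
    write_result_csv(as.data.frame(cmp), file.path(out_dir, paste0("dep_", tag, ".csv")),
                     params = list(contrast = attr(cmp, "contrast"),
                                   batch = ct$batch %||% "all",
                                   p_threshold = attr(cmp, "p_threshold"),
                                   fc_threshold = attr(cmp, "fc_threshold")))
    deps <- filter_deps(cmp)
    writeLines(deps$up, file.path(out_dir, paste0("dep_", tag, "_up.txt")))
    writeLines(deps$down, file.path(out_dir, paste0("dep_", tag, "_down.txt")))
    manifest$stages[[paste0("dep_", tag)]] <-
      list(n_tested = sum(!cmp$flagged), n_dep_up = length(deps$up),
           n_dep_down = length(deps$down))
    completed <- c(completed, stage)
    logf(tag, ": ", length(deps$up), " up, ", length(deps$down), " down")

    # ORA on the SD-rule down-regulated list
    stage <- paste0("ora:", tag)
    sd_down <- tryCatch(
      filter_sd_down(cmp, sd_multiplier = dep_conf$sd_multiplier %||% 1.96),
      error = function(e) fail(stage, e))
    if (length(sd_down) > 0) {
      ora <- tryCatch(
        ora_test(sd_down, tr$sets, universe = universe,
                 p_threshold = ora_conf$p_threshold %||% 0.05),
        error = function(e) fail(stage, e))
      write_result_csv(as.data.frame(ora), file.path(out_dir, paste0("ora_", tag, ".csv")),
                       params = list(criterion = sprintf("p < %.3g",
                                                         attr(ora, "p_threshold"))))
      manifest$stages[[paste0("ora_", tag)]] <-
        list(query_size = length(sd_down),
             n_significant = sum(ora$significant))
    } else {
      logf(tag, ": no SD-rule down-regulated genes, ORA skipped")
      manifest$stages[[paste0("ora_", tag)]] <- list(query_size = 0)
    }
    completed <- c(completed, stage)

    # preranked GSEA on the full ranking
    stage <- paste0("gsea:", tag)
    gsea <- tryCatch(
      gsea_preranked(dep_ranking(cmp), tr$sets,
                     n_perm = gsea_conf$n_perm %||% 1000,
                     weight_exponent = gsea_conf$weight_exponent %||% 1,
                     seed = seed + 1000L,
                     min_size = gsea_conf$min_size %||% 5,
                     max_size = gsea_conf$max_size %||% 500,
                     fdr_threshold = gsea_conf$fdr_threshold %||% 0.25,
                     p_threshold = gsea_conf$p_threshold %||% 0.05),
      error = function(e) fail(stage, e))
    write_result_csv(as.data.frame(gsea), file.path(out_dir, paste0("gsea_", tag, ".csv")),
                     params = list(criterion = sprintf("FDR < %.2g & p < %.2g",
                                                       attr(gsea, "fdr_threshold"),
                                                       attr(gsea, "p_threshold")),
                                   n_perm = attr(gsea, "n_perm"),
                                   seed = seed + 1000L))
    manifest$stages[[paste0("gsea_", tag)]] <-
      list(n_sets = nrow(gsea), n_significant = sum(gsea$significant))
    completed <- c(completed, stage)
  }

  manifest$stages_completed <- completed
  jsonlite_write_manifest(manifest, out_dir)
  logf("done: ", length(completed), " stages")
  invisible(manifest)
}

# manifest writer kept separate so a failing run still records progress
jsonlite_write_manifest <- function(manifest, out_dir) {
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
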