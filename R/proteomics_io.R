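# Readers and writers for the table formats the pipeline touches:
# MaxQuant-style protein-group tables, sample-design tables, GMT gene-set
# collections and RNK ranked lists.

MARKER_COLUMNS <- c(reverse = "Reverse",
                    contaminant = "Potential contaminant",
                    site_only = "Only identified by site")

#' Construct a protein quantification table
#'
#' Protein groups by samples reporter-intensity matrix with per-sample
#' condition and batch annotation. Missing quantifications are `NA`.
#'
#' @param protein_ids character vector of unique protein-group identifiers
#' @param gene_symbols character vector (blanks allowed), uppercased for
#'   gene-set matching
#' @param intensities numeric matrix, proteins x samples; nonnegative
#'   where present, `NA` for missing
#' @param design data.frame with columns `sample`, `condition`, `batch`
#'   (see [read_design()]); may be `NULL` until attached
#' @param filtered_counts named integer vector of rows removed per filter
#' @param log2 logical, whether intensities are on the log2 scale
#' @param normalization character, normalization applied (`"none"` until
#'   [normalize_quant()] is run)
#' @return an object of class `protein_quant`
#' @export
protein_quant <- function(protein_ids, gene_symbols, intensities,
                          design = NULL,
                          filtered_counts = c(reverse = 0L, contaminant = 0L,
                                              site_only = 0L),
                          log2 = FALSE, normalization = "none") {
  intensities <- as.matrix(intensities)
  if (length(protein_ids) != nrow(intensities))
    stop_input("protein_ids length must equal nrow(intensities)")
  if (anyDuplicated(protein_ids))
    stop_input("duplicated protein IDs: ",
               paste(unique(protein_ids[duplicated(protein_ids)]),
                     collapse = ", "))
  if (length(gene_symbols) != length(protein_ids))
    stop_input("gene_symbols length must equal protein_ids length")
  if (!log2 && any(intensities < 0, na.rm = TRUE))
    stop_input("negative intensities are not valid reporter intensities")
  if (is.null(colnames(intensities)))
    stop_input("intensities must carry sample names as column names")
  rownames(intensities) <- protein_ids
  x <- structure(list(protein_ids = as.character(protein_ids),
                      gene_symbols = toupper(as.character(gene_symbols)),
                      intensities = intensities,
                      sample_names = colnames(intensities),
                      design = NULL,
                      filtered_counts = filtered_counts,
                      log2 = log2, normalization = normalization),
                 class = "protein_quant")
  if (!is.null(design)) x <- attach_design(x, design)
  x
}

#' @export
print.protein_quant <- function(x, ...) {
  cat(sprintf("Protein quantification table: %d protein groups x %d samples\n",
              nrow(x$intensities), ncol(x$intensities)))
  cat(sprintf("  scale: %s, normalization: %s, missing: %.1f%%\n",
              if (x$log2) "log2" else "linear", x$normalization,
              100 * mean(is.na(x$intensities))))
  if (sum(x$filtered_counts) > 0)
    cat("  filtered rows:",
        paste(names(x$filtered_counts), x$filtered_counts, sep = "=",
              collapse = ", "), "\n")
  if (!is.null(x$design))
    print(table(condition = x$design$condition, batch = x$design$batch))
  invisible(x)
}

#' Attach a sample design to a quantification table
#'
#' @param x a `protein_quant`
#' @param design data.frame from [read_design()]
#' @return `x` with validated design (rows ordered to match the samples)
#' @export
attach_design <- function(x, design) {
  missing <- setdiff(x$sample_names, design$sample)
  if (length(missing))
    stop_input("samples present in the quantification table but absent ",
               "from the design: ", paste(missing, collapse = ", "))
  idx <- match(x$sample_names, design$sample)
  x$design <- design[idx, , drop = FALSE]
  rownames(x$design) <- NULL
  x
}

#' Read a MaxQuant-style protein-groups table
#'
#' Tab-separated with a header row. Rows flagged `+` in any present
#' marker column (`Reverse`, `Potential contaminant`,
#' `Only identified by site`) are removed and counted. Reporter
#' intensities of exactly 0 are recorded as missing (`NA`), the standard
#' convention for unquantified channels.
#'
#' @param path file path
#' @param intensity_column_prefix prefix selecting the per-channel
#'   reporter columns; sample names are the remainder of each header.
#'   Default `"Reporter intensity corrected"`.
#' @param id_column,gene_column header names for protein-group IDs and
#'   gene symbols
#' @return a `protein_quant` (design not yet attached)
#' @export
read_protein_groups <- function(path,
                                intensity_column_prefix = "Reporter intensity corrected",
                                id_column = "Protein IDs",
                                gene_column = "Gene names") {
  if (!file.exists(path)) stop_input("no such file: ", path)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "")
  int_cols <- grep(paste0("^", intensity_column_prefix), names(tab),
                   value = TRUE)
  if (!length(int_cols))
    stop_input("no intensity columns with prefix '",
               intensity_column_prefix, "'; available headers: ",
               paste(names(tab), collapse = ", "))
  present <- MARKER_COLUMNS[MARKER_COLUMNS %in% names(tab)]
  filtered <- stats::setNames(integer(length(MARKER_COLUMNS)),
                              names(MARKER_COLUMNS))
  keep <- rep(TRUE, nrow(tab))
  for (nm in names(present)) {
    # rows already removed by an earlier marker are not double-counted
    hit <- tab[[present[[nm]]]] == "+" & keep
    filtered[[nm]] <- sum(hit, na.rm = TRUE)
    keep <- keep & !(hit %in% TRUE)
  }
  tab <- tab[keep, , drop = FALSE]
  ids <- as.character(tab[[id_column]])
  if (is.null(tab[[id_column]]))
    stop_input("missing ID column '", id_column, "'")
  if (anyDuplicated(ids))
    stop_input("duplicated protein IDs after filtering: ",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  genes <- if (!is.null(tab[[gene_column]])) as.character(tab[[gene_column]])
           else rep("", length(ids))
  mat <- as.matrix(tab[, int_cols, drop = FALSE])
  storage.mode(mat) <- "numeric"
  mat[mat == 0] <- NA_real_
  colnames(mat) <- trimws(sub(paste0("^", intensity_column_prefix), "",
                              int_cols))
  protein_quant(ids, genes, mat, filtered_counts = filtered)
}

#' Write a protein quantification table in the MaxQuant dialect
#'
#' Inverse of [read_protein_groups()]: missing values are written as 0,
#' marker columns are emitted empty.
#'
#' @param x a `protein_quant` with linear-scale intensities
#' @param path output path (tab-separated)
#' @param intensity_column_prefix prefix for the per-sample columns
#' @return `path`, invisibly
#' @export
write_protein_groups <- function(x, path,
                                 intensity_column_prefix = "Reporter intensity corrected") {
  if (x$log2) stop_input("refusing to write log2-scale intensities in the ",
                         "linear reporter dialect; supply the raw table")
  mat <- x$intensities
  mat[is.na(mat)] <- 0
  out <- data.frame(`Protein IDs` = x$protein_ids,
                    `Gene names` = x$gene_symbols,
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(mat)))
    out[[paste(intensity_column_prefix, colnames(mat)[j])]] <- mat[, j]
  out[["Reverse"]] <- ""
  out[["Potential contaminant"]] <- ""
  out[["Only identified by site"]] <- ""
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample-design table
#'
#' Delimited file with columns `sample`, `condition`, `batch`, mapping
#' each TMT channel to its treatment condition and MS batch.
#'
#' @param path file path (comma- or tab-separated, inferred)
#' @param conditions allowed condition vocabulary
#' @return data.frame with character `sample`, factor-free `condition`,
#'   integer `batch`
#' @export
read_design <- function(path, conditions = c("CTL", "P", "S", "PS")) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  d <- utils::read.table(path, sep = sep, header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("sample", "condition", "batch")
  if (!all(need %in% names(d)))
    stop_input("design must have columns sample, condition, batch; got: ",
               paste(names(d), collapse = ", "))
  if (anyDuplicated(d$sample))
    stop_input("duplicate sample rows in design: ",
               paste(unique(d$sample[duplicated(d$sample)]), collapse = ", "))
  unknown <- setdiff(unique(d$condition), conditions)
  if (length(unknown))
    stop_input("unknown condition(s) ", paste(unknown, collapse = ", "),
               "; allowed: ", paste(conditions, collapse = ", "))
  d$sample <- as.character(d$sample)
  d$batch <- as.integer(d$batch)
  d[need]
}

#' Write a sample-design table
#' @param design data.frame with sample, condition, batch
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_design <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a gene-set collection
#'
#' @param sets named list; each element a character vector of member gene
#'   symbols (uppercased on construction)
#' @param descriptions optional named character vector of set descriptions
#' @param universe optional explicit background gene list
#' @return object of class `gene_set_collection`
#' @export
gene_set_collection <- function(sets, descriptions = NULL, universe = NULL) {
  if (!length(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop_input("sets must be a non-empty named list")
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty))
    stop_input("empty gene set(s): ", paste(empty, collapse = ", "))
  sets <- lapply(sets, function(g) unique(toupper(g)))
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  structure(list(sets = sets,
                 descriptions = descriptions[names(sets)],
                 universe = if (is.null(universe)) NULL else unique(toupper(universe))),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- lengths(x$sets)
  cat(sprintf("Gene-set collection: %d sets, sizes %d-%d (median %.0f)\n",
              length(x$sets), min(sz), max(sz), stats::median(sz)))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' One set per tab-separated line: name, description, then member genes.
#'
#' @param path file path
#' @return a [gene_set_collection()]
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop_input("GMT line ", i, " has no members (need name, ",
                 "description, >=1 gene)")
    sets[[f[1]]] <- f[-(1:2)]
    desc[f[1]] <- f[2]
  }
  gene_set_collection(sets, desc)
}

#' Write a gene-set collection in GMT format
#' @param x a `gene_set_collection`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gmt <- function(x, path) {
  lines <- vapply(names(x$sets), function(nm)
    paste(c(nm, x$descriptions[[nm]] %||% "", x$sets[[nm]]), collapse = "\t"),
    "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an RNK ranked gene list
#'
#' Two tab-separated columns: gene, score. Returned sorted by decreasing
#' score; ties keep their input order (stable sort).
#'
#' @param path file path
#' @return named numeric vector of scores, names = genes, sorted
#'   descending
#' @export
read_rnk <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 2)
  if (length(bad))
    stop_input("RNK line ", bad[1], " lacks a gene TAB score pair")
  genes <- toupper(vapply(f, `[`, "", 1))
  scores <- suppressWarnings(as.numeric(vapply(f, `[`, "", 2)))
  if (anyNA(scores))
    stop_input("non-numeric RNK score at line ", which(is.na(scores))[1])
  if (anyDuplicated(genes))
    stop_input("duplicated gene in RNK file: ",
               genes[duplicated(genes)][1])
  ord <- order(-scores)  # stable in R: ties keep input order
  stats::setNames(scores[ord], genes[ord])
}

#' Write a ranked gene list in RNK format
#' @param ranked named numeric vector (names = genes)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_rnk <- function(ranked, path) {
  writeLines(paste(names(ranked), format(ranked, trim = TRUE, digits = 15),
                   sep = "\t"), path)
  invisible(path)
}
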