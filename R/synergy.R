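# Delta synergy scoring on dose-response matrices.
#
# The observed inhibition at each concentration pair is compared with the
# inhibition expected if the two drugs acted as independent agents; the
# difference (delta, in percentage points) is the synergy score: positive
# means synergy, near zero additivity, negative antagonism.

#' Construct a dose-response matrix
#'
#' A viability grid indexed by the concentration ladders of two drugs:
#' rows follow drug S, columns follow drug P. Values are percent viability;
#' values outside \[0, 100\] are measurement noise and are preserved.
#'
#' @param viability numeric matrix of percent viability,
#'   `length(drug_s_concs)` rows by `length(drug_p_concs)` columns
#' @param drug_s_concs,drug_p_concs strictly increasing concentration
#'   ladders (micromolar); the first entry may be 0 (single-agent margin)
#' @param drug_s_name,drug_p_name drug labels
#' @return an object of class `dose_response`
#' @export
dose_response <- function(viability, drug_s_concs, drug_p_concs,
                          drug_s_name = "drug_S", drug_p_name = "drug_P") {
  viability <- as.matrix(viability)
  if (!is.numeric(viability))
    stop_input("viability must be a numeric matrix")
  if (nrow(viability) != length(drug_s_concs) ||
      ncol(viability) != length(drug_p_concs))
    stop_input("viability must be ", length(drug_s_concs), " x ",
               length(drug_p_concs), " (rows = drug S concentrations, ",
               "columns = drug P concentrations); got ",
               nrow(viability), " x ", ncol(viability))
  for (v in list(drug_s_concs, drug_p_concs))
    if (any(diff(v) <= 0))
      stop_input("concentration ladders must be strictly increasing")
  bad <- which(!is.finite(viability), arr.ind = TRUE)
  if (nrow(bad))
    stop_input("non-finite viability at row ", bad[1, 1], ", column ",
               bad[1, 2])
  dimnames(viability) <- list(format(drug_s_concs, trim = TRUE),
                              format(drug_p_concs, trim = TRUE))
  structure(list(viability = viability,
                 drug_s_concs = as.numeric(drug_s_concs),
                 drug_p_concs = as.numeric(drug_p_concs),
                 drug_s_name = drug_s_name, drug_p_name = drug_p_name),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("Dose-response matrix: %s (rows, %d doses) x %s (columns, %d doses)\n",
              x$drug_s_name, length(x$drug_s_concs),
              x$drug_p_name, length(x$drug_p_concs)))
  print(round(x$viability, 1))
  invisible(x)
}

#' Read a dose-response matrix from delimited text
#'
#' Layout: first row holds the drug P concentrations, first column the
#' drug S concentrations, body the viability percentages. The top-left
#' header cell may carry the two drug names separated by `/`.
#'
#' @param path file path
#' @param sep field separator; default auto-detects tab vs comma
#' @return a [dose_response()] object
#' @export
read_dose_matrix <- function(path, sep = NULL) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  corner <- as.character(raw[1, 1])
  names2 <- strsplit(corner, "/", fixed = TRUE)[[1]]
  p_concs <- suppressWarnings(as.numeric(raw[1, -1]))
  s_concs <- suppressWarnings(as.numeric(raw[-1, 1]))
  if (anyNA(p_concs) || anyNA(s_concs))
    stop_input("non-numeric concentration in header row/column of ", path)
  body <- as.matrix(raw[-1, -1, drop = FALSE])
  storage.mode(body) <- "numeric"
  dose_response(body, s_concs, p_concs,
                drug_s_name = if (length(names2) == 2) trimws(names2[1]) else "drug_S",
                drug_p_name = if (length(names2) == 2) trimws(names2[2]) else "drug_P")
}

#' Convert percent viability to percent inhibition
#'
#' Inhibition = 100 - viability, elementwise. No clamping: inhibitions
#' below 0 or above 100 are propagated as-is.
#'
#' @param viability numeric vector or matrix of percent viability
#' @return object of the same shape with inhibition percentages
#' @export
viability_to_inhibition <- function(viability) {
  bad <- which(!is.finite(viability))
  if (length(bad)) {
    if (is.matrix(viability)) {
      ij <- arrayInd(bad[1], dim(viability))
      stop_input("non-finite viability at row ", ij[1], ", column ", ij[2])
    }
    stop_input("non-finite viability at position ", bad[1])
  }
  100 - viability
}

#' Expected inhibition of a drug combination under independent action
#'
#' For single-agent inhibition vectors `Ii0` (drug S alone) and `I0j`
#' (drug P alone), the default expectation is the product rule
#' `E[i,j] = Ii0[i] * I0j[j] / 100`. Mode `"bliss"` instead applies
#' Bliss independence on inhibitions,
#' `E[i,j] = Ii0[i] + I0j[j] - Ii0[i] * I0j[j] / 100`.
#'
#' @param single_agent_s numeric vector, inhibition of drug S alone at
#'   each row concentration
#' @param single_agent_p numeric vector, inhibition of drug P alone at
#'   each column concentration
#' @param mode `"product"` (default) or `"bliss"`
#' @return matrix of expected inhibition,
#'   `length(single_agent_s)` x `length(single_agent_p)`
#' @export
expected_inhibition <- function(single_agent_s, single_agent_p,
                                mode = c("product", "bliss")) {
  mode <- match.arg(mode)
  if (!is.numeric(single_agent_s) || !is.numeric(single_agent_p) ||
      any(!is.finite(single_agent_s)) || any(!is.finite(single_agent_p)))
    stop_input("single-agent inhibition vectors must be finite numeric")
  prod <- outer(single_agent_s, single_agent_p) / 100
  if (mode == "product") prod
  else outer(single_agent_s, single_agent_p, `+`) - prod
}

#' Delta synergy scores
#'
#' Elementwise observed minus expected inhibition, in percentage points.
#'
#' @param observed,expected inhibition matrices of equal shape
#' @return delta matrix
#' @export
delta_scores <- function(observed, expected) {
  if (!identical(dim(as.matrix(observed)), dim(as.matrix(expected))))
    stop_input("observed and expected matrices differ in shape")
  observed - expected
}

#' Classify each concentration pair by its delta score
#'
#' Delta above the additivity band is synergy, below its negative is
#' antagonism, inside the band additive.
#'
#' @param delta delta matrix (percentage points)
#' @param additivity_band nonnegative half-width of the "near zero" band
#' @return character matrix with entries `"synergy"`, `"additive"`,
#'   `"antagonism"`
#' @export
classify_interaction <- function(delta, additivity_band = 5) {
  if (!is.numeric(additivity_band) || length(additivity_band) != 1 ||
      is.na(additivity_band) || additivity_band < 0)
    stop_input("additivity_band must be a single nonnegative number")
  lab <- ifelse(delta > additivity_band, "synergy",
                ifelse(delta < -additivity_band, "antagonism", "additive"))
  if (is.matrix(delta)) dimnames(lab) <- dimnames(delta)
  lab
}

#' Fit the delta synergy model to a dose-response matrix
#'
#' Transforms viability to inhibition, extracts (or accepts) the
#' single-agent margins, computes the independent-action expectation and
#' the delta score for every concentration pair, and classifies each pair.
#'
#' Margins: when the concentration ladders contain a zero dose, the
#' zero-dose row and column are the single-agent measurements. For those
#' margin cells only one drug is present, so their expectation is the
#' margin's own single-agent inhibition (hence delta = 0 there by
#' construction); the zero-zero cell uses the formula with both margins'
#' own values (`Ii0[1] * I0j[1] / 100`, typically 0). Alternatively supply
#' `single_agent_s`/`single_agent_p` explicitly, in which case every cell
#' of the matrix is treated as a combination measurement.
#'
#' If a list of matrices is supplied, viability is averaged per cell
#' across replicates before the transform.
#'
#' @param x a [dose_response()] object, or a list of them (replicates with
#'   identical ladders)
#' @param additivity_band half-width of the additive band (percentage
#'   points); default 5
#' @param mode expectation model, `"product"` (default) or `"bliss"`;
#'   see [expected_inhibition()]
#' @param single_agent_s,single_agent_p optional explicit single-agent
#'   inhibition vectors (used when the matrix has no zero-dose margins)
#' @return an object of class `synergy_fit` with components
#'   `observed_inhibition`, `expected_inhibition`, `delta`, `labels`
#'   (all matrices of the input shape), `additivity_band`, `mode`,
#'   and the input `dose_response`
#' @examples
#' v <- matrix(c(100, 70, 60, 40), 2, 2)
#' dr <- dose_response(v, c(0, 4), c(0, 1))
#' fit <- synergy_fit(dr)
#' fit$delta
#' @export
synergy_fit <- function(x, additivity_band = 5, mode = c("product", "bliss"),
                        single_agent_s = NULL, single_agent_p = NULL) {
  mode <- match.arg(mode)
  if (is.list(x) && !inherits(x, "dose_response")) {
    if (!all(vapply(x, inherits, TRUE, "dose_response")))
      stop_input("replicate list must contain dose_response objects")
    ref <- x[[1]]
    for (r in x[-1])
      if (!identical(r$drug_s_concs, ref$drug_s_concs) ||
          !identical(r$drug_p_concs, ref$drug_p_concs))
        stop_input("replicate matrices must share concentration ladders")
    vbar <- Reduce(`+`, lapply(x, `[[`, "viability")) / length(x)
    x <- dose_response(vbar, ref$drug_s_concs, ref$drug_p_concs,
                       ref$drug_s_name, ref$drug_p_name)
  }
  if (!inherits(x, "dose_response"))
    stop_input("x must be a dose_response object (see dose_response())")

  obs <- viability_to_inhibition(x$viability)
  have_margins <- x$drug_s_concs[1] == 0 && x$drug_p_concs[1] == 0
  explicit <- !is.null(single_agent_s) && !is.null(single_agent_p)

  if (explicit) {
    if (length(single_agent_s) != nrow(obs) ||
        length(single_agent_p) != ncol(obs))
      stop_input("single-agent vectors must match the matrix shape")
    exp_inh <- expected_inhibition(single_agent_s, single_agent_p, mode)
  } else if (have_margins) {
    Ii0 <- obs[, 1]   # drug S alone (column at P = 0)
    I0j <- obs[1, ]   # drug P alone (row at S = 0)
    exp_inh <- expected_inhibition(Ii0, I0j, mode)
    # single-agent cells: only one drug present, expectation is that
    # drug's own inhibition
    exp_inh[, 1] <- obs[, 1]
    exp_inh[1, ] <- obs[1, ]
    exp_inh[1, 1] <- if (mode == "product") Ii0[1] * I0j[1] / 100
                     else Ii0[1] + I0j[1] - Ii0[1] * I0j[1] / 100
  } else {
    stop_input("the matrix has no zero-dose margins and no explicit ",
               "single-agent vectors were given; either include a ",
               "zero-concentration row and column (single-agent ",
               "measurements) or pass single_agent_s and single_agent_p")
  }
  dimnames(exp_inh) <- dimnames(obs)
  delta <- delta_scores(obs, exp_inh)
  labels <- classify_interaction(delta, additivity_band)
  structure(list(observed_inhibition = obs, expected_inhibition = exp_inh,
                 delta = delta, labels = labels,
                 additivity_band = additivity_band, mode = mode,
                 dose_response = x),
            class = "synergy_fit")
}

#' @export
print.synergy_fit <- function(x, ...) {
  cat(sprintf("Delta synergy scores (%s expectation, additivity band %.3g)\n",
              x$mode, x$additivity_band))
  cat(sprintf("%s (rows) x %s (columns)\n",
              x$dose_response$drug_s_name, x$dose_response$drug_p_name))
  print(round(x$delta, 2))
  invisible(x)
}

#' @export
summary.synergy_fit <- function(object, ...) {
  tab <- table(factor(object$labels,
                      levels = c("synergy", "additive", "antagonism")))
  cat(sprintf("Delta synergy summary (%s expectation)\n", object$mode))
  cat(sprintf("  cells: %d  |  synergy %d, additive %d, antagonism %d\n",
              length(object$delta), tab[["synergy"]], tab[["additive"]],
              tab[["antagonism"]]))
  cat(sprintf("  delta range: [%.2f, %.2f], mean %.2f\n",
              min(object$delta), max(object$delta), mean(object$delta)))
  invisible(object)
}

#' @export
as.data.frame.synergy_fit <- function(x, ...) {
  dr <- x$dose_response
  data.frame(
    drug_s_conc = rep(dr$drug_s_concs, times = length(dr$drug_p_concs)),
    drug_p_conc = rep(dr$drug_p_concs, each = length(dr$drug_s_concs)),
    observed_inhibition = as.vector(x$observed_inhibition),
    expected_inhibition = as.vector(x$expected_inhibition),
    delta = as.vector(x$delta),
    label = as.vector(x$labels),
    stringsAsFactors = FALSE)
}

#' Heatmap of delta synergy scores
#'
#' Diverging palette: cold blues for antagonism, warm oranges for synergy,
#' white near zero; each cell is annotated with its delta value.
#'
#' @param x a `synergy_fit`
#' @param ... passed to [graphics::image()]
#' @export
plot.synergy_fit <- function(x, ...) {
  d <- x$delta
  lim <- max(abs(d), 1)
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#E66101"))(101)
  nr <- nrow(d); nc <- ncol(d)
  graphics::image(seq_len(nc), seq_len(nr), t(d)[, nr:1, drop = FALSE],
                  zlim = c(-lim, lim), col = pal, axes = FALSE,
                  xlab = x$dose_response$drug_p_name,
                  ylab = x$dose_response$drug_s_name, ...)
  graphics::axis(1, at = seq_len(nc),
                 labels = format(x$dose_response$drug_p_concs, trim = TRUE))
  graphics::axis(2, at = seq_len(nr),
                 labels = rev(format(x$dose_response$drug_s_concs, trim = TRUE)))
  for (i in seq_len(nr)) for (j in seq_len(nc))
    graphics::text(j, nr - i + 1, sprintf("%.1f", d[i, j]), cex = 0.7)
  invisible(x)
}

#' Write synergy results to disk
#'
#' Emits a long-format CSV (one row per concentration pair) and a
#' square-matrix CSV of deltas.
#'
#' @param fit a `synergy_fit`
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix
#' @return character vector of the paths written, invisibly
#' @export
write_synergy <- function(fit, dir, prefix = "synergy") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long_path <- file.path(dir, paste0(prefix, "_long.csv"))
  mat_path <- file.path(dir, paste0(prefix, "_delta_matrix.csv"))
  write_result_csv(as.data.frame(fit), long_path,
                   params = list(mode = fit$mode,
                                 additivity_band = fit$additivity_band))
  dmat <- data.frame(drug_s_conc = fit$dose_response$drug_s_concs,
                     fit$delta, check.names = FALSE)
  utils::write.csv(dmat, mat_path, row.names = FALSE)
  invisible(c(long_path, mat_path))
}
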