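#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a consistent error class
#' @noRd
stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("synprot_input_error", "error")))
}

#' Write a data.frame as CSV with a comment header recording provenance
#'
#' Result tables carry one or more `#`-prefixed header lines with the
#' package version and the parameters that produced them, so a table on
#' disk is self-describing.
#'
#' @param df data.frame to write
#' @param path output file path
#' @param params named list echoed into the header comment
#' @return `path`, invisibly
#' @export
write_result_csv <- function(df, path, params = list()) {
  ver <- as.character(utils::packageVersion("synprot"))
  hdr <- sprintf("# synprot %s", ver)
  if (length(params)) {
    kv <- paste(names(params), vapply(params, function(p)
      paste(format(p, trim = TRUE), collapse = ";"), ""), sep = "=")
    hdr <- c(hdr, paste0("# ", paste(kv, collapse = " ")))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a CSV written by [write_result_csv()]
#' @param path file path
#' @return data.frame (header comments skipped)
#' @export
read_result_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
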