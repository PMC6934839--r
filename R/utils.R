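#' @importFrom stats rgamma rnorm rexp rbinom runif quantile pchisq setNames
#' @importFrom utils head tail
#' @import data.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn_fmt <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Format numbers for text output
#'
#' Deterministic plain formatting (no scientific notation drift) so that
#' identical objects always serialise to identical bytes.
#' @param x numeric vector
#' @param digits significant digits
#' @return character vector
#' @keywords internal
num_chr <- function(x, digits = 6L) {
  out <- formatC(x, format = "g", digits = digits)
  gsub(" ", "", out, fixed = TRUE)
}

# Write a TSV with a header line; provenance comments prefixed with '#'.
write_tsv <- function(df, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df)) {
    cols <- lapply(df, function(col) {
      if (is.numeric(col) && !is.integer(col)) num_chr(col, 10L) else as.character(col)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

read_tsv <- function(path, ...) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  as.data.frame(data.table::fread(text = lines, sep = "\t", header = TRUE,
                                  data.table = FALSE, ...))
}
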