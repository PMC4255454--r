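#' Read an expression matrix from tab-separated text
#'
#' Expected layout: first row sample identifiers, first column gene
#' identifiers, tab-separated numeric cells; empty fields or `NA` mark
#' missing values.  Malformed input (ragged rows, duplicate gene ids,
#' non-numeric cells) raises an error naming the offending line.
#'
#' @param path file path.
#' @return numeric genes x samples matrix with gene ids as rownames and
#'   sample ids as colnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = "\t", quote = "",
                            blank.lines.skip = FALSE)
  if (length(nf) < 2L) stop("file has no data rows: ", path, call. = FALSE)
  ragged <- which(nf != nf[1L])
  if (length(ragged)) {
    stop("ragged rows (field count differs from header) at line(s): ",
         paste(utils::head(ragged, 5L), collapse = ", "), call. = FALSE)
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", check.names = FALSE,
                           row.names = NULL, na.strings = c("NA", ""))
  ids <- raw[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate gene identifier(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(vals) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric cell(s), e.g. \"", cells[bad[1L, , drop = FALSE]],
         "\" at line ", bad[1L, 1L] + 1L, ", column ", bad[1L, 2L] + 1L,
         call. = FALSE)
  }
  dimnames(vals) <- list(ids, colnames(raw)[-1L])
  .validate_expression(vals)
}

#' Write an expression matrix as tab-separated text
#'
#' Mirrors the [read_expression()] format; missing values are written as
#' `NA`.
#'
#' @param mat genes x samples numeric matrix with rownames.
#' @param path output file path.
#' @export
write_expression <- function(mat, path) {
  mat <- .validate_expression(mat)
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Table-style formatting: 3 decimals for effect-size columns, 4
# significant digits E-notation for p-values.
.fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.3f", x))
.fmt_p <- function(x) ifelse(is.na(x), "NA",
                             toupper(formatC(x, digits = 3, format = "e")))

#' Write a pipeline result table
#'
#' Writes the triplet results in the standard layout — columns `X1`,
#' `X2`, `X3`, `rho_diff`, `MLA`, `Wald`, `p-value`, `p-adj`, `model` —
#' with the run configuration echoed in `#`-prefixed header lines for
#' provenance.  Effect sizes are printed with 3 decimals and p-values in
#' 4-significant-digit scientific notation (`2.501E-12` style);
#' [read_results()] recovers the table at that printed precision.
#'
#' @param results a [run_pipeline()] result (or any data.frame with the
#'   same columns).
#' @param path output path.
#' @param config optional named list echoed into the header.
#' @export
write_results <- function(results, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) {
    for (k in names(config)) {
      writeLines(paste0("# ", k, "=", format(config[[k]])), con)
    }
  }
  writeLines(paste(c("X1", "X2", "X3", "rho_diff", "MLA", "Wald",
                     "p-value", "p-adj", "model"), collapse = "\t"), con)
  if (nrow(results)) {
    lines <- paste(results$x1, results$x2, results$x3,
                   .fmt_num(results$rho_diff), .fmt_num(results$mla),
                   .fmt_num(results$wald), .fmt_p(results$pvalue),
                   .fmt_p(results$padj), results$model, sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path file path.
#' @return data.frame with the [run_pipeline()] column names; the header
#'   configuration, if present, is attached as attribute `"config"`.
#' @export
read_results <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  config <- NULL
  if (length(hdr)) {
    kv <- sub("^#\\s*", "", lines[hdr])
    config <- stats::setNames(as.list(sub("^[^=]*=", "", kv)),
                              sub("=.*$", "", kv))
  }
  body <- lines[setdiff(seq_along(lines), hdr)]
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  names(df) <- c("x1", "x2", "x3", "rho_diff", "mla", "wald", "pvalue",
                 "padj", "model")
  for (col in c("rho_diff", "mla", "wald", "pvalue", "padj")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  attr(df, "config") <- config
  df
}
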