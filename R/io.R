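#' Read a UMI count matrix
#'
#' Reads either a Matrix Market coordinate file with companion one-id-per-line
#' gene and cell files, or a dense delimited text matrix. Rows are genes and
#' columns are cells; use \code{transpose = TRUE} for inputs stored cells x
#' genes. Entries must be non-negative integers; offending coordinates are
#' named in the error.
#'
#' @param path path to the \code{.mtx} or dense text file.
#' @param format \code{"matrix-market"} or \code{"dense"}.
#' @param geneFile,cellFile id files for matrix-market input (one id per line);
#'   optional for dense input.
#' @param batchFile optional per-cell batch file (one label per line).
#' @param transpose input is stored cells x genes.
#' @param sep field separator for dense input (whitespace by default).
#' @return A \linkS4class{CountData}.
#' @examples
#' f <- tempfile(); writeLines(c("0 1", "2 0", "5 3"), f)
#' umiCounts(readCountMatrix(f, format = "dense"))
#' @export
readCountMatrix <- function(path, format = c("matrix-market", "dense"),
                            geneFile = NULL, cellFile = NULL, batchFile = NULL,
                            transpose = FALSE, sep = "") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "matrix-market") {
    m <- Matrix::readMM(path)
    badEntry <- which(m@x < 0 | m@x != floor(m@x))
    if (length(badEntry)) {
      tr <- methods::as(m, "TsparseMatrix")
      stop(sprintf("non-integer or negative entry at (row %d, col %d): %g",
                   tr@i[badEntry[1]] + 1L, tr@j[badEntry[1]] + 1L,
                   tr@x[badEntry[1]]))
    }
    m <- as.matrix(m)
    if (transpose) m <- t(m)
    if (is.null(geneFile) || is.null(cellFile))
      stop("matrix-market input requires geneFile and cellFile")
    genes <- readLines(geneFile)
    cells <- readLines(cellFile)
  } else {
    tab <- utils::read.table(path, sep = sep, header = FALSE,
                             colClasses = "numeric")
    m <- as.matrix(tab)
    dimnames(m) <- NULL
    if (transpose) m <- t(m)
    bad <- which(m < 0 | m != floor(m), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-integer or negative entry at (row %d, col %d): %g",
                   bad[1, 1], bad[1, 2], m[bad[1, 1], bad[1, 2]]))
    genes <- if (!is.null(geneFile)) readLines(geneFile) else
      sprintf("gene%d", seq_len(nrow(m)))
    cells <- if (!is.null(cellFile)) readLines(cellFile) else
      sprintf("cell%d", seq_len(ncol(m)))
  }
  if (length(genes) != nrow(m))
    stop(sprintf("gene id count (%d) does not match row count (%d)",
                 length(genes), nrow(m)))
  if (length(cells) != ncol(m))
    stop(sprintf("cell id count (%d) does not match column count (%d)",
                 length(cells), ncol(m)))
  batch <- NULL
  if (!is.null(batchFile)) {
    batch <- readLines(batchFile)
    if (length(batch) != ncol(m))
      stop("batch file length does not match the cell count")
  }
  CountData(m, geneIds = genes, cellIds = cells, batch = batch)
}

#' Write a count matrix in Matrix Market format
#'
#' Writes \code{<prefix>.mtx}, \code{<prefix>.genes.txt},
#' \code{<prefix>.cells.txt} and, if batches are present,
#' \code{<prefix>.batch.txt}.
#'
#' @param x a \linkS4class{CountData}.
#' @param prefix output path prefix.
#' @return Invisibly, the paths written.
#' @export
writeCountMatrix <- function(x, prefix) {
  m <- methods::as(Matrix::Matrix(umiCounts(x), sparse = TRUE), "generalMatrix")
  paths <- c(mtx = paste0(prefix, ".mtx"), genes = paste0(prefix, ".genes.txt"),
             cells = paste0(prefix, ".cells.txt"))
  Matrix::writeMM(m, paths["mtx"])
  writeLines(rownames(x), paths["genes"])
  writeLines(colnames(x), paths["cells"])
  if (!is.null(batchOf(x))) {
    paths["batch"] <- paste0(prefix, ".batch.txt")
    writeLines(as.character(batchOf(x)), paths["batch"])
  }
  invisible(paths)
}

#' Read candidate label sets
#'
#' One column per candidate label set, one row per cell, with a header row of
#' label-set names. Arbitrary cluster names are re-coded to 1..K in
#' first-occurrence order.
#'
#' @param path delimited text file (tab or comma separated).
#' @return A list of \linkS4class{LabelSet} objects in file column order.
#' @export
readLabelSets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE)
  if (ncol(tab) == 0L || nrow(tab) == 0L) stop("no label columns found")
  if (anyNA(tab) || any(tab == ""))
    stop("label column has missing entries")
  lapply(names(tab), function(nm) LabelSet(tab[[nm]], name = nm))
}

#' Write a result table as delimited text
#'
#' Numeric columns are written with 17 significant digits so a read-back
#' reproduces the doubles bit-identically. Optional provenance lines are
#' prepended as '#' comments.
#'
#' @param table a data.frame of results (e.g. from \code{rankLabelSets}).
#' @param path output file.
#' @param comments character vector of provenance lines (written as
#'   \code{# ...}).
#' @param sep field separator.
#' @return Invisibly, \code{path}.
#' @export
writeReport <- function(table, path, comments = character(), sep = "\t") {
  out <- as.data.frame(table)
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(out, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a report written by \code{writeReport}
#'
#' @param path report file.
#' @param sep field separator.
#' @return data.frame with comment lines skipped.
#' @export
readReport <- function(path, sep = "\t") {
  utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                    check.names = FALSE)
}
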