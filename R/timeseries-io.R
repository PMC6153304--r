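#' @include AllClasses.R AllGenerics.R accessors.R
NULL

#' Construct a TimeSeriesMatrix
#'
#' @param values numeric T x n matrix, rows = time, columns = nodes.
#' @param nodeLabels optional character labels; defaults to column names
#'   or "V1".."Vn".
#' @param standardized logical; set TRUE only if `values` already follow
#'   the standardization convention (checked by the validity method).
#' @return a [TimeSeriesMatrix-class].
#' @examples
#' ts <- TimeSeriesMatrix(matrix(rnorm(40), 20, 2))
#' @export
TimeSeriesMatrix <- function(values, nodeLabels = NULL,
                             standardized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(nodeLabels)) {
    nodeLabels <- colnames(values)
    if (is.null(nodeLabels))
      nodeLabels <- paste0("V", seq_len(ncol(values)))
  }
  colnames(values) <- nodeLabels
  new("TimeSeriesMatrix", values = values,
      nodeLabels = as.character(nodeLabels),
      standardized = isTRUE(standardized))
}

## Sniff the delimiter of the first non-empty line: comma wins if present,
## otherwise any whitespace.
sniffDelimiter <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("file '", path, "' is empty")
  if (grepl(",", first, fixed = TRUE)) "," else ""
}

#' Read a time-series matrix from a delimited text file
#'
#' Accepts CSV or whitespace-delimited text with one column per node and
#' one row per time point, with an optional single header line of node
#' labels. The delimiter is auto-detected from the first line unless
#' given.
#'
#' @param path file path.
#' @param delimiter "," for CSV, "" for whitespace, or NULL to sniff.
#' @param transpose set TRUE if the file stores nodes in rows and time in
#'   columns.
#' @return a [TimeSeriesMatrix-class] with `standardized = FALSE`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("a,b", "1,2", "3,4", "5,6"), f)
#' loadTimeSeries(f)
#' @export
loadTimeSeries <- function(path, delimiter = NULL, transpose = FALSE) {
  if (!file.exists(path)) stop("file '", path, "' does not exist")
  if (is.null(delimiter)) delimiter <- sniffDelimiter(path)
  first <- scan(path, what = "character", nlines = 1L, sep = delimiter,
                quiet = TRUE, strip.white = TRUE)
  first <- first[nzchar(first)]
  header <- length(first) > 0L &&
    any(is.na(suppressWarnings(as.numeric(first))))
  tab <- tryCatch(
    read.table(path, header = header, sep = delimiter,
               colClasses = "character", strip.white = TRUE,
               blank.lines.skip = TRUE),
    error = function(e) stop("malformed (ragged?) table in '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  m <- suppressWarnings(
    matrix(as.numeric(as.matrix(tab)), nrow(tab), ncol(tab)))
  colnames(m) <- colnames(tab)
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0L)[1L] + as.integer(header)
    stop("non-numeric value at data line ", bad, " of '", path, "'")
  }
  if (transpose) m <- t(m)
  if (ncol(m) < 2L)
    stop("need at least 2 node columns, found ", ncol(m))
  labels <- if (header && !transpose) colnames(tab) else NULL
  TimeSeriesMatrix(m, nodeLabels = labels)
}

#' Write a time-series matrix to a delimited text file
#'
#' @param ts a [TimeSeriesMatrix-class].
#' @param path output file path.
#' @param delimiter "," (default) or "" for whitespace.
#' @param header write the node labels as the first line?
#' @return the path, invisibly.
#' @export
saveTimeSeries <- function(ts, path, delimiter = ",", header = TRUE) {
  stopifnot(is(ts, "TimeSeriesMatrix"))
  sep <- if (identical(delimiter, "")) " " else delimiter
  v <- ts@values
  out <- matrix(sprintf("%.17g", v), nrow(v), ncol(v))  # lossless text
  colnames(out) <- colnames(v)
  write.table(out, path, sep = sep, row.names = FALSE,
              col.names = header, quote = FALSE)
  invisible(path)
}

#' @describeIn standardize center each node and scale all nodes by the
#'   single global factor mean(per-column SD).
#' @export
setMethod("standardize", "TimeSeriesMatrix", function(x) {
  if (x@standardized)
    stop("time series are already standardized")
  v <- x@values
  s <- apply(v, 2L, popSD)
  zero <- which(s <= 0)
  if (length(zero))
    stop("node(s) with zero variance cannot be standardized: ",
         paste(x@nodeLabels[zero], collapse = ", "))
  v <- sweep(v, 2L, colMeans(v), "-")
  v <- v / mean(apply(v, 2L, popSD))
  new("TimeSeriesMatrix", values = v, nodeLabels = x@nodeLabels,
      standardized = TRUE)
})

#' Read a binary adjacency matrix from CSV
#'
#' Entry \[i, j\] = 1 encodes the edge i -> j (row = parent, column =
#' child).
#'
#' @param path CSV file, optionally with a header of node labels.
#' @return n x n binary matrix.
#' @export
readAdjacency <- function(path) {
  m <- as.matrix(loadTimeSeries(path)@values)
  if (nrow(m) != ncol(m)) stop("adjacency matrix must be square")
  if (!all(m %in% c(0, 1))) stop("adjacency matrix must be binary")
  rownames(m) <- colnames(m)
  m
}

#' Write a directed network (or adjacency matrix) to CSV
#'
#' @param net a [DirectedNetwork-class] or binary matrix.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeAdjacency <- function(net, path) {
  A <- if (is(net, "DirectedNetwork")) adjacency(net) else net
  write.table(A, path, sep = ",", row.names = FALSE, col.names = TRUE,
              quote = FALSE)
  invisible(path)
}

#' Write a directed network as an edge list
#'
#' One line per edge in the form `i -> j` (parent -> child), using node
#' labels when available.
#'
#' @param net a [DirectedNetwork-class].
#' @param path output text file.
#' @return the path, invisibly.
#' @export
writeEdgeList <- function(net, path) {
  stopifnot(is(net, "DirectedNetwork"))
  A <- adjacency(net)
  lab <- nodeLabels(net)
  idx <- which(A == 1, arr.ind = TRUE)
  lines <- sprintf("%s -> %s", lab[idx[, 1L]], lab[idx[, 2L]])
  writeLines(lines, path)
  invisible(path)
}

#' Write time-varying coefficient paths of a fitted node model
#'
#' One CSV per child: T rows by |Pa| + 1 columns, the first column being
#' the intercept path, the remaining columns the coefficient paths of
#' the parents in order.
#'
#' @param fit a [DLMFit-class].
#' @param path output CSV path.
#' @param labels optional node labels used to name the parent columns.
#' @return the path, invisibly.
#' @export
writeCoefficientPaths <- function(fit, path, labels = NULL) {
  stopifnot(is(fit, "DLMFit"))
  m <- fit@mPath
  pa <- fit@parents
  nm <- if (is.null(labels)) as.character(pa) else labels[pa]
  colnames(m) <- c("intercept", nm)
  write.table(m, path, sep = ",", row.names = FALSE, col.names = TRUE,
              quote = FALSE)
  invisible(path)
}
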