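#' Read an observation matrix from delimited text or Matrix Market
#'
#' CSV/TSV files are read with rows as observations (an optional header row
#' is detected automatically for \code{format = "auto"} via
#' non-numeric first-line fields). Matrix Market (.mtx) input is read with
#' \code{Matrix::readMM}; set \code{transpose = TRUE} for the genes-x-cells
#' convention where observations are columns.
#'
#' @param path Input file path.
#' @param format \code{"auto"} (by extension), \code{"csv"}, \code{"tsv"}
#'   or \code{"mtx"}.
#' @param transpose Transpose after reading (MTX convention flag).
#' @param header Logical or \code{NA} (auto-detect) for delimited input.
#' @return A dense numeric matrix.
#' @export
read_observations <- function(path, format = c("auto", "csv", "tsv", "mtx"),
                              transpose = FALSE, header = NA) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_observations(): no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mtx = "mtx", tsv = "tsv", txt = "tsv", "csv")
  }
  if (format == "mtx") {
    X <- as.matrix(Matrix::readMM(path))
  } else {
    sep <- if (format == "tsv") "\t" else ","
    if (is.na(header)) {
      first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
      header <- anyNA(suppressWarnings(as.numeric(first)))
    }
    X <- as.matrix(utils::read.table(path, sep = sep, header = header))
  }
  if (transpose) X <- t(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("read_observations(): non-finite entries in ", path)
  X
}

#' Write an embedding to CSV
#'
#' One row per observation; columns \code{dim1..dimM} plus an optional
#' \code{label} column.
#'
#' @param Y Embedding matrix.
#' @param path Output path.
#' @param labels Optional label vector.
#' @export
write_embedding <- function(Y, path, labels = NULL) {
  df <- as.data.frame(Y)
  names(df) <- paste0("dim", seq_len(ncol(Y)))
  if (!is.null(labels)) df$label <- labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a per-iteration loss trace to CSV
#'
#' Two columns: \code{iteration} (0 = before the first step) and
#' \code{loss}.
#'
#' @param trace Numeric loss trace.
#' @param path Output path.
#' @export
write_loss_trace <- function(trace, path) {
  utils::write.csv(
    data.frame(iteration = seq_along(trace) - 1L, loss = trace),
    path, row.names = FALSE
  )
  invisible(path)
}
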