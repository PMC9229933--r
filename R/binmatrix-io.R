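#' Write a BinMatrix as CSV
#'
#' One row per sample; first column \code{sample_id}, remaining column
#' headers are the bin labels. Values are written with 15 significant
#' digits so the round trip through \code{\link{readBinMatrix}} is lossless
#' at stored precision.
#'
#' @param m a \linkS4class{BinMatrix}.
#' @param path output CSV path.
#' @return Invisibly, \code{path}.
#' @export
writeBinMatrix <- function(m, path) {
  stopifnot(is(m, "BinMatrix"))
  v <- binValues(m)                      # samples x bins
  df <- data.frame(sample_id = rownames(v), check.names = FALSE,
                   stringsAsFactors = FALSE)
  body <- format(v, digits = 15, trim = TRUE, scientific = FALSE)
  df <- cbind(df, as.data.frame(body, check.names = FALSE,
                                stringsAsFactors = FALSE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a BinMatrix from CSV
#'
#' Inverse of \code{\link{writeBinMatrix}}: expects one row per sample,
#' first column \code{sample_id}, remaining headers bin labels.
#'
#' @param path CSV path.
#' @param stage cascade stage tag to attach (default "raw").
#' @return A \linkS4class{BinMatrix}.
#' @export
readBinMatrix <- function(path, stage = c("raw", "excluded", "thresholded")) {
  stage <- match.arg(stage)
  if (!file.exists(path)) stop("bin-matrix file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (length(header) < 2L)
    stop("bin-matrix CSV needs a sample_id column plus at least one bin")
  labels <- header[-1]
  dup <- labels[duplicated(labels)]
  if (length(dup))
    stop("duplicated bin column(s) in '", path, "': ",
         paste(unique(dup), collapse = ", "))
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 colClasses = c("character", rep("numeric",
                                                 length(labels))))
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  BinMatrix(v, labels, df[[1]], stage = stage)
}

#' Subset a BinMatrix to a set of bin labels
#'
#' @param m a \linkS4class{BinMatrix}.
#' @param labels bin labels to keep, in matrix order.
#' @param stage stage tag for the result.
#' @return A \linkS4class{BinMatrix} with only those bins.
#' @keywords internal
.subsetBins <- function(m, labels, stage) {
  keep <- binLabels(m) %in% labels
  BinMatrix(binValues(m)[, keep, drop = FALSE], binLabels(m)[keep],
            sampleIds(m), stage = stage)
}
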