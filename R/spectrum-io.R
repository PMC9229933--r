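#' Read a spectrum from two-column delimited text
#'
#' Parses a (ppm, intensity) file — comma- or tab-delimited, autodetected,
#' optional header line — into an \linkS4class{NMRSpectrum}. A descending
#' ppm axis (common in instrument exports) is normalized to ascending.
#' Malformed rows raise an error naming the offending line number.
#'
#' @param path path to the spectrum file.
#' @param sampleId sample identifier to attach; defaults to the file name
#'   without extension.
#' @return An \linkS4class{NMRSpectrum}.
#' @seealso \code{\link{writeSpectrum}}
#' @export
readSpectrum <- function(path, sampleId = NULL) {
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  if (is.null(sampleId))
    sampleId <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lineno <- seq_along(lines)[keep]
  lines <- lines[keep]
  if (!length(lines)) stop("spectrum file is empty: ", path)

  delim <- if (grepl("\t", lines[[1]])) "\t" else ","
  fields <- strsplit(lines, delim, fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 2L)
  if (length(bad))
    stop(sprintf("line %d of '%s': expected 2 %s-separated fields, got %d",
                 lineno[bad[1]], path,
                 if (delim == ",") "comma" else "tab", nf[bad[1]]))

  first <- suppressWarnings(as.numeric(trimws(fields[[1]])))
  hasHeader <- anyNA(first)
  if (hasHeader) {
    fields <- fields[-1]
    lineno <- lineno[-1]
  }
  if (length(fields) < 2L)
    stop("spectrum file must contain at least 2 data points: ", path)

  x <- suppressWarnings(as.numeric(trimws(vapply(fields, `[`, "", 1L))))
  y <- suppressWarnings(as.numeric(trimws(vapply(fields, `[`, "", 2L))))
  bad <- which(is.na(x) | is.na(y))
  if (length(bad))
    stop(sprintf("line %d of '%s': non-numeric field in row '%s'",
                 lineno[bad[1]], path,
                 paste(fields[[bad[1]]], collapse = delim)))

  d <- diff(x)
  if (any(d == 0) || (!all(d > 0) && !all(d < 0)))
    stop("ppm axis in '", path, "' is not strictly monotone")
  NMRSpectrum(sampleId, x, y)
}

#' Write a spectrum as two-column CSV
#'
#' @param s an \linkS4class{NMRSpectrum}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeSpectrum <- function(s, path) {
  stopifnot(is(s, "NMRSpectrum"))
  df <- data.frame(ppm = s@ppm, intensity = s@intensity)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
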