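#' Default interference-bin list (suppressed water region)
#'
#' The 20 bins of \code{[4.70, 4.90)} ppm — the residual-water resonance in
#' aqueous-extract 1H NMR, the canonical region excluded before statistics.
#' Editable copies ship in \code{inst/extdata/excluded_bins_water.txt}.
#'
#' @param lo,hi region bounds in ppm (must span 20 bins of 0.01).
#' @return Character vector of 20 bin labels.
#' @examples
#' defaultExcludedBins()
#' @export
defaultExcludedBins <- function(lo = 4.70, hi = 4.90) {
  n <- round((hi - lo) / 0.01)
  sprintf("%.2f", lo + 0.01 * (seq_len(n) - 1))
}

#' Exclude interference bins
#'
#' First stage of the filter cascade: drop the listed bins (e.g. the water
#' region) from the matrix. In strict mode (default) every listed label
#' must exist; in lenient mode unknown labels are warned about and skipped.
#' Retained values are never modified.
#'
#' @param m a \linkS4class{BinMatrix}.
#' @param excluded character vector of bin labels to drop.
#' @param strict error (TRUE, default) or warn-and-skip (FALSE) on labels
#'   absent from \code{m}.
#' @return list with \code{matrix} (stage "excluded") and \code{trace}
#'   (\linkS4class{FilterTrace}).
#' @export
excludeBins <- function(m, excluded = defaultExcludedBins(), strict = TRUE) {
  stopifnot(is(m, "BinMatrix"))
  excluded <- as.character(excluded)
  unknown <- setdiff(excluded, binLabels(m))
  if (length(unknown)) {
    if (strict)
      stop("exclusion list contains unknown bin label(s): ",
           paste(unknown, collapse = ", "))
    warning("skipping unknown bin label(s): ",
            paste(unknown, collapse = ", "))
    excluded <- setdiff(excluded, unknown)
  }
  keep <- setdiff(binLabels(m), excluded)
  out <- .subsetBins(m, keep, stage = "excluded")
  trace <- new("FilterTrace", nInitial = nrow(m),
               excludedLabels = intersect(binLabels(m), excluded),
               nAfterExclusion = nrow(out))
  list(matrix = out, trace = trace)
}

#' Intensity-threshold filter
#'
#' Second stage of the cascade: a bin is retained iff its column statistic
#' across samples (default: the maximum) is at least \code{threshold}
#' (inclusive). The maximum is the most permissive reading — a bin present
#' in only one sample or condition survives.
#'
#' @param m a \linkS4class{BinMatrix}, normally at stage "excluded" (a raw
#'   matrix is accepted with a warning).
#' @param threshold non-negative intensity threshold (default 100000).
#' @param statistic "max" (default), "mean" or "median" across samples.
#' @param trace optional \linkS4class{FilterTrace} from
#'   \code{\link{excludeBins}} to complete; if NULL a fresh trace with no
#'   exclusions is created.
#' @return list with \code{matrix} (stage "thresholded") and \code{trace}.
#' @export
thresholdFilter <- function(m, threshold = 1e5,
                            statistic = c("max", "mean", "median"),
                            trace = NULL) {
  stopifnot(is(m, "BinMatrix"))
  statistic <- match.arg(statistic)
  if (threshold < 0) stop("threshold must be non-negative")
  if (identical(stageTag(m), "raw"))
    warning("threshold filter applied to a raw matrix; ",
            "interference bins have not been excluded")
  statFun <- switch(statistic, max = max, mean = mean,
                    median = stats::median)
  colStat <- apply(binValues(m), 2L, statFun)
  keep <- binLabels(m)[colStat >= threshold]
  out <- .subsetBins(m, keep, stage = "thresholded")
  if (is.null(trace))
    trace <- new("FilterTrace", nInitial = nrow(m),
                 excludedLabels = character(), nAfterExclusion = nrow(m))
  trace@threshold <- threshold
  trace@statistic <- statistic
  trace@nAfterThreshold <- nrow(out)
  validObject(trace)
  list(matrix = out, trace = trace)
}

#' Serialize a FilterTrace to a plain list
#' @param x a \linkS4class{FilterTrace}.
#' @return list suitable for JSON serialization.
#' @export
filterTraceAsList <- function(x) {
  stopifnot(is(x, "FilterTrace"))
  list(n_initial = x@nInitial,
       excluded_labels = x@excludedLabels,
       n_after_exclusion = x@nAfterExclusion,
       threshold = if (is.na(x@threshold)) NULL else x@threshold,
       statistic = if (is.na(x@statistic)) NULL else x@statistic,
       n_after_threshold = if (is.na(x@nAfterThreshold)) NULL else
         x@nAfterThreshold)
}
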