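#' Enumerate the bins of a binning specification
#'
#' Bins are contiguous half-open intervals \code{[lo, lo + width)} covering
#' the window; labels are the left edge formatted to exactly 2 decimals
#' (the convention used to name bins throughout).
#'
#' @param spec a \linkS4class{BinSpec}.
#' @return data.frame with columns \code{label}, \code{lo}, \code{hi}.
#' @examples
#' nrow(makeBins(binSpec()))   # 1000
#' @export
makeBins <- function(spec = binSpec()) {
  validObject(spec)
  n <- round((spec@windowHi - spec@windowLo) / spec@width)
  lo <- spec@windowLo + spec@width * (seq_len(n) - 1)
  data.frame(label = sprintf("%.2f", lo), lo = lo, hi = lo + spec@width,
             stringsAsFactors = FALSE)
}

#' Bin (bucket) one spectrum
#'
#' Assigns every in-window data point to its half-open bin
#' \code{[lo, lo + width)} — a point exactly on a left edge belongs to that
#' bin, a point at \code{windowHi} is excluded — and aggregates per bin.
#' With \code{aggregation = "sum"} the bin value is the plain sum of point
#' intensities, so total in-window signal is conserved exactly; with
#' \code{"trapezoid"} it is the trapezoidal integral over the in-bin points.
#' Points outside the window are dropped; empty bins get 0.
#'
#' @param s an \linkS4class{NMRSpectrum}.
#' @param spec a \linkS4class{BinSpec}.
#' @return Named numeric vector of bin values, in \code{\link{makeBins}}
#'   order.
#' @export
binSpectrum <- function(s, spec = binSpec()) {
  stopifnot(is(s, "NMRSpectrum"))
  validObject(s)
  bins <- makeBins(spec)
  n <- nrow(bins)
  inWin <- s@ppm >= spec@windowLo & s@ppm < spec@windowHi
  if (!any(inWin))
    stop("spectrum '", s@sampleId, "' does not intersect the window [",
         spec@windowLo, ", ", spec@windowHi, ")")
  breaks <- spec@windowLo + spec@width * (0:n)
  x <- s@ppm[inWin]
  y <- s@intensity[inWin]
  idx <- findInterval(x, breaks)     # left-closed, right-open by definition
  v <- numeric(n)
  if (spec@aggregation == "sum") {
    agg <- rowsum(y, idx)
    v[as.integer(rownames(agg))] <- agg[, 1L]
  } else {
    for (i in unique(idx)) {
      sel <- idx == i
      xi <- x[sel]; yi <- y[sel]
      if (length(xi) > 1L)
        v[i] <- sum(diff(xi) * (yi[-length(yi)] + yi[-1]) / 2)
    }
  }
  setNames(v, bins$label)
}

#' Bin a cohort of spectra into a BinMatrix
#'
#' @param spectra list of \linkS4class{NMRSpectrum} with unique sample ids.
#' @param spec a \linkS4class{BinSpec}.
#' @return A \linkS4class{BinMatrix} with \code{stage = "raw"}, rows in
#'   input order.
#' @export
binCohort <- function(spectra, spec = binSpec()) {
  if (!length(spectra)) stop("no spectra supplied")
  ids <- vapply(spectra, function(s) s@sampleId, "")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "))
  v <- t(vapply(spectra, binSpectrum, numeric(nrow(makeBins(spec))),
                spec = spec))
  BinMatrix(v, makeBins(spec)$label, ids, stage = "raw")
}
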