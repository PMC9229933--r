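#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importFrom S4Vectors metadata
#' @importFrom stats pt rnorm setNames
#' @importFrom utils read.csv write.csv packageVersion
NULL

#' One-dimensional 1H-NMR spectrum
#'
#' Holds a single sample's spectrum as paired chemical-shift (ppm) and
#' intensity vectors. The ppm axis is kept strictly ascending; constructors
#' and readers reorder descending input automatically.
#'
#' @slot sampleId single character identifier.
#' @slot ppm strictly ascending numeric chemical-shift axis (ppm).
#' @slot intensity numeric intensities (arbitrary instrument units), same
#'   length as \code{ppm}.
#'
#' @exportClass NMRSpectrum
setClass("NMRSpectrum",
  representation(sampleId = "character", ppm = "numeric",
                 intensity = "numeric"))

setValidity("NMRSpectrum", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L || is.na(object@sampleId) ||
      !nzchar(object@sampleId))
    msg <- c(msg, "sampleId must be a single non-empty string")
  if (length(object@ppm) != length(object@intensity))
    msg <- c(msg, "ppm and intensity must have equal length")
  if (length(object@ppm) < 2L)
    msg <- c(msg, "a spectrum needs at least 2 data points")
  if (anyNA(object@ppm) || anyNA(object@intensity))
    msg <- c(msg, "ppm and intensity must not contain NA")
  d <- diff(object@ppm)
  if (length(d) && any(d <= 0))
    msg <- c(msg, "ppm must be strictly ascending")
  if (length(msg)) msg else TRUE
})

#' Construct an NMRSpectrum
#'
#' Accepts the ppm axis in either direction and normalizes it to ascending
#' order, reordering intensities consistently.
#'
#' @param sampleId sample identifier.
#' @param ppm numeric chemical-shift axis, strictly monotone in either
#'   direction.
#' @param intensity numeric intensities aligned to \code{ppm}.
#' @return An \linkS4class{NMRSpectrum}.
#' @examples
#' s <- NMRSpectrum("a", ppm = c(2, 1, 0), intensity = c(3, 2, 1))
#' ppm(s)  # ascending
#' @export
NMRSpectrum <- function(sampleId, ppm, intensity) {
  ppm <- as.numeric(ppm)
  intensity <- as.numeric(intensity)
  if (length(ppm) >= 2L && !anyNA(ppm)) {
    d <- diff(ppm)
    if (all(d < 0)) {          # descending instrument export
      ppm <- rev(ppm)
      intensity <- rev(intensity)
    }
  }
  new("NMRSpectrum", sampleId = as.character(sampleId), ppm = ppm,
      intensity = intensity)
}

setMethod("show", "NMRSpectrum", function(object) {
  cat(sprintf("NMRSpectrum '%s': %d points, ppm [%.4g, %.4g]\n",
              object@sampleId, length(object@ppm), min(object@ppm),
              max(object@ppm)))
})

#' Binning specification
#'
#' Defines the chemical-shift window, bin width and aggregation rule used to
#' bucket a spectrum. Bins are contiguous half-open intervals
#' \code{[lo, lo + width)}; the default window \code{[0, 10)} ppm at width
#' 0.01 yields 1000 bins.
#'
#' @slot windowLo,windowHi window bounds in ppm.
#' @slot width bin width in ppm.
#' @slot aggregation "sum" (sum of in-bin point intensities, signal
#'   conserving) or "trapezoid" (trapezoidal integral over in-bin points).
#' @exportClass BinSpec
setClass("BinSpec",
  representation(windowLo = "numeric", windowHi = "numeric",
                 width = "numeric", aggregation = "character"),
  prototype(windowLo = 0, windowHi = 10, width = 0.01, aggregation = "sum"))

setValidity("BinSpec", function(object) {
  msg <- character()
  if (object@windowHi <= object@windowLo)
    msg <- c(msg, "windowHi must exceed windowLo")
  if (object@width <= 0)
    msg <- c(msg, "width must be positive")
  nb <- (object@windowHi - object@windowLo) / object@width
  if (abs(nb - round(nb)) > 1e-8)
    msg <- c(msg, sprintf(
      "window span %g is not an integer multiple of width %g",
      object@windowHi - object@windowLo, object@width))
  if (!object@aggregation %in% c("sum", "trapezoid"))
    msg <- c(msg, "aggregation must be 'sum' or 'trapezoid'")
  if (length(msg)) msg else TRUE
})

#' @param windowLo,windowHi window bounds in ppm (default 0 and 10).
#' @param width bin width in ppm (default 0.01).
#' @param aggregation "sum" (default) or "trapezoid".
#' @return A \linkS4class{BinSpec}.
#' @rdname BinSpec-class
#' @examples
#' binSpec()                 # 1000 bins of 0.01 ppm
#' binSpec(0, 0.03, 0.01)    # 3 bins
#' @export
binSpec <- function(windowLo = 0, windowHi = 10, width = 0.01,
                    aggregation = c("sum", "trapezoid")) {
  aggregation <- match.arg(aggregation)
  new("BinSpec", windowLo = windowLo, windowHi = windowHi, width = width,
      aggregation = aggregation)
}

setMethod("show", "BinSpec", function(object) {
  cat(sprintf("BinSpec: [%g, %g) ppm, width %g (%d bins), aggregation=%s\n",
              object@windowLo, object@windowHi, object@width,
              round((object@windowHi - object@windowLo) / object@width),
              object@aggregation))
})

#' Samples-by-bins intensity matrix
#'
#' A \linkS4class{SummarizedExperiment} holding one assay \code{"intensity"}
#' with bins as rows (rownames are 2-decimal left-edge ppm labels) and
#' samples as columns. A \code{stage} tag in \code{metadata()} records where
#' the matrix sits in the filter cascade: \code{"raw"} (fresh from binning),
#' \code{"excluded"} (interference bins dropped) or \code{"thresholded"}
#' (intensity filter applied). The on-disk CSV interchange format is the
#' transpose: one row per sample, first column \code{sample_id}.
#'
#' @exportClass BinMatrix
setClass("BinMatrix", contains = "SummarizedExperiment")

setValidity("BinMatrix", function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "BinMatrix needs an 'intensity' assay")
  st <- S4Vectors::metadata(object)$stage
  if (is.null(st) || !st %in% c("raw", "excluded", "thresholded"))
    msg <- c(msg, "metadata()$stage must be raw, excluded or thresholded")
  rn <- rownames(object)
  if (nrow(object) > 0L) {
    if (is.null(rn) || anyDuplicated(rn))
      msg <- c(msg, "bin labels (rownames) must be present and unique")
    else if (is.unsorted(suppressWarnings(as.numeric(rn))))
      msg <- c(msg, "bin labels must be sorted by ppm")
  }
  cn <- colnames(object)
  if (is.null(cn) || anyDuplicated(cn))
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  a <- SummarizedExperiment::assay(object, "intensity")
  if (length(a) && !all(is.finite(a)))
    msg <- c(msg, "all intensities must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a BinMatrix
#'
#' @param values numeric matrix, samples x bins (the CSV orientation); it is
#'   stored internally bins x samples.
#' @param binLabels character bin labels (2-decimal ppm left edges), one per
#'   column of \code{values}.
#' @param sampleIds character sample identifiers, one per row of
#'   \code{values}.
#' @param stage cascade stage tag: "raw", "excluded" or "thresholded".
#' @return A \linkS4class{BinMatrix}.
#' @examples
#' m <- BinMatrix(matrix(1:6, 2, 3), c("0.00", "0.01", "0.02"),
#'                c("s1", "s2"))
#' binLabels(m)
#' @export
BinMatrix <- function(values, binLabels, sampleIds,
                      stage = c("raw", "excluded", "thresholded")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  if (ncol(values) != length(binLabels))
    stop("ncol(values) must equal length(binLabels)")
  if (nrow(values) != length(sampleIds))
    stop("nrow(values) must equal length(sampleIds)")
  a <- t(values)
  dimnames(a) <- list(as.character(binLabels), as.character(sampleIds))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = a),
    metadata = list(stage = stage))
  new("BinMatrix", se)
}

setMethod("show", "BinMatrix", function(object) {
  cat(sprintf("BinMatrix [stage=%s]: %d samples x %d bins\n",
              stageTag(object), ncol(object), nrow(object)))
  if (nrow(object))
    cat("  bins:", paste(utils::head(rownames(object), 3), collapse = ", "),
        if (nrow(object) > 3) sprintf("... %s", rownames(object)[nrow(object)])
        else "", "\n")
})

#' Filter-cascade bookkeeping
#'
#' Records the bin counts before and after each stage of the two-stage
#' filter cascade (interference exclusion, then intensity thresholding),
#' so the trajectory (e.g. 1000 -> 980 -> retained) is auditable.
#'
#' @slot nInitial bins before any filtering.
#' @slot excludedLabels labels dropped by the exclusion stage.
#' @slot nAfterExclusion bins after exclusion.
#' @slot threshold intensity threshold (NA until the threshold stage ran).
#' @slot statistic column statistic the threshold applies to.
#' @slot nAfterThreshold bins after thresholding (NA until it ran).
#' @exportClass FilterTrace
setClass("FilterTrace",
  representation(nInitial = "integer", excludedLabels = "character",
                 nAfterExclusion = "integer", threshold = "numeric",
                 statistic = "character", nAfterThreshold = "integer"),
  prototype(threshold = NA_real_, statistic = NA_character_,
            nAfterThreshold = NA_integer_))

setValidity("FilterTrace", function(object) {
  msg <- character()
  if (object@nAfterExclusion != object@nInitial - length(object@excludedLabels))
    msg <- c(msg, "nAfterExclusion must equal nInitial - length(excludedLabels)")
  if (object@nInitial < object@nAfterExclusion)
    msg <- c(msg, "cascade must be monotone: nInitial >= nAfterExclusion")
  if (!is.na(object@nAfterThreshold) &&
      (object@nAfterThreshold > object@nAfterExclusion ||
       object@nAfterThreshold < 0L))
    msg <- c(msg, "cascade must be monotone: nAfterExclusion >= nAfterThreshold >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FilterTrace", function(object) {
  cat(sprintf("FilterTrace: %d -> %d (excluded %d)",
              object@nInitial, object@nAfterExclusion,
              length(object@excludedLabels)))
  if (!is.na(object@nAfterThreshold))
    cat(sprintf(" -> %d (threshold %g on %s)",
                object@nAfterThreshold, object@threshold, object@statistic))
  cat("\n")
})

#' Metabolite spectral signature
#'
#' A named set of Lorentzian peaks (center, relative area, linewidth) that
#' together make up one metabolite's contribution to a 1H spectrum.
#' Relative areas sum to 1 over the metabolite's peaks.
#'
#' @slot name metabolite name.
#' @slot peaks data.frame with columns \code{center_ppm},
#'   \code{relative_area}, \code{linewidth_ppm} (FWHM).
#' @slot origin expected biological origin: "diet", "microbiome" or
#'   "endogenous".
#' @exportClass MetaboliteSignature
setClass("MetaboliteSignature",
  representation(name = "character", peaks = "data.frame",
                 origin = "character"))

setValidity("MetaboliteSignature", function(object) {
  msg <- character()
  pk <- object@peaks
  need <- c("center_ppm", "relative_area", "linewidth_ppm")
  if (!all(need %in% names(pk)))
    msg <- c(msg, "peaks needs columns center_ppm, relative_area, linewidth_ppm")
  else {
    if (nrow(pk) < 1L) msg <- c(msg, "at least one peak required")
    if (any(pk$relative_area <= 0) || any(pk$linewidth_ppm <= 0))
      msg <- c(msg, "relative areas and linewidths must be positive")
    if (nrow(pk) && abs(sum(pk$relative_area) - 1) > 1e-8)
      msg <- c(msg, "relative areas must sum to 1")
  }
  if (!object@origin %in% c("diet", "microbiome", "endogenous"))
    msg <- c(msg, "origin must be diet, microbiome or endogenous")
  if (length(msg)) msg else TRUE
})

#' @param name metabolite name.
#' @param centers peak centers (ppm).
#' @param origin "diet", "microbiome" or "endogenous".
#' @param relativeAreas relative peak areas; normalized to sum to 1
#'   (default: equal areas).
#' @param linewidth peak full width at half maximum in ppm (recycled).
#' @rdname MetaboliteSignature-class
#' @return A \linkS4class{MetaboliteSignature}.
#' @export
metaboliteSignature <- function(name, centers, origin,
                                relativeAreas = NULL, linewidth = 0.005) {
  if (is.null(relativeAreas))
    relativeAreas <- rep(1, length(centers))
  relativeAreas <- relativeAreas / sum(relativeAreas)
  pk <- data.frame(center_ppm = as.numeric(centers),
                   relative_area = relativeAreas,
                   linewidth_ppm = rep_len(linewidth, length(centers)))
  new("MetaboliteSignature", name = name, peaks = pk, origin = origin)
}

setMethod("show", "MetaboliteSignature", function(object) {
  cat(sprintf("MetaboliteSignature '%s' (%s): %d peak(s) at %s ppm\n",
              object@name, object@origin, nrow(object@peaks),
              paste(format(object@peaks$center_ppm), collapse = ", ")))
})

#' Synthetic cohort design
#'
#' Parameters of the synthetic 2 (condition: HSC vs LSC) x 2 (age: week 14
#' vs 22) cohort generator: cell size, planted HSC/LSC ratios per metabolite
#' and week, abundance scale, animal-level biological variability, point
#' noise, baseline, the interference (water) region and the master seed.
#' See \code{\link{cohortDesign}} for defaults and units.
#'
#' @exportClass CohortDesign
setClass("CohortDesign",
  representation(nPerCell = "integer", plantedRatio = "data.frame",
                 baseAbundance = "numeric", animalCv = "numeric",
                 noiseSd = "numeric", baselineAmplitude = "numeric",
                 interferenceLo = "numeric", interferenceHi = "numeric",
                 interferenceBase = "numeric", interferencePeak = "numeric",
                 windowLo = "numeric", windowHi = "numeric",
                 pointsPerBin = "integer", seed = "integer"))

setValidity("CohortDesign", function(object) {
  msg <- character()
  if (object@nPerCell < 2L)
    msg <- c(msg, "nPerCell must be >= 2 (the per-bin model needs >= 2 per cell)")
  pr <- object@plantedRatio
  if (nrow(pr)) {
    if (!all(c("metabolite", "week", "ratio") %in% names(pr)))
      msg <- c(msg, "plantedRatio needs columns metabolite, week, ratio")
    else {
      if (any(pr$ratio <= 0)) msg <- c(msg, "planted ratios must be positive")
      if (!all(pr$week %in% c(14, 22)))
        msg <- c(msg, "plantedRatio week must be 14 or 22")
      if (anyDuplicated(pr[c("metabolite", "week")]))
        msg <- c(msg, "one planted ratio per (metabolite, week)")
    }
  }
  nb <- (object@interferenceHi - object@interferenceLo) / 0.01
  if (abs(nb - 20) > 1e-8)
    msg <- c(msg, "interference region must span exactly 20 bins of 0.01 ppm")
  if (object@interferenceLo < object@windowLo ||
      object@interferenceHi > object@windowHi)
    msg <- c(msg, "interference region must lie inside the spectral window")
  if (any(object@baseAbundance <= 0))
    msg <- c(msg, "base abundances must be positive")
  if (object@animalCv < 0 || object@noiseSd < 0)
    msg <- c(msg, "animalCv and noiseSd must be non-negative")
  if (object@windowHi <= object@windowLo)
    msg <- c(msg, "windowHi must exceed windowLo")
  if (object@pointsPerBin < 2L)
    msg <- c(msg, "pointsPerBin must be >= 2")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CohortDesign", function(object) {
  cat(sprintf(paste0(
    "CohortDesign: 2x2 cells of n=%d (%d samples), window [%g, %g) ppm,\n",
    "  animalCv=%g, noiseSd=%g, interference [%g, %g), seed=%d\n"),
    object@nPerCell, 4L * object@nPerCell, object@windowLo, object@windowHi,
    object@animalCv, object@noiseSd, object@interferenceLo,
    object@interferenceHi, object@seed))
  if (nrow(object@plantedRatio))
    cat(sprintf("  planted ratios for %d (metabolite, week) pairs\n",
                nrow(object@plantedRatio)))
})
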