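#' @name binNMR-accessors
#' @title Accessors for binNMR classes
#' @description Small accessor generics: \code{ppm()} / \code{intensity()}
#'   for spectra, \code{binLabels()} / \code{sampleIds()} /
#'   \code{stageTag()} / \code{binValues()} for bin matrices, and
#'   \code{filterCounts()} for filter traces.
#' @param x an object of the documented class.
#' @return The corresponding slot or derived value.
NULL

#' @rdname binNMR-accessors
#' @export
setGeneric("ppm", function(x) standardGeneric("ppm"))

#' @rdname binNMR-accessors
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))

#' @rdname binNMR-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname binNMR-accessors
#' @export
setGeneric("binLabels", function(x) standardGeneric("binLabels"))

#' @rdname binNMR-accessors
#' @export
setGeneric("stageTag", function(x) standardGeneric("stageTag"))

#' @rdname binNMR-accessors
#' @export
setGeneric("binValues", function(x) standardGeneric("binValues"))

#' @rdname binNMR-accessors
#' @export
setGeneric("filterCounts", function(x) standardGeneric("filterCounts"))

#' @rdname binNMR-accessors
setMethod("ppm", "NMRSpectrum", function(x) x@ppm)

#' @rdname binNMR-accessors
setMethod("intensity", "NMRSpectrum", function(x) x@intensity)

#' @rdname binNMR-accessors
setMethod("sampleIds", "NMRSpectrum", function(x) x@sampleId)

#' @rdname binNMR-accessors
setMethod("sampleIds", "BinMatrix", function(x) colnames(x))

#' @rdname binNMR-accessors
setMethod("binLabels", "BinMatrix", function(x) rownames(x))

#' @rdname binNMR-accessors
setMethod("stageTag", "BinMatrix",
          function(x) S4Vectors::metadata(x)$stage)

#' @rdname binNMR-accessors
#' @aliases binValues
setMethod("binValues", "BinMatrix",
          function(x) t(SummarizedExperiment::assay(x, "intensity")))

#' @rdname binNMR-accessors
setMethod("filterCounts", "FilterTrace", function(x) {
  c(n_initial = x@nInitial, n_after_exclusion = x@nAfterExclusion,
    n_after_threshold = x@nAfterThreshold)
})
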