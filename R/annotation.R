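#' Load and validate a bin-to-metabolite annotation table
#'
#' CSV with columns \code{bin_label}, \code{metabolite}, \code{origin}
#' (diet / microbiome / endogenous) and optional logical columns
#' \code{tentative} (closest-plausible annotation without confirmatory
#' evidence) and \code{shared} (a bin carrying overlapping resonances of
#' two metabolites, e.g. the 2.18 ppm bin shared by butyrate and
#' propionate). A bin may map to more than one metabolite only when all of
#' its rows are flagged shared.
#'
#' @param path CSV path; defaults to the packaged map of the pig fecal
#'   study (see \code{\link{defaultAnnotation}}).
#' @return Validated data.frame.
#' @export
loadAnnotation <- function(path = system.file("extdata",
                                              "table1_annotation.csv",
                                              package = "binNMR")) {
  if (!nzchar(path) || !file.exists(path))
    stop("annotation file not found: ", path)
  ann <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("bin_label", "metabolite", "origin")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation is missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(ann$tentative)) ann$tentative <- FALSE
  if (is.null(ann$shared)) ann$shared <- FALSE
  ann$tentative <- as.logical(ann$tentative)
  ann$shared <- as.logical(ann$shared)
  bad <- which(!ann$origin %in% c("diet", "microbiome", "endogenous"))
  if (length(bad))
    stop(sprintf("invalid origin '%s' in annotation row(s) %s",
                 paste(unique(ann$origin[bad]), collapse = "', '"),
                 paste(bad, collapse = ", ")))
  ann$bin_label <- as.character(ann$bin_label)
  if (anyDuplicated(ann[c("bin_label", "metabolite")]))
    stop("duplicate (bin_label, metabolite) rows in annotation")
  multi <- names(which(table(ann$bin_label) > 1L))
  for (b in multi) {
    if (!all(ann$shared[ann$bin_label == b]))
      stop("bin ", b, " maps to multiple metabolites but is not flagged ",
           "shared in every row")
  }
  ann
}

#' The packaged bin-to-metabolite annotation
#'
#' The bin map of the pig fecal cohort: xanthine (7.93), butyrate (1.52,
#' 0.88, 2.18), propionate (1.06, 2.18 shared with butyrate), UDP-glucose
#' (5.62-5.64), valerate (0.84, tentative), uridine derivates (5.94,
#' 6.11-6.13, 7.86, 7.89), bile acids (0.73-0.77, tentative) and kynurenic
#' acid (6.65, 7.49, 7.68, 7.82).
#'
#' @return Validated annotation data.frame.
#' @export
defaultAnnotation <- function() loadAnnotation()

#' Aggregate per-bin results into per-metabolite summaries
#'
#' For each annotated metabolite and week: the summary ratio is the
#' unweighted arithmetic mean of its bins' HSC/LSC ratios and the summary
#' q-value is, by default, the unweighted mean of its bins' q-values
#' ("mean FDR over bins"); the significance tier is derived from that
#' summary q. Averaging q-values is statistically unconventional but is
#' the reporting convention this table style uses; \code{fdrAggregation =
#' "min"} substitutes the (anti-conservative) minimum-q alternative.
#' Single-bin metabolites pass their bin's values through unchanged.
#' Annotated bins absent from \code{results} are warned about and skipped;
#' metabolites with no surviving bin are excluded with a warning. All
#' arithmetic is at full precision — rounding happens only in
#' \code{\link{renderTable1}}.
#'
#' @param results data.frame from \code{\link{fitBinModel}} (per-week
#'   mode).
#' @param annot annotation data.frame from \code{\link{loadAnnotation}}.
#' @param fdrAggregation "mean" (default) or "min".
#' @param tiers tier thresholds, see \code{\link{assignTier}}.
#' @return data.frame with one row per metabolite: \code{metabolite},
#'   \code{origin}, \code{tentative}, \code{bins} (comma-joined labels),
#'   \code{n_bins}, and \code{week14_ratio}, \code{week14_q},
#'   \code{week14_tier}, \code{week22_ratio}, \code{week22_q},
#'   \code{week22_tier}.
#' @export
summarizeMetabolites <- function(results, annot = defaultAnnotation(),
                                 fdrAggregation = c("mean", "min"),
                                 tiers = c(0.05, 0.1)) {
  fdrAggregation <- match.arg(fdrAggregation)
  aggFun <- if (fdrAggregation == "mean") mean else min
  mets <- unique(annot$metabolite)
  missing <- setdiff(annot$bin_label, results$bin_label)
  if (length(missing))
    warning("annotated bin(s) absent from results (skipped): ",
            paste(sort(unique(missing)), collapse = ", "))
  rows <- lapply(mets, function(met) {
    bins <- annot$bin_label[annot$metabolite == met]
    bins <- bins[bins %in% results$bin_label]
    if (!length(bins)) {
      warning("metabolite '", met, "' has no bins in the results; excluded")
      return(NULL)
    }
    arow <- annot[annot$metabolite == met, ][1L, ]
    out <- data.frame(metabolite = met, origin = arow$origin,
                      tentative = arow$tentative,
                      bins = paste(bins, collapse = ","),
                      n_bins = length(bins), stringsAsFactors = FALSE)
    for (w in c("14", "22")) {
      sub <- results[results$week == w & results$bin_label %in% bins, ]
      r <- if (nrow(sub)) mean(sub$ratio_hsc_lsc) else NA_real_
      q <- if (nrow(sub) && !all(is.na(sub$q_fdr)))
        aggFun(sub$q_fdr, na.rm = TRUE) else NA_real_
      out[[paste0("week", w, "_ratio")]] <- r
      out[[paste0("week", w, "_q")]] <- q
      out[[paste0("week", w, "_tier")]] <- assignTier(q, tiers)
    }
    out
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(metabolite = character(), origin = character(),
                      tentative = logical(), bins = character(),
                      n_bins = integer(), week14_ratio = numeric(),
                      week14_q = numeric(), week14_tier = character(),
                      week22_ratio = numeric(), week22_q = numeric(),
                      week22_tier = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Render the metabolite ratio report table
#'
#' Lays out per-bin rows (for multi-bin metabolites) followed by a
#' "Mean <metabolite>" row, in origin order (diet, microbiome, endogenous),
#' with ratios rounded half-up to 2 decimals and FDR cells shown as
#' "<0.05", "<0.1" or "ns". A bin shared between two metabolites is printed
#' once, named "A and b". An empty summary gives a header-only (0-row)
#' table.
#'
#' @param summaries data.frame from \code{\link{summarizeMetabolites}}.
#' @param binResults data.frame from \code{\link{fitBinModel}}.
#' @param annot the annotation table the summaries were built from.
#' @return Character data.frame with columns \code{expected_origin},
#'   \code{bins}, \code{metabolite}, \code{week14_ratio},
#'   \code{week14_fdr}, \code{week22_ratio}, \code{week22_fdr}.
#' @export
renderTable1 <- function(summaries, binResults,
                         annot = defaultAnnotation()) {
  empty <- data.frame(expected_origin = character(), bins = character(),
                      metabolite = character(), week14_ratio = character(),
                      week14_fdr = character(), week22_ratio = character(),
                      week22_fdr = character(), stringsAsFactors = FALSE)
  if (is.null(summaries) || nrow(summaries) == 0L) return(empty)
  ord <- order(match(summaries$origin,
                     c("diet", "microbiome", "endogenous")),
               match(summaries$metabolite, unique(annot$metabolite)))
  summaries <- summaries[ord, , drop = FALSE]
  # lowercase a leading capital unless the name starts with an acronym
  lower1 <- function(s) ifelse(grepl("^[A-Z][a-z]", s),
                               paste0(tolower(substring(s, 1, 1)),
                                      substring(s, 2)), s)
  emittedShared <- character()
  rows <- list()
  for (i in seq_len(nrow(summaries))) {
    s <- summaries[i, ]
    bins <- strsplit(s$bins, ",", fixed = TRUE)[[1]]
    origin <- .originLabel[[s$origin]]
    if (length(bins) > 1L) {
      for (b in bins) {
        partners <- unique(annot$metabolite[annot$bin_label == b])
        if (length(partners) > 1L) {
          if (b %in% emittedShared) next
          emittedShared <- c(emittedShared, b)
          name <- paste0(partners[1],
                         paste0(" and ", lower1(partners[-1]),
                                collapse = ""))
        } else name <- s$metabolite
        br14 <- binResults[binResults$week == "14" &
                             binResults$bin_label == b, ]
        br22 <- binResults[binResults$week == "22" &
                             binResults$bin_label == b, ]
        rows[[length(rows) + 1L]] <- data.frame(
          expected_origin = origin, bins = b, metabolite = name,
          week14_ratio = .formatRatio(if (nrow(br14)) br14$ratio_hsc_lsc
                                      else NA),
          week14_fdr = .tierLabel(if (nrow(br14)) br14$tier else NA),
          week22_ratio = .formatRatio(if (nrow(br22)) br22$ratio_hsc_lsc
                                      else NA),
          week22_fdr = .tierLabel(if (nrow(br22)) br22$tier else NA),
          stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        expected_origin = origin, bins = "",
        metabolite = paste("Mean", lower1(s$metabolite)),
        week14_ratio = .formatRatio(s$week14_ratio),
        week14_fdr = .tierLabel(s$week14_tier),
        week22_ratio = .formatRatio(s$week22_ratio),
        week22_fdr = .tierLabel(s$week22_tier),
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        expected_origin = origin, bins = bins, metabolite = s$metabolite,
        week14_ratio = .formatRatio(s$week14_ratio),
        week14_fdr = .tierLabel(s$week14_tier),
        week22_ratio = .formatRatio(s$week22_ratio),
        week22_fdr = .tierLabel(s$week22_tier),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
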