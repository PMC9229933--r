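.TREATMENTS <- c("HSC", "LSC")
.WEEKS <- c(14L, 22L)

#' Validate a sample-metadata table
#'
#' Checks the 2x2 cohort metadata: required columns, unique sample ids, and
#' factor levels restricted to treatment HSC/LSC and week 14/22.
#'
#' @param meta data.frame with columns \code{sample_id}, \code{animal_id},
#'   \code{pen_id}, \code{treatment}, \code{week}.
#' @return The validated data.frame, with \code{treatment} as character and
#'   \code{week} as integer.
#' @export
validateSampleMetadata <- function(meta) {
  need <- c("sample_id", "animal_id", "pen_id", "treatment", "week")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  meta <- as.data.frame(meta)[need]
  if (nrow(meta) == 0L) {
    warning("metadata table is empty")
    meta$week <- integer(0)
    return(meta)
  }
  for (col in c("sample_id", "animal_id", "pen_id", "treatment"))
    meta[[col]] <- as.character(meta[[col]])
  dup <- meta$sample_id[duplicated(meta$sample_id)]
  if (length(dup))
    stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "))
  badT <- which(!meta$treatment %in% .TREATMENTS)
  if (length(badT))
    stop(sprintf("invalid treatment level(s) %s in row(s) %s (allowed: %s)",
                 paste(unique(meta$treatment[badT]), collapse = ", "),
                 paste(badT, collapse = ", "),
                 paste(.TREATMENTS, collapse = ", ")))
  wk <- suppressWarnings(as.integer(meta$week))
  badW <- which(is.na(wk) | !wk %in% .WEEKS)
  if (length(badW))
    stop(sprintf("invalid week value(s) %s in row(s) %s (allowed: 14, 22)",
                 paste(unique(meta$week[badW]), collapse = ", "),
                 paste(badW, collapse = ", ")))
  meta$week <- wk
  rownames(meta) <- NULL
  meta
}

#' Read and validate sample metadata
#'
#' @param path CSV file with columns \code{sample_id}, \code{animal_id},
#'   \code{pen_id}, \code{treatment} (HSC or LSC) and \code{week} (14 or
#'   22).
#' @return A validated data.frame (see \code{\link{validateSampleMetadata}}).
#' @export
readSampleMetadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  meta <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  validateSampleMetadata(meta)
}

#' Write sample metadata
#' @param meta a validated metadata data.frame.
#' @param path output CSV path.
#' @return Invisibly, \code{path}.
#' @export
writeSampleMetadata <- function(meta, path) {
  write.csv(meta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
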