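#' Signature library of the pig fecal cohort metabolites
#'
#' Lorentzian signatures for the eight annotated metabolites, one peak per
#' annotated bin, centered mid-bin: xanthine (7.93), butyrate (1.52, 0.88,
#' 2.18), propionate (1.06, 2.18), UDP-glucose (5.62-5.64), valerate
#' (0.84), uridine derivates (5.94, 6.11-6.13, 7.86, 7.89), bile acids
#' (0.73-0.77) and kynurenic acid (6.65, 7.49, 7.68, 7.82). Relative areas
#' are equal within a metabolite and sum to 1; default linewidth 0.005 ppm
#' (FWHM) keeps most of a peak inside its 0.01-ppm bin.
#'
#' @param linewidth peak FWHM in ppm (default 0.005).
#' @return Named list of \linkS4class{MetaboliteSignature}.
#' @export
defaultSignatureLibrary <- function(linewidth = 0.005) {
  mid <- function(labels) as.numeric(labels) + 0.005
  sigs <- list(
    metaboliteSignature("Xanthine", mid("7.93"), "diet",
                        linewidth = linewidth),
    metaboliteSignature("Butyrate", mid(c("1.52", "0.88", "2.18")),
                        "microbiome", linewidth = linewidth),
    metaboliteSignature("Propionate", mid(c("1.06", "2.18")),
                        "microbiome", linewidth = linewidth),
    metaboliteSignature("UDP-glucose", mid(c("5.62", "5.63", "5.64")),
                        "microbiome", linewidth = linewidth),
    metaboliteSignature("Valerate", mid("0.84"), "microbiome",
                        linewidth = linewidth),
    metaboliteSignature("Uridine derivates",
                        mid(c("5.94", "6.11", "6.12", "6.13", "7.86",
                              "7.89")), "microbiome",
                        linewidth = linewidth),
    metaboliteSignature("Bile acids",
                        mid(c("0.73", "0.74", "0.75", "0.76", "0.77")),
                        "endogenous", linewidth = linewidth),
    metaboliteSignature("Kynurenic acid",
                        mid(c("6.65", "7.49", "7.68", "7.82")),
                        "endogenous", linewidth = linewidth))
  names(sigs) <- vapply(sigs, function(s) s@name, "")
  sigs
}

# Table-1-style per-metabolite HSC/LSC planting targets
.defaultPlantedRatio <- function() {
  data.frame(
    metabolite = rep(c("Xanthine", "Butyrate", "Propionate", "UDP-glucose",
                       "Valerate", "Uridine derivates", "Bile acids",
                       "Kynurenic acid"), each = 2L),
    week = rep(c(14L, 22L), 8L),
    ratio = c(1.53, 1.41,   # xanthine
              0.74, 0.79,   # butyrate (per-metabolite mean)
              0.73, 0.73,   # propionate
              1.15, 4.76,   # UDP-glucose
              0.84, 1.37,   # valerate
              2.27, 1.36,   # uridine derivates
              0.64, 1.54,   # bile acids
              0.80, 0.62),  # kynurenic acid
    stringsAsFactors = FALSE)
}

#' Construct a synthetic cohort design
#'
#' Defaults emulate the study conditions the analysis assumes: 6 animals
#' per treatment per age (24 samples), a [0, 10) ppm window binning into
#' 1000 bins, planted per-metabolite HSC/LSC ratios taken from the
#' reported ratio table, a 20-bin water interference region at
#' [4.70, 4.90), multiplicative log-normal animal variability (CV 0.15)
#' and additive Gaussian point noise (sd 25 intensity units). Base
#' abundance 600 area-units per metabolite puts single-bin peaks roughly
#' 25x above the 100,000 intensity threshold and noise-only bins roughly
#' 25x below it.
#'
#' @param nPerCell animals per treatment-by-week cell (default 6, min 2).
#' @param plantedRatio data.frame (metabolite, week, ratio) of HSC/LSC
#'   planting targets; metabolites or weeks not listed get ratio 1.
#' @param baseAbundance named numeric of per-metabolite integrated areas;
#'   a single unnamed value is used for every metabolite (default 600).
#' @param animalCv coefficient of variation of the log-normal animal
#'   effect (default 0.15).
#' @param noiseSd additive Gaussian noise sd per data point (default 25).
#' @param baselineAmplitude smooth-baseline scale per point (default 50;
#'   0 disables the baseline).
#' @param interferenceLo,interferenceHi water-hump region, must span
#'   exactly 20 bins of 0.01 ppm (default [4.70, 4.90)).
#' @param interferenceBase,interferencePeak per-point plateau and crest
#'   heights of the interference hump (defaults 2e5 and 1e6, large enough
#'   that the 20 hump bins are always the most intense bins).
#' @param windowLo,windowHi spectral window in ppm (default [0, 10)).
#' @param pointsPerBin sampled data points per 0.01-ppm bin (default 64).
#' @param seed master seed; all randomness streams from it.
#' @return A \linkS4class{CohortDesign}.
#' @export
cohortDesign <- function(nPerCell = 6L,
                         plantedRatio = .defaultPlantedRatio(),
                         baseAbundance = 600, animalCv = 0.15,
                         noiseSd = 25, baselineAmplitude = 50,
                         interferenceLo = 4.70, interferenceHi = 4.90,
                         interferenceBase = 2e5, interferencePeak = 1e6,
                         windowLo = 0, windowHi = 10, pointsPerBin = 64L,
                         seed = 1L) {
  new("CohortDesign", nPerCell = as.integer(nPerCell),
      plantedRatio = plantedRatio,
      baseAbundance = baseAbundance, animalCv = animalCv,
      noiseSd = noiseSd, baselineAmplitude = baselineAmplitude,
      interferenceLo = interferenceLo, interferenceHi = interferenceHi,
      interferenceBase = interferenceBase,
      interferencePeak = interferencePeak,
      windowLo = windowLo, windowHi = windowHi,
      pointsPerBin = as.integer(pointsPerBin), seed = as.integer(seed))
}

# planted ratio lookup with default 1
.plantedRatioFor <- function(design, metabolite, week) {
  pr <- design@plantedRatio
  hit <- pr$metabolite == metabolite & pr$week == week
  if (any(hit)) pr$ratio[hit][1L] else 1
}

# per-metabolite base abundance, recycling an unnamed scalar
.baseAbundanceFor <- function(design, metabolites) {
  ba <- design@baseAbundance
  if (is.null(names(ba)) || !any(nzchar(names(ba))))
    return(setNames(rep_len(ba, length(metabolites)), metabolites))
  out <- ba[metabolites]
  if (anyNA(out))
    stop("baseAbundance missing metabolite(s): ",
         paste(metabolites[is.na(out)], collapse = ", "))
  out
}

# analytic fraction of a metabolite's total area falling in each 0.01 bin
.binFractions <- function(sig, windowLo, windowHi) {
  nb <- round((windowHi - windowLo) / 0.01)
  lo <- windowLo + 0.01 * (seq_len(nb) - 1)
  frac <- numeric(nb)
  for (k in seq_len(nrow(sig@peaks))) {
    c0 <- sig@peaks$center_ppm[k]
    g <- sig@peaks$linewidth_ppm[k] / 2
    frac <- frac + sig@peaks$relative_area[k] *
      (atan((lo + 0.01 - c0) / g) - atan((lo - c0) / g)) / pi
  }
  setNames(frac, sprintf("%.2f", lo))
}

#' Simulate a synthetic 2x2 NMR cohort
#'
#' Generates \code{2 x 2 x nPerCell} spectra. Each spectrum is the sum of
#' Lorentzian metabolite signatures scaled by per-sample abundances, a
#' smooth baseline, a large interference hump in the water region, and
#' i.i.d. Gaussian point noise. The abundance of metabolite m in a sample
#' is \code{base_m * animalEffect(animal, m) * ratio_m(week)} for HSC
#' samples and \code{base_m * animalEffect(animal, m)} for LSC, with
#' log-normal (mean 1) animal effects drawn once per animal and metabolite
#' — the same 12 animals are sampled at both weeks. A single master seed
#' streams per-sample sub-seeds, so identical designs reproduce identical
#' cohorts regardless of generation order.
#'
#' @param design a \linkS4class{CohortDesign}.
#' @param library list of \linkS4class{MetaboliteSignature}; every peak
#'   center must lie inside the design window.
#' @return list with \code{spectra} (list of \linkS4class{NMRSpectrum}),
#'   \code{metadata} (validated data.frame) and \code{truth} (data.frame
#'   metabolite / week / true_ratio / affected_bins, where affected bins
#'   hold at least 0.5\% of the metabolite's area).
#' @export
simulateCohort <- function(design = cohortDesign(),
                           library = defaultSignatureLibrary()) {
  validObject(design)
  for (sig in library) {
    validObject(sig)
    if (any(sig@peaks$center_ppm <= design@windowLo |
            sig@peaks$center_ppm >= design@windowHi))
      stop("peak center of '", sig@name, "' lies outside the window [",
           design@windowLo, ", ", design@windowHi, ")")
  }
  mets <- vapply(library, function(s) s@name, "")
  base <- .baseAbundanceFor(design, mets)

  nb <- round((design@windowHi - design@windowLo) / 0.01)
  delta <- 0.01 / design@pointsPerBin
  N <- nb * design@pointsPerBin
  x <- design@windowLo + (seq_len(N) - 0.5) * delta

  # per-metabolite unit-area signal profiles (Lorentzian mixtures)
  S <- vapply(library, function(sig) {
    v <- numeric(N)
    for (k in seq_len(nrow(sig@peaks))) {
      g <- sig@peaks$linewidth_ppm[k] / 2          # HWHM
      v <- v + sig@peaks$relative_area[k] * g /
        (pi * ((x - sig@peaks$center_ppm[k])^2 + g^2))
    }
    v
  }, numeric(N))

  baseline <- design@baselineAmplitude *
    (1 + 0.5 * sin(2 * pi * x / 3.7))
  hump <- numeric(N)
  inReg <- x >= design@interferenceLo & x < design@interferenceHi
  span <- design@interferenceHi - design@interferenceLo
  hump[inReg] <- design@interferenceBase +
    (design@interferencePeak - design@interferenceBase) *
    sin(pi * (x[inReg] - design@interferenceLo) / span)^2
  fixedPart <- baseline + hump

  n <- design@nPerCell
  treatments <- c("HSC", "LSC")
  nAnimals <- 2L * n
  nSamples <- 2L * nAnimals
  seeds <- .deriveSeeds(design@seed, nSamples + 1L)

  # persistent animal effects: one log-normal draw per animal x metabolite
  sdlog <- sqrt(log(1 + design@animalCv^2))
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed,
                                        envir = globalenv()))
  set.seed(seeds[1L])
  eff <- matrix(exp(rnorm(nAnimals * length(mets), -sdlog^2 / 2, sdlog)),
                nAnimals, length(mets),
                dimnames = list(NULL, mets))

  spectra <- vector("list", nSamples)
  meta <- vector("list", nSamples)
  idx <- 0L
  for (week in c(14L, 22L)) {
    for (ti in seq_along(treatments)) {
      tr <- treatments[ti]
      for (a in seq_len(n)) {
        idx <- idx + 1L
        animalRow <- (ti - 1L) * n + a
        ratios <- vapply(mets, function(met)
          if (tr == "HSC") .plantedRatioFor(design, met, week) else 1,
          0)
        abund <- base * eff[animalRow, ] * ratios
        set.seed(seeds[idx + 1L])
        inten <- as.numeric(S %*% abund) + fixedPart +
          rnorm(N, 0, design@noiseSd)
        sid <- sprintf("S_%s_w%d_%02d", tr, week, a)
        spectra[[idx]] <- NMRSpectrum(sid, x, inten)
        meta[[idx]] <- data.frame(
          sample_id = sid,
          animal_id = sprintf("A_%s_%02d", tr, a),
          pen_id = sprintf("P_%s_%02d", tr, a),
          treatment = tr, week = week, stringsAsFactors = FALSE)
      }
    }
  }
  metadata <- validateSampleMetadata(do.call(rbind, meta))

  truth <- do.call(rbind, lapply(mets, function(met) {
    frac <- .binFractions(library[[met]], design@windowLo, design@windowHi)
    aff <- names(frac)[frac >= 0.005]
    data.frame(metabolite = met, week = c(14L, 22L),
               true_ratio = c(.plantedRatioFor(design, met, 14L),
                              .plantedRatioFor(design, met, 22L)),
               affected_bins = paste(aff, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL
  list(spectra = spectra, metadata = metadata, truth = truth)
}

#' Simulate a null cohort (no planted effects)
#'
#' Identical to \code{\link{simulateCohort}} with every planted ratio
#' forced to 1, for type-I-error calibration; the truth table records
#' \code{true_ratio = 1} throughout.
#'
#' @inheritParams simulateCohort
#' @return As \code{\link{simulateCohort}}.
#' @export
nullCohort <- function(design = cohortDesign(),
                       library = defaultSignatureLibrary()) {
  pr <- design@plantedRatio
  if (nrow(pr)) pr$ratio <- 1
  design@plantedRatio <- pr
  simulateCohort(design, library)
}
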