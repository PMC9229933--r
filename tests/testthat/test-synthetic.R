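test_that("the signature library covers the annotated metabolites", {
  lib <- defaultSignatureLibrary()
  expect_named(lib)
  xan <- lib[["Xanthine"]]
  expect_equal(nrow(xan@peaks), 1L)
  expect_true(all(xan@peaks$center_ppm >= 7.93 &
                    xan@peaks$center_ppm < 7.94))
  kyn <- lib[["Kynurenic acid"]]
  expect_equal(nrow(kyn@peaks), 4L)
  expect_true(all((floor(kyn@peaks$center_ppm * 100) / 100) %in%
                    c(6.65, 7.49, 7.68, 7.82)))
  for (sig in lib) {
    expect_equal(sum(sig@peaks$relative_area), 1)
    expect_true(all(sig@peaks$linewidth_ppm > 0))
  }
  # every annotated bin has a matching peak in its signature
  ann <- defaultAnnotation()
  for (i in seq_len(nrow(ann))) {
    sig <- lib[[ann$metabolite[i]]]
    lo <- as.numeric(ann$bin_label[i])
    expect_true(any(sig@peaks$center_ppm >= lo &
                      sig@peaks$center_ppm < lo + 0.01),
                info = ann$bin_label[i])
  }
})

test_that("cohort generation honours the 2x2 design and the seed", {
  d <- smallDesign(seed = 41)
  co <- simulateCohort(d, smallLibrary())
  expect_length(co$spectra, 24L)
  expect_equal(nrow(co$metadata), 24L)
  expect_equal(unname(table(co$metadata$treatment, co$metadata$week)),
               matrix(6L, 2, 2))

  co2 <- simulateCohort(d, smallLibrary())
  expect_identical(lapply(co$spectra, intensity),
                   lapply(co2$spectra, intensity))

  d2 <- smallDesign(seed = 42)
  co3 <- simulateCohort(d2, smallLibrary())
  expect_false(identical(intensity(co$spectra[[1]]),
                         intensity(co3$spectra[[1]])))
})

test_that("zero-noise cohorts recover planted ratios at affected bins", {
  planted <- data.frame(metabolite = c("MetA", "MetE", "MetA", "MetE"),
                        week = c(14L, 14L, 22L, 22L),
                        ratio = c(0.5, 2.0, 0.8, 1.6))
  d <- smallDesign(seed = 1, plantedRatio = planted, animalCv = 0,
                   noiseSd = 0, baselineAmplitude = 0)
  d@nPerCell <- 2L
  co <- simulateCohort(d, smallLibrary())
  m <- binCohort(co$spectra, smallBinSpec())
  r14 <- groupRatio(m, co$metadata, 14)
  r22 <- groupRatio(m, co$metadata, 22)
  # planted bins (peaks sit mid-bin at 0.105 and 0.905)
  expect_equal(unname(r14[["0.10"]]), 0.5, tolerance = 5e-3)
  expect_equal(unname(r14[["0.90"]]), 2.0, tolerance = 5e-3)
  expect_equal(unname(r22[["0.10"]]), 0.8, tolerance = 5e-3)
  expect_equal(unname(r22[["0.90"]]), 1.6, tolerance = 5e-3)
  # unaffected single-metabolite bins stay at 1
  expect_equal(unname(r14[["0.20"]]), 1, tolerance = 5e-3)
  expect_equal(unname(r22[["0.40"]]), 1, tolerance = 5e-3)

  # truth table records the planting and the affected bins
  expect_equal(nrow(co$truth), 10L)   # 5 metabolites x 2 weeks
  t14 <- co$truth[co$truth$metabolite == "MetA" & co$truth$week == 14, ]
  expect_equal(t14$true_ratio, 0.5)
  expect_match(t14$affected_bins, "0.10")
})

test_that("the interference hump dominates exactly its 20 bins", {
  d <- cohortDesign(pointsPerBin = 8L, seed = 12)
  co <- simulateCohort(d)
  m <- binCohort(co$spectra)
  water <- defaultExcludedBins()
  for (i in c(1L, 13L)) {
    v <- binValues(m)[i, ]
    top20 <- names(sort(v, decreasing = TRUE))[1:20]
    expect_setequal(top20, water)
  }
})

test_that("interference region must span 20 bins inside the window", {
  expect_error(cohortDesign(interferenceLo = 4.7, interferenceHi = 4.85),
               "20 bins")
  expect_error(smallDesign(1, interferenceLo = 0.95,
                           interferenceHi = 1.15), "inside the spectral")
  expect_error(cohortDesign(nPerCell = 1L), "nPerCell")
  expect_error(cohortDesign(animalCv = -0.1), "non-negative")
})

test_that("null cohorts carry no effect and few false discoveries", {
  nSig <- integer(15)
  for (i in seq_len(15)) {
    co <- nullCohort(smallDesign(seed = 300 + i), smallLibrary())
    expect_true(all(co$truth$true_ratio == 1))
    m <- binCohort(co$spectra, smallBinSpec())
    ex <- excludeBins(m, sprintf("%.2f", seq(0.50, 0.69, by = 0.01)))
    th <- thresholdFilter(ex$matrix, trace = ex$trace)
    res <- fitBinModel(th$matrix, co$metadata)
    nSig[i] <- sum(res$q_fdr < 0.1, na.rm = TRUE)
  }
  expect_equal(median(nSig), 0)

  # zero-noise null: every retained bin ratio is 1
  d0 <- smallDesign(seed = 2, animalCv = 0, noiseSd = 0,
                    baselineAmplitude = 0)
  co0 <- nullCohort(d0, smallLibrary())
  m0 <- binCohort(co0$spectra, smallBinSpec())
  keep <- vapply(smallLibrary(), function(s)
    sprintf("%.2f", floor(s@peaks$center_ppm * 100) / 100), "")
  r <- groupRatio(m0, co0$metadata, 14)[keep]
  expect_equal(unname(r), rep(1, 5), tolerance = 5e-3)
})
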