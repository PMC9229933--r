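test_that("the packaged annotation reproduces the study's bin map", {
  ann <- defaultAnnotation()
  expect_true(all(c("bin_label", "metabolite", "origin", "tentative",
                    "shared") %in% names(ann)))
  xan <- ann[ann$bin_label == "7.93", ]
  expect_equal(xan$metabolite, "Xanthine")
  expect_equal(xan$origin, "diet")
  # bin 2.18 is shared between butyrate and propionate
  shared <- ann[ann$bin_label == "2.18", ]
  expect_setequal(shared$metabolite, c("Butyrate", "Propionate"))
  expect_true(all(shared$shared))
  expect_setequal(ann$bin_label[ann$metabolite == "Kynurenic acid"],
                  c("6.65", "7.49", "7.68", "7.82"))
  expect_true(all(ann$tentative[ann$metabolite %in%
                                  c("Valerate", "Bile acids")]))
})

test_that("annotation validation rejects bad origins and unflagged clashes", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("bin_label,metabolite,origin",
               "1.00,Foo,plant"), f)
  expect_error(loadAnnotation(f), "origin 'plant'")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("bin_label,metabolite,origin",
               "1.00,Foo,diet", "1.00,Bar,diet"), f2)
  expect_error(loadAnnotation(f2), "not flagged")
})

test_that("metabolite summaries are bin means, reproducing the table rows", {
  summ <- suppressWarnings(
    summarizeMetabolites(printedBinResults(), defaultAnnotation()))
  but <- summ[summ$metabolite == "Butyrate", ]
  expect_equal(but$week14_ratio, 0.74)       # mean of 0.76, 0.65, 0.81
  pro <- summ[summ$metabolite == "Propionate", ]
  expect_equal(pro$week14_ratio, 0.77)       # mean of 0.73, 0.81
  # bin 2.18 contributes to BOTH butyrate and propionate means
  expect_match(but$bins, "2.18")
  expect_match(pro$bins, "2.18")
  # single-bin metabolites pass their bin's values through unchanged
  xan <- summ[summ$metabolite == "Xanthine", ]
  expect_identical(xan$week14_ratio, 1.53)
  expect_identical(xan$week22_ratio, 1.41)
})

test_that("aggregation uses the mean q and is bin-order invariant", {
  res <- data.frame(
    bin_label = c("5.62", "5.63", "5.64"), week = "14",
    ratio_hsc_lsc = c(4, 5, 6), q_fdr = c(0.03, 0.06, 0.09),
    stringsAsFactors = FALSE)
  ann <- data.frame(bin_label = c("5.62", "5.63", "5.64"),
                    metabolite = "UDP-glucose", origin = "microbiome",
                    tentative = FALSE, shared = FALSE,
                    stringsAsFactors = FALSE)
  s1 <- suppressWarnings(summarizeMetabolites(res, ann))
  expect_equal(s1$week14_ratio, 5)
  expect_equal(s1$week14_q, 0.06)            # mean FDR over bins
  expect_equal(s1$week14_tier, "lt_0.1")
  s2 <- suppressWarnings(summarizeMetabolites(res[c(3, 1, 2), ], ann))
  expect_equal(s2$week14_ratio, s1$week14_ratio)
  expect_equal(s2$week14_q, s1$week14_q)
  # minimum-q alternative
  s3 <- suppressWarnings(summarizeMetabolites(res, ann,
                                              fdrAggregation = "min"))
  expect_equal(s3$week14_q, 0.03)
  expect_equal(s3$week14_tier, "lt_0.05")
})

test_that("missing bins are skipped with a warning, empty metabolites drop", {
  res <- data.frame(bin_label = "7.93", week = c("14", "22"),
                    ratio_hsc_lsc = 1.5, q_fdr = 0.2,
                    stringsAsFactors = FALSE)
  w <- capture_warnings(summ <- summarizeMetabolites(res,
                                                     defaultAnnotation()))
  expect_true(any(grepl("absent from results", w)))
  expect_true(any(grepl("no bins in the results", w)))
  expect_equal(summ$metabolite, "Xanthine")
})

test_that("the rendered table follows the reporting layout", {
  res <- printedBinResults()
  res$q_fdr <- rep(c(0.2, 0.2, 0.2, 0.2, 0.03, 0.2,
                     0.07, 0.07, 0.07, 0.07, 0.03, 0.07), 1)
  res$tier <- assignTier(res$q_fdr)
  summ <- suppressWarnings(summarizeMetabolites(res, defaultAnnotation()))
  tab <- suppressWarnings(renderTable1(summ, res, defaultAnnotation()))
  expect_equal(names(tab), c("expected_origin", "bins", "metabolite",
                             "week14_ratio", "week14_fdr", "week22_ratio",
                             "week22_fdr"))
  xan <- tab[tab$metabolite == "Xanthine", ]
  expect_equal(xan$expected_origin, "Diet")
  expect_equal(xan$week14_ratio, "1.53")
  # a q of 0.07 renders as the "<0.1" tier
  expect_true("<0.1" %in% tab$week22_fdr)
  # multi-bin metabolites get per-bin rows plus a mean row
  expect_true("Mean butyrate" %in% tab$metabolite)
  expect_true("Butyrate and propionate" %in% tab$metabolite)
  expect_equal(sum(tab$metabolite == "Butyrate and propionate"), 1L)
  expect_equal(tab$week14_ratio[tab$metabolite == "Mean butyrate"], "0.74")

  # empty summaries give a header-only table
  empty <- renderTable1(summ[0, ], res, defaultAnnotation())
  expect_equal(nrow(empty), 0L)
  expect_equal(names(empty), names(tab))
})
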