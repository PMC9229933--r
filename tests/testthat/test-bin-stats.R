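test_that("group ratio is the HSC mean over the LSC mean, raw scale", {
  gm <- makeGroupMatrix(hsc = c(2, 4), lsc = c(4, 4))
  r <- groupRatio(gm$matrix, gm$meta, 14)
  expect_equal(unname(r), c(0.75, 0.75))

  same <- makeGroupMatrix(hsc = c(3, 3, 3), lsc = c(3, 3, 3))
  expect_equal(unname(groupRatio(same$matrix, same$meta, 22)), c(1, 1))

  # LSC mean of zero flags the ratio as undefined instead of dropping it
  z <- makeGroupMatrix(hsc = c(1, 2), lsc = c(0, 0))
  expect_warning(rz <- groupRatio(z$matrix, z$meta, 14), "undefined")
  expect_true(all(is.na(rz)))
})

test_that("per-week fit equals the pooled-variance t-test", {
  gm <- makeGroupMatrix(hsc = c(10, 12, 14), lsc = c(20, 22, 24))
  res <- fitBinModel(gm$matrix, gm$meta, transform = "identity")
  r14 <- res[res$week == "14" & res$bin_label == "0.10", ]
  oracle <- pooledT(c(10, 12, 14), c(20, 22, 24))
  expect_equal(r14$t_stat, oracle$t, tolerance = 1e-6)
  expect_equal(r14$t_stat, -6.123724, tolerance = 1e-6)
  expect_equal(r14$df, 4)
  expect_equal(r14$p_raw, oracle$p, tolerance = 1e-6)
  expect_equal(r14$p_raw, 0.0036, tolerance = 1e-3)

  # and stats::t.test as a second, independent route on random data
  set.seed(21)
  v <- matrix(rexp(12 * 8, 1e-4), 12, 8)
  meta <- makeMeta(3)
  m <- BinMatrix(v, sprintf("%.2f", 1:8 / 100), meta$sample_id,
                 stage = "thresholded")
  res <- fitBinModel(m, meta, transform = "log2", pseudocount = 0.5)
  for (w in c("14", "22")) {
    sel <- meta$week == as.integer(w)
    for (b in seq_len(8)) {
      y <- log2(v[sel, b] + 0.5)
      tt <- t.test(y[meta$treatment[sel] == "HSC"],
                   y[meta$treatment[sel] == "LSC"], var.equal = TRUE)
      row <- res[res$week == w & res$bin_label == sprintf("%.2f", b / 100), ]
      expect_equal(row$t_stat, unname(tt$statistic), tolerance = 1e-10)
      expect_equal(row$p_raw, tt$p.value, tolerance = 1e-10)
    }
  }
})

test_that("per-week p-values agree with a 10,000-draw permutation test", {
  set.seed(314)
  x <- c(rnorm(10, 0.8), rnorm(10, 0))
  isA <- rep(c(TRUE, FALSE), each = 10)
  pPerm <- permutationP(x, isA, B = 10000, seed = 2)
  pT <- pooledT(x[isA], x[!isA])$p
  gm <- makeGroupMatrix(hsc = x[isA], lsc = x[!isA])
  res <- suppressWarnings(
    fitBinModel(gm$matrix, gm$meta, transform = "identity"))
  pFit <- res$p_raw[res$week == "14"][1]
  expect_equal(pFit, pT, tolerance = 1e-10)
  expect_lt(abs(pFit - pPerm), 0.025)
})

test_that("identical groups give zero effect and p = 1", {
  gm <- makeGroupMatrix(hsc = c(5, 5, 5), lsc = c(5, 5, 5))
  res <- fitBinModel(gm$matrix, gm$meta, transform = "identity")
  expect_true(all(res$log2_effect == 0))
  expect_true(all(res$p_raw == 1))
  expect_false(any(res$degenerate))

  # zero variance with a real difference flags a degenerate fit
  gd <- makeGroupMatrix(hsc = c(4, 4, 4), lsc = c(8, 8, 8))
  resd <- fitBinModel(gd$matrix, gd$meta, transform = "identity")
  expect_true(all(resd$degenerate))
  expect_true(all(is.na(resd$p_raw)))
})

test_that("pooled additive mode reports one treatment contrast per bin", {
  set.seed(33)
  v <- matrix(rexp(24 * 5, 1e-4), 24, 5)
  meta <- makeMeta(6)
  m <- BinMatrix(v, sprintf("%.2f", 1:5 / 100), meta$sample_id,
                 stage = "thresholded")
  res <- fitBinModel(m, meta, mode = "pooled_additive",
                     transform = "log2", pseudocount = 1)
  expect_equal(nrow(res), 5L)
  expect_true(all(res$week == "pooled"))
  expect_true(all(res$df == 21))
  # cross-check against lm() on the first bin
  y <- log2(v[, 1] + 1)
  fit <- summary(lm(y ~ I(meta$treatment == "HSC") + I(meta$week == 22)))
  expect_equal(res$t_stat[1], fit$coefficients[2, "t value"],
               tolerance = 1e-9)
  expect_equal(res$p_raw[1], fit$coefficients[2, "Pr(>|t|)"],
               tolerance = 1e-9)
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.37), 0.37)        # m = 1 identity

  set.seed(99)
  for (i in 1:1000) {
    m <- sample(1:40, 1)
    p <- switch(sample(3, 1), runif(m), rbeta(m, 0.3, 4),
                round(runif(m), 2))       # include ties
    q <- bhAdjust(p)
    expect_equal(q, bruteForceBH(p), tolerance = 1e-12)
    expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
  expect_equal(bhAdjust(c(0.02, NA, 0.04)),
               c(p.adjust(c(0.02, 0.04), "BH")[1], NA,
                 p.adjust(c(0.02, 0.04), "BH")[2]))
})

test_that("significance tiers follow the q thresholds with strict bounds", {
  expect_equal(assignTier(c(0.04, 0.07, 0.10, 0.5, 0.0499999, 0.05)),
               c("lt_0.05", "lt_0.1", "ns", "ns", "lt_0.05", "lt_0.1"))
  expect_true(is.na(assignTier(NA_real_)))
})
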