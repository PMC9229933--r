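#' Per-bin HSC/LSC group-mean ratio
#'
#' Ratio of the arithmetic mean bin intensity in HSC samples to that in LSC
#' samples, on the raw intensity scale. A ratio is undefined (NA, with a
#' warning) where the LSC mean is not positive; it is never silently
#' dropped.
#'
#' @param m a \linkS4class{BinMatrix}.
#' @param meta validated sample metadata covering \code{sampleIds(m)}.
#' @param week 14, 22 or "pooled" (both weeks together).
#' @return Named numeric vector, one ratio per bin.
#' @export
groupRatio <- function(m, meta, week = c("14", "22", "pooled")) {
  week <- match.arg(as.character(week), c("14", "22", "pooled"))
  meta <- .alignMeta(m, meta)
  sel <- if (week == "pooled") rep(TRUE, nrow(meta)) else meta$week ==
    as.integer(week)
  if (!any(sel & meta$treatment == "HSC") ||
      !any(sel & meta$treatment == "LSC"))
    stop("need at least one HSC and one LSC sample at week ", week)
  a <- SummarizedExperiment::assay(m, "intensity")
  mHSC <- rowMeans(a[, sel & meta$treatment == "HSC", drop = FALSE])
  mLSC <- rowMeans(a[, sel & meta$treatment == "LSC", drop = FALSE])
  bad <- mLSC <= 0
  if (any(bad))
    warning("ratio undefined (LSC mean <= 0) for bin(s): ",
            paste(names(bad)[bad], collapse = ", "))
  r <- mHSC / mLSC
  r[bad] <- NA_real_
  r
}

# match metadata rows to matrix columns, in column order
.alignMeta <- function(m, meta) {
  meta <- validateSampleMetadata(meta)
  miss <- setdiff(sampleIds(m), meta$sample_id)
  if (length(miss))
    stop("metadata is missing sample(s): ", paste(miss, collapse = ", "))
  meta[match(sampleIds(m), meta$sample_id), , drop = FALSE]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' The classical step-up rule: with sorted p-values \eqn{p_{(1)} \le \dots
#' \le p_{(m)}}, \eqn{q_{(i)} = \min_{j \ge i} m \, p_{(j)} / j}, capped at
#' 1 and mapped back to input order. NAs are propagated and not counted in
#' \eqn{m}.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Numeric vector of q-values, same length and order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  m <- sum(ok)
  if (m) {
    o <- order(p[ok])
    sorted <- p[ok][o]
    adj <- m * sorted / seq_len(m)
    qs <- pmin(1, rev(cummin(rev(adj))))
    tmp <- numeric(m)
    tmp[o] <- qs
    q[ok] <- tmp
  }
  q
}

#' Map a q-value to its significance tier
#'
#' Tiers follow the reporting convention \code{q < 0.05} ("lt_0.05"),
#' \code{0.05 <= q < 0.1} ("lt_0.1") and \code{q >= 0.1} ("ns"); the upper
#' threshold is strict, so q = 0.10 is not significant.
#'
#' @param q numeric q-value(s) in [0, 1]; NA gives NA.
#' @param tiers ascending pair of thresholds (default \code{c(0.05, 0.1)}).
#' @return Character vector of tiers.
#' @export
assignTier <- function(q, tiers = c(0.05, 0.1)) {
  stopifnot(length(tiers) == 2L, tiers[1] > 0, tiers[1] < tiers[2],
            tiers[2] <= 1)
  out <- rep(NA_character_, length(q))
  ok <- !is.na(q)
  out[ok] <- ifelse(q[ok] < tiers[1], sprintf("lt_%g", tiers[1]),
                    ifelse(q[ok] < tiers[2], sprintf("lt_%g", tiers[2]),
                           "ns"))
  out
}

#' Per-bin linear-model tests of the treatment effect
#'
#' Fits, for every bin, an ordinary-least-squares linear model of the
#' (log2-transformed) bin intensity on treatment, by closed-form least
#' squares. Two modes:
#' \describe{
#'   \item{per_week (default)}{each week analysed separately: intensity ~
#'     treatment, treatment t-statistic on n - 2 df. Algebraically
#'     identical to the pooled-variance two-sample t-test.}
#'   \item{pooled_additive}{one fit per bin with additive treatment + age
#'     (week) effects; the treatment contrast is reported once, on n - 3
#'     df, with week = "pooled".}
#' }
#' P-values are two-sided from the t distribution. Benjamini-Hochberg
#' q-values are computed within each week across the bins of \code{m} (run
#' this on the post-filter matrix so the FDR is over retained bins only).
#' Ratios are reported on the raw intensity scale regardless of the test
#' transform.
#'
#' Degenerate fits (zero residual variance) get p = 1 when the effect is
#' also zero, otherwise p = NA with \code{degenerate = TRUE}.
#'
#' @param m a \linkS4class{BinMatrix}; must contain at least one bin.
#' @param meta validated sample metadata.
#' @param mode "per_week" or "pooled_additive".
#' @param transform "log2" (default; log2(value + pseudocount)) or
#'   "identity".
#' @param pseudocount "auto" (half the smallest positive value in \code{m})
#'   or a number. In the assembled pipeline the auto pseudocount is
#'   computed on the raw pre-filter matrix and passed down, so that
#'   post-filter intensities (all large) do not inflate it.
#' @param tiers significance-tier thresholds, see \code{\link{assignTier}}.
#' @return data.frame with one row per (bin, week): \code{bin_label},
#'   \code{week}, \code{ratio_hsc_lsc}, \code{log2_effect}, \code{t_stat},
#'   \code{df}, \code{p_raw}, \code{q_fdr}, \code{tier},
#'   \code{degenerate}.
#' @export
fitBinModel <- function(m, meta,
                        mode = c("per_week", "pooled_additive"),
                        transform = c("log2", "identity"),
                        pseudocount = "auto", tiers = c(0.05, 0.1)) {
  stopifnot(is(m, "BinMatrix"))
  mode <- match.arg(mode)
  transform <- match.arg(transform)
  if (nrow(m) == 0L)
    stop("no bins to test (the filter cascade removed everything)")
  meta <- .alignMeta(m, meta)
  a <- SummarizedExperiment::assay(m, "intensity")   # bins x samples

  if (transform == "log2") {
    pc <- if (identical(pseudocount, "auto")) {
      pos <- a[a > 0]
      if (!length(pos)) stop("matrix has no positive values")
      min(pos) / 2
    } else as.numeric(pseudocount)
    if (any(a + pc <= 0))
      stop("log2 transform needs value + pseudocount > 0 everywhere")
    y <- log2(a + pc)
  } else {
    y <- a
  }

  if (mode == "per_week") {
    out <- do.call(rbind, lapply(c(14L, 22L), function(w) {
      sel <- meta$week == w
      .twoGroupFit(y[, sel, drop = FALSE],
                   meta$treatment[sel] == "HSC", m, meta, w, tiers)
    }))
  } else {
    out <- .additiveFit(y, meta, m, tiers)
  }
  rownames(out) <- NULL
  out
}

# closed-form OLS of y on an intercept + group indicator; identical to the
# pooled-variance two-sample t-test
.twoGroupFit <- function(y, isHSC, m, meta, week, tiers) {
  n1 <- sum(isHSC); n0 <- sum(!isHSC)
  if (n1 < 2L || n0 < 2L)
    stop("need >= 2 samples per treatment at week ", week)
  m1 <- rowMeans(y[, isHSC, drop = FALSE])
  m0 <- rowMeans(y[, !isHSC, drop = FALSE])
  rss <- rowSums((y[, isHSC, drop = FALSE] - m1)^2) +
    rowSums((y[, !isHSC, drop = FALSE] - m0)^2)
  df <- n1 + n0 - 2L
  s2 <- rss / df
  eff <- m1 - m0
  se <- sqrt(s2 * (1 / n1 + 1 / n0))
  t <- eff / se
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  degen <- s2 <= 0
  if (any(degen)) {
    zeroEff <- degen & abs(eff) < .Machine$double.eps^0.5
    t[zeroEff] <- 0; p[zeroEff] <- 1
    t[degen & !zeroEff] <- sign(eff[degen & !zeroEff]) * Inf
    p[degen & !zeroEff] <- NA_real_
    degen <- degen & !zeroEff
  }
  q <- bhAdjust(p)
  data.frame(bin_label = rownames(y), week = as.character(week),
             ratio_hsc_lsc = unname(groupRatio(m, meta, week)),
             log2_effect = unname(eff), t_stat = unname(t), df = df,
             p_raw = unname(p), q_fdr = q, tier = assignTier(q, tiers),
             degenerate = unname(degen), stringsAsFactors = FALSE)
}

# OLS with intercept + treatment + age indicators via the normal equations
.additiveFit <- function(y, meta, m, tiers) {
  tr <- as.numeric(meta$treatment == "HSC")
  ag <- as.numeric(meta$week == 22L)
  X <- cbind(1, tr, ag)
  if (qr(X)$rank < 3L) stop("singular design for pooled_additive mode")
  n <- nrow(X)
  if (n < 4L) stop("pooled_additive mode needs > 3 samples")
  XtXi <- solve(crossprod(X))
  B <- y %*% X %*% XtXi                 # bins x 3 coefficients
  fitted <- B %*% t(X)
  rss <- rowSums((y - fitted)^2)
  df <- n - 3L
  s2 <- rss / df
  eff <- B[, 2L]
  se <- sqrt(s2 * XtXi[2L, 2L])
  t <- eff / se
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  degen <- s2 <= 0
  if (any(degen)) {
    zeroEff <- degen & abs(eff) < .Machine$double.eps^0.5
    t[zeroEff] <- 0; p[zeroEff] <- 1
    t[degen & !zeroEff] <- sign(eff[degen & !zeroEff]) * Inf
    p[degen & !zeroEff] <- NA_real_
    degen <- degen & !zeroEff
  }
  q <- bhAdjust(p)
  data.frame(bin_label = rownames(y), week = "pooled",
             ratio_hsc_lsc = unname(groupRatio(m, meta, "pooled")),
             log2_effect = unname(eff), t_stat = unname(t), df = df,
             p_raw = unname(p), q_fdr = q, tier = assignTier(q, tiers),
             degenerate = unname(degen), stringsAsFactors = FALSE)
}
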