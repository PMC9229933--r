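# Independent oracles and small fixtures shared across the suite.

# Brute-force Benjamini-Hochberg step-up: q_i = min over j with
# p_j >= p_i of m * p_j / rank_j, straight from the definition, O(m^2).
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  rank <- integer(m)
  rank[o] <- seq_len(m)
  vapply(seq_len(m), function(i) {
    cand <- which(p >= p[i] - 1e-15)
    min(1, min(m * p[cand] / rank[cand]))
  }, 0)
}

# classical pooled-variance two-sample t (HSC - LSC), closed form
pooledT <- function(hsc, lsc) {
  n1 <- length(hsc); n0 <- length(lsc)
  sp2 <- (sum((hsc - mean(hsc))^2) + sum((lsc - mean(lsc))^2)) /
    (n1 + n0 - 2)
  t <- (mean(hsc) - mean(lsc)) / sqrt(sp2 * (1 / n1 + 1 / n0))
  list(t = t, df = n1 + n0 - 2,
       p = 2 * pt(abs(t), n1 + n0 - 2, lower.tail = FALSE))
}

# Monte-Carlo permutation p-value for the two-sample t statistic
permutationP <- function(x, isA, B = 10000, seed = 1) {
  set.seed(seed)
  tObs <- abs(pooledT(x[isA], x[!isA])$t)
  hits <- 0L
  for (b in seq_len(B)) {
    g <- sample(isA)
    if (abs(pooledT(x[g], x[!g])$t) >= tObs - 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (B + 1)
}

# 2x2 metadata for hand-built matrices: n samples per treatment per week
makeMeta <- function(n, weeks = c(14L, 22L)) {
  g <- expand.grid(i = seq_len(n), treatment = c("HSC", "LSC"),
                   week = weeks, stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("s_%s_w%d_%d", g$treatment, g$week, g$i),
             animal_id = sprintf("a_%s_%d", g$treatment, g$i),
             pen_id = sprintf("p_%s_%d", g$treatment, g$i),
             treatment = g$treatment, week = g$week,
             stringsAsFactors = FALSE)
}

# a BinMatrix with given per-group values replicated at every bin
makeGroupMatrix <- function(hsc, lsc, bins = c("0.10", "0.20"),
                            weeks = c(14L, 22L)) {
  meta <- makeMeta(length(hsc), weeks)
  v <- matrix(NA_real_, nrow(meta), length(bins))
  for (w in weeks) {
    v[meta$treatment == "HSC" & meta$week == w, ] <- hsc
    v[meta$treatment == "LSC" & meta$week == w, ] <- lsc
  }
  list(matrix = BinMatrix(v, bins, meta$sample_id, stage = "thresholded"),
       meta = meta)
}

# reduced-size synthetic design on a 1-ppm window (100 bins), interference
# moved to [0.50, 0.70); five single-peak metabolites clear of that region
smallLibrary <- function() {
  sigs <- list(
    metaboliteSignature("MetA", 0.105, "diet"),
    metaboliteSignature("MetB", 0.205, "microbiome"),
    metaboliteSignature("MetC", 0.305, "microbiome"),
    metaboliteSignature("MetD", 0.405, "endogenous"),
    metaboliteSignature("MetE", 0.905, "microbiome"))
  names(sigs) <- vapply(sigs, function(s) s@name, "")
  sigs
}

smallDesign <- function(seed, plantedRatio = data.frame(
                          metabolite = character(), week = integer(),
                          ratio = numeric()), ...) {
  args <- list(nPerCell = 6L, plantedRatio = plantedRatio,
               windowLo = 0, windowHi = 1,
               interferenceLo = 0.50, interferenceHi = 0.70,
               pointsPerBin = 8L, seed = seed)
  do.call(cohortDesign, utils::modifyList(args, list(...)))
}

smallBinSpec <- function() binSpec(0, 1, 0.01)

# Table-1-style printed per-bin ratio rows, as a fitBinModel-shaped frame
printedBinResults <- function() {
  df <- data.frame(
    bin_label = rep(c("7.93", "1.52", "0.88", "2.18", "1.06", "0.84"), 2),
    week = rep(c("14", "22"), each = 6),
    ratio_hsc_lsc = c(1.53, 0.76, 0.65, 0.81, 0.73, 0.84,
                      1.41, 0.78, 0.75, 0.86, 0.73, 1.37),
    stringsAsFactors = FALSE)
  df$q_fdr <- NA_real_
  df
}
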