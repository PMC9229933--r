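# round half away from zero (presentation only; internal arithmetic stays
# at full precision)
.roundHalfUp <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

.formatRatio <- function(x, digits = 2) {
  ifelse(is.na(x), "", sprintf(paste0("%.", digits, "f"),
                               .roundHalfUp(x, digits)))
}

# human-readable origin labels for report tables
.originLabel <- c(diet = "Diet", microbiome = "Microbiome",
                  endogenous = "Endogenous (host)")

.tierLabel <- function(tier) {
  ifelse(is.na(tier), "",
         ifelse(tier == "ns", "ns", sub("^lt_", "<", tier)))
}

# deterministic stream of sub-seeds from one master seed (31-bit range)
.deriveSeeds <- function(master, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n)
}
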