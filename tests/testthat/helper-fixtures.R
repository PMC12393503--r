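# Shared fixtures, built in code at test time.

# small cohort config: one exposure, fast
smallConfig <- function(seed = 11, ...) {
    simConfig(nGenes = 300, exposures = "As", replicatesPerCell = 4,
              nDegShared = 10, nRegions = 200, nDar = 20, nDmr = 20,
              nStateSwitch = 8, seed = seed, ...)
}

# build a DifferentialResult by hand: named effect vector + significant ids
makeDiffResult <- function(effects, sigFeatures,
                           contrast = list(tissue = "liver", sex = "F",
                                           age = "5mo", exposure = "As"),
                           type = "expression") {
    stats <- data.frame(feature = names(effects), effect = unname(effects),
                        p = ifelse(names(effects) %in% sigFeatures,
                                   1e-9, 0.9),
                        stringsAsFactors = FALSE)
    callDifferential(stats, qMax = 0.05, effectMin = 1,
                     contrast = contrast, type = type)
}

# build a PatternAssignment by hand from gene -> pattern id
makeAssignment <- function(patterns,
                           condition = list(tissue = "liver", sex = "F",
                                            exposure = "control")) {
    dirs <- patternDirections()
    idx <- match(patterns, dirs$pattern)
    tb <- data.frame(gene = names(patterns), d1 = dirs$d1[idx],
                     d2 = dirs$d2[idx], pattern = as.integer(patterns),
                     effect1 = 0, q1 = 1, effect2 = 0, q2 = 1,
                     classified = TRUE, stringsAsFactors = FALSE)
    new("PatternAssignment", condition = condition, table = tb)
}

# exhaustive hypergeometric upper tail by enumeration (test oracle)
enumTail <- function(k, K, n, N) {
    j <- k:min(K, n)
    sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Welch t-test oracle via stats::t.test on one feature
welchOracle <- function(a, b) {
    tt <- t.test(b, a, var.equal = FALSE)
    list(effect = mean(b) - mean(a), p = tt$p.value)
}
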