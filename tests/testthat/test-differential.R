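mat1 <- function(a, b) {
    m <- rbind(c(a, b))
    dimnames(m) <- list("g1", c(paste0("a", seq_along(a)),
                                paste0("b", seq_along(b))))
    m
}

test_that("two-group test handles identical and degenerate groups", {
    m <- mat1(c(1, 1, 1), c(1, 1, 1))
    r <- twoGroupTest(m, paste0("a", 1:3), paste0("b", 1:3))
    expect_equal(r$effect, 0)
    expect_equal(r$p, 1)
    expect_false(r$degenerate)

    m <- mat1(c(3, 3, 3), c(15, 15, 15))
    r <- twoGroupTest(m, paste0("a", 1:3), paste0("b", 1:3))
    expect_equal(r$effect, log2(16) - log2(4))  # exactly 2
    expect_equal(r$p, 0)
    expect_true(r$degenerate)
})

test_that("two-group test enforces its contracts", {
    m <- mat1(1:3, 4:6)
    expect_error(twoGroupTest(m, c("a1", "a2"), paste0("b", 1:3)),
                 ">= 3 samples")
    expect_error(twoGroupTest(m, paste0("a", 1:3), c("b1", "b2", "a1")),
                 "disjoint")
    expect_error(twoGroupTest(m, paste0("a", 1:3), c("b1", "b2", "zz")),
                 "unknown sample")
})

test_that("Welch statistics match the t.test oracle on random instances", {
    set.seed(42)
    for (i in 1:200) {
        na <- sample(3:8, 1); nb <- sample(3:8, 1)
        a <- rexp(na, 0.2); b <- rexp(nb, 0.2)
        m <- mat1(a, b)
        r <- twoGroupTest(m, paste0("a", seq_len(na)),
                          paste0("b", seq_len(nb)))
        o <- welchOracle(log2(a + 1), log2(b + 1))
        expect_equal(r$effect, o$effect, tolerance = 1e-12)
        expect_lt(abs(r$p - o$p), 1e-12)
    }
})

test_that("identity scale gives mean differences for beta values", {
    m <- mat1(c(0.2, 0.25, 0.3), c(0.6, 0.62, 0.61))
    r <- twoGroupTest(m, paste0("a", 1:3), paste0("b", 1:3),
                      scale = "identity")
    expect_equal(r$effect, mean(c(0.6, 0.62, 0.61)) - 0.25)
})

test_that("BH adjustment is the standard step-up with domain checks", {
    expect_equal(bhAdjust(0.5), 0.5)
    expect_equal(bhAdjust(c(1, 1)), c(1, 1))
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("differential calls respect thresholds and directions", {
    stats <- data.frame(feature = c("g1", "g2", "g3"),
                        effect = c(3, -2, 0.2),
                        p = c(1e-6, 1e-5, 1e-4))
    res <- callDifferential(stats)
    tb <- resultTable(res)
    expect_identical(significantFeatures(res), c("g1", "g2"))
    expect_identical(tb$direction[1:2], c("up", "down"))
    # sub-floor effect is never significant, whatever its q
    expect_false(tb$significant[3])

    allNull <- data.frame(feature = paste0("g", 1:5), effect = rnorm(5),
                          p = rep(1, 5))
    expect_length(significantFeatures(callDifferential(allNull)), 0)

    meth <- callDifferential(data.frame(feature = "r1", effect = -0.3,
                                        p = 1e-8), type = "methylation")
    expect_identical(resultTable(meth)$direction, "hypo")
})

test_that("thresholds act monotonically on the number of calls", {
    set.seed(7)
    stats <- data.frame(feature = sprintf("g%03d", 1:300),
                        effect = rnorm(300, 0, 2),
                        p = runif(300)^2)
    nsig <- function(q, e)
        length(significantFeatures(callDifferential(stats, qMax = q,
                                                    effectMin = e)))
    for (e in c(0, 0.5, 1, 2))
        expect_true(all(diff(sapply(c(0.5, 1, 2, 3),
                                    function(x) nsig(0.05, x))) <= 0))
    for (q in c(0.2, 0.1, 0.05, 0.01))
        expect_true(all(diff(sapply(c(0.2, 0.1, 0.05, 0.01),
                                    function(x) nsig(x, 1))) <= 0))
})

test_that("direction summaries cover both defined and undefined cases", {
    eff <- c(rep(2, 7), rep(-2, 3)); names(eff) <- paste0("g", 1:10)
    res <- makeDiffResult(eff, names(eff))
    s <- summarizeDirection(res)
    expect_equal(s$fraction_up, 0.7)
    expect_equal(s$fraction_up + s$fraction_down, 1)

    none <- makeDiffResult(eff, character())
    expect_false(summarizeDirection(none)$defined)

    meth <- makeDiffResult(-eff[1:5] / 2, paste0("g", 1:5),
                           type = "methylation")
    expect_equal(summarizeDirection(meth)$fraction_hypo, 1)
})

test_that("signature decomposition partitions the union", {
    eff <- c(g1 = 2, g2 = 2, g3 = 2)
    res <- list(As = makeDiffResult(eff, c("g1", "g2")),
                Pb = makeDiffResult(eff, c("g2", "g3"),
                                    contrast = list(tissue = "liver",
                                                    sex = "F", age = "5mo",
                                                    exposure = "Pb")))
    dec <- decomposeSignatures(res)
    expect_identical(specificSets(dec)$As, "g1")
    expect_identical(specificSets(dec)$Pb, "g3")
    expect_identical(sharedFeatures(dec), list(g2 = c("As", "Pb")))
    expect_equal(multiResponseFraction(dec), 1 / 3)

    single <- decomposeSignatures(res["As"])
    expect_identical(sort(specificSets(single)$As), c("g1", "g2"))
    expect_length(sharedFeatures(single), 0)
    expect_equal(multiResponseFraction(single), 0)

    mism <- makeDiffResult(eff, "g1",
                           contrast = list(tissue = "blood", sex = "F",
                                           age = "5mo", exposure = "Pb"))
    expect_error(decomposeSignatures(list(As = res$As, Pb = mism)),
                 "mix tissue")
})

test_that("decomposition partition property holds on random set systems", {
    set.seed(99)
    genes <- sprintf("g%03d", 1:60)
    for (i in 1:20) {
        eff <- structure(rep(2, 60), names = genes)
        res <- lapply(c("As", "Pb", "TBT"), function(e)
            makeDiffResult(eff, sample(genes, sample(5:30, 1)),
                           contrast = list(tissue = "liver", sex = "M",
                                           age = "3wk", exposure = e)))
        names(res) <- c("As", "Pb", "TBT")
        dec <- decomposeSignatures(res)
        expect_identical(length(featureUnion(dec)),
                         sum(lengths(specificSets(dec))) +
                         length(sharedFeatures(dec)))
    }
})

test_that("empty decompositions mark the fraction undefined", {
    eff <- c(g1 = 0.1)
    dec <- decomposeSignatures(list(As = makeDiffResult(eff, character())))
    expect_warning(f <- multiResponseFraction(dec), "undefined")
    expect_true(is.na(f))
})

test_that("cross-tissue concordance partitions by joint direction", {
    eff <- c(g1 = 2, g2 = 2, g3 = -2, g4 = -2)
    liver <- makeDiffResult(eff, c("g1", "g2", "g3"))
    effB <- c(g1 = 2, g2 = -2, g4 = -2)
    blood <- makeDiffResult(effB, c("g1", "g2", "g4"))
    cc <- crossTissueConcordance(liver, blood)
    expect_identical(cc$common_up, "g1")
    expect_identical(cc$common_down, character(0))
    expect_identical(cc$anticorrelated, "g2")
    expect_identical(cc$liver_only, "g3")
    expect_identical(cc$blood_only, "g4")

    same <- crossTissueConcordance(liver, liver)
    expect_length(same$anticorrelated, 0)
    expect_identical(sort(c(same$common_up, same$common_down)),
                     sort(significantFeatures(liver)))

    meth <- makeDiffResult(c(g1 = -0.3), "g1", type = "methylation")
    expect_error(crossTissueConcordance(liver, meth), "gene features")
})

test_that("planted DEGs are recovered with controlled false positives", {
    cfg <- simConfig(nGenes = 2000, exposures = "As",
                     replicatesPerCell = 5, nSexBiased = 0,
                     exposureEffects = list(As = list(nDegSpecific = 50,
                                                     degLog2fc = 2)),
                     nDegShared = 0, seed = 77)
    sim <- simulateCohort(cfg)
    res <- exposureContrast(sim$experiment, "liver", "F", "5mo", "As")
    called <- significantFeatures(res)
    planted <- sim$truth$degSets$As$gene
    expect_gte(length(intersect(called, planted)), 45)
    expect_lte(length(setdiff(called, planted)), 10)
    # recovered directions match the planted ones
    tb <- resultTable(res)
    hit <- tb[tb$feature %in% planted & tb$significant, ]
    expect_identical(hit$direction,
                     sim$truth$degSets$As$direction[
                         match(hit$feature, planted)])
})

test_that("region-level methylation averages contained CpGs", {
    cpg <- GRanges("chr1", IRanges(c(10, 20, 30, 40, 110, 120), width = 1))
    regions <- GRanges("chr1", IRanges(c(1, 100), c(50, 150)))
    mcols(regions)$name <- c("r1", "r2"); names(regions) <- c("r1", "r2")
    betas <- matrix(c(0.2, 0.4, 0.6, 0.8, 0.1, 0.3), ncol = 1,
                    dimnames = list(NULL, "s1"))
    expect_message(out <- regionLevelMethylation(betas, cpg, regions,
                                                 minCpg = 3), "dropped")
    expect_identical(rownames(out), "r1")
    expect_equal(out["r1", "s1"], 0.5)

    out2 <- regionLevelMethylation(betas, cpg, regions, minCpg = 2)
    expect_equal(out2["r2", "s1"], 0.2)

    unsorted <- GRanges("chr1", IRanges(c(20, 10, 30, 40, 110, 120),
                                        width = 1))
    expect_error(regionLevelMethylation(betas, unsorted, regions),
                 "sorted")
})
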