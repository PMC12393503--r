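# raw-scale matrix whose log2(x+1) values are exactly L
rawFromLog2 <- function(L) pmax(2^L - 1, 0)

test_that("embeddings capture exact low-rank structure and are deterministic", {
    set.seed(5)
    basis <- qr.Q(qr(matrix(rnorm(40 * 2), 40)))   # 40 genes, rank-2 plane
    scores <- matrix(rnorm(12 * 2, sd = 3), 12)
    L <- t(scores %*% t(basis)) + 5
    dimnames(L) <- list(paste0("g", 1:40), paste0("s", 1:12))
    m <- rawFromLog2(L)
    em <- fitEmbedding(m, colnames(m), nPc = 2)
    expect_equal(sum(em@varExplained), 1, tolerance = 1e-10)

    em2 <- fitEmbedding(m, colnames(m), nPc = 2)
    expect_identical(em@loadings, em2@loadings)

    expect_error(fitEmbedding(m[1:5, ], colnames(m), nPc = 8), "rank")
    expect_error(fitEmbedding(m, colnames(m)[1:3], nPc = 3), "nPc \\+ 1")
})

test_that("column signs follow the largest-magnitude-loading rule", {
    set.seed(8)
    L <- matrix(rnorm(30 * 10, 4), 30,
                dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
    em <- fitEmbedding(rawFromLog2(L), paste0("s", 1:10), nPc = 3)
    for (j in 1:3) {
        lead <- which.max(abs(em@loadings[, j]))
        expect_gt(em@loadings[lead, j], 0)
    }
    expect_lt(max(abs(crossprod(em@loadings) - diag(3))), 1e-10)
})

test_that("projection reproduces fit coordinates and sends the center to the origin", {
    set.seed(13)
    L <- matrix(rnorm(50 * 15, 5), 50,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:15)))
    m <- rawFromLog2(L)
    em <- fitEmbedding(m, colnames(m), nPc = 4)
    co <- projectSamples(em, m)
    pc <- prcomp(t(log2(m + 1)), center = TRUE)
    ref <- pc$x[, 1:4]
    # same coordinates up to the deterministic column sign fix
    for (j in 1:4)
        expect_equal(unname(abs(co[, j])), unname(abs(ref[, j])),
                     tolerance = 1e-8)

    centerSample <- matrix(rawFromLog2(em@center), ncol = 1,
                           dimnames = list(names(em@center), "c0"))
    expect_equal(max(abs(projectSamples(em, centerSample))), 0,
                 tolerance = 1e-8)

    expect_error(projectSamples(em, m[1:10, ]), "missing genes")
})

test_that("the truncated embedding matches an SVD oracle", {
    set.seed(21)
    L <- matrix(rnorm(50 * 20, 5), 50,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:20)))
    m <- rawFromLog2(L)
    nPc <- 5
    em <- fitEmbedding(m, colnames(m), nPc = nPc)
    co <- projectSamples(em, m)
    recon <- em@loadings %*% t(co) + em@center
    X <- log2(m + 1)
    Xc <- X - rowMeans(X)
    sv <- svd(Xc)
    reconOracle <- sv$u[, 1:nPc] %*% diag(sv$d[1:nPc]) %*%
        t(sv$v[, 1:nPc]) + rowMeans(X)
    expect_lt(max(abs(recon - reconOracle)), 1e-8)
})

test_that("distances to the control centroid are Euclidean in the leading PCs", {
    co <- rbind(a = c(1, 2, 3, 9), b = c(4, 6, 3, -9))
    centroid <- c(1, 2, 3, 0)
    d <- distanceToControl(co, centroid, nPcUsed = 3)
    expect_equal(unname(d), c(0, 5))   # offset (3,4,0) -> 5
    expect_error(distanceToControl(co, numeric(0)), "empty")
})

test_that("sex scores pin control centroids to 0 and 1 at every age", {
    sim <- simulateCohort(smallConfig(seed = 23))
    sdf <- sampleData(sim$experiment)
    ctrl <- sdf$sample_id[sdf$exposure == "control"]
    em <- fitEmbedding(sim$experiment, ctrl, nPc = 2)
    co <- projectSamples(em, sim$experiment)
    for (age in ageLevels()) {
        ax <- sexAxis(co, sdf, age)
        f <- colMeans(co[sdf$sample_id[sdf$sex == "F" & sdf$age == age &
                                       sdf$exposure == "control"], ,
                         drop = FALSE])
        m <- colMeans(co[sdf$sample_id[sdf$sex == "M" & sdf$age == age &
                                       sdf$exposure == "control"], ,
                         drop = FALSE])
        expect_equal(unname(sexDiscrepancyScore(rbind(f), ax)), 0,
                     tolerance = 1e-10)
        expect_equal(unname(sexDiscrepancyScore(rbind(m), ax)), 1,
                     tolerance = 1e-10)
        expect_equal(unname(sexDiscrepancyScore(rbind((f + m) / 2), ax)),
                     0.5, tolerance = 1e-10)
        # unsigned variant also normalizes the male centroid to 1
        expect_equal(unname(sexDiscrepancyScore(rbind(m), ax,
                                                unsigned = TRUE)), 1,
                     tolerance = 1e-10)
    }
    expect_error(sexAxis(co, sdf[sdf$sex == "F", ], "3wk"), "both sexes")
})

test_that("scores and distances are invariant to a constant expression shift", {
    sim <- simulateCohort(smallConfig(seed = 29))
    sdf <- sampleData(sim$experiment)
    ctrl <- sdf$sample_id[sdf$exposure == "control"]
    m <- exprValues(sim$experiment)
    shifted <- rawFromLog2(log2(m + 1) + 1)   # +1 log2 unit everywhere
    em <- fitEmbedding(m, ctrl, nPc = 2)
    emS <- fitEmbedding(shifted, ctrl, nPc = 2)
    sc <- sexDiscrepancyScore(projectSamples(em, m),
                              sexAxis(projectSamples(em, m), sdf, "5mo"))
    scS <- sexDiscrepancyScore(projectSamples(emS, shifted),
                               sexAxis(projectSamples(emS, shifted), sdf,
                                       "5mo"))
    expect_equal(sc, scS, tolerance = 1e-6)
})

test_that("score deviation has exact degenerate behavior and contracts", {
    x <- c(0.1, 0.2, 0.3, 0.4, 0.5)
    d <- scoreDeviation(x, x, nPerm = 500, seed = 1)
    expect_equal(d$delta, 0)
    expect_gt(d$p, 0.5)
    expect_error(scoreDeviation(x, x, nPerm = 50), ">= 100")
    expect_error(scoreDeviation(numeric(0), x), "non-empty")
})

test_that("null permutation p-values are close to uniform", {
    set.seed(31)
    ps <- vapply(1:300, function(i) {
        pool <- rnorm(12)
        scoreDeviation(pool[1:6], pool[7:12], nPerm = 200)$p
    }, 0)
    ks <- suppressWarnings(ks.test(ps, "punif"))
    expect_lt(unname(ks$statistic), 0.1)
})

test_that("sex-biased gene discovery is symmetric under label swap", {
    cfg <- simConfig(nGenes = 600, exposures = "As",
                     replicatesPerCell = 5, nSexBiased = 60,
                     sexEffectLog2 = 2, nDegShared = 0,
                     exposureEffects = list(As = list(nDegSpecific = 0)),
                     seed = 37)
    sim <- simulateCohort(cfg)
    sb <- sexBiasedGenes(sim$experiment, age = "5mo")
    truthM <- sim$truth$maleBiased
    truthF <- sim$truth$femaleBiased
    expect_gte(length(intersect(sb$maleBiased, truthM)), 27)
    expect_gte(length(intersect(sb$femaleBiased, truthF)), 27)
    expect_lte(length(setdiff(c(sb$maleBiased, sb$femaleBiased),
                              c(truthM, truthF))), 6)

    # swapping the sex labels swaps the two sets exactly
    swapped <- sim$experiment
    sdf <- sampleData(swapped)
    SummarizedExperiment::colData(swapped)$sex <-
        ifelse(sdf$sex == "F", "M", "F")
    sb2 <- sexBiasedGenes(swapped, age = "5mo")
    expect_setequal(sb2$maleBiased, sb$femaleBiased)
    expect_setequal(sb2$femaleBiased, sb$maleBiased)
})

test_that("feminization classes follow significance and movement toward the female mean", {
    # 3 genes x (M control, M exposed, F control), 4 reps each:
    # g1 male-biased, exposed males drop to the female mean -> toward_female
    # g2 male-biased, unchanged -> unchanged
    # g3 male-biased, exposed males rise away from female mean -> away
    ids <- c(outer(c("MC", "ME", "FC"), 1:4, paste0))
    sdf <- data.frame(sample_id = ids, tissue = "liver",
                      sex = rep(c("M", "M", "F"), 4),
                      age = "10mo",
                      exposure = rep(c("control", "PM25_CHI", "control"),
                                     4),
                      animal_id = ids, litter_id = "L1",
                      stringsAsFactors = FALSE)
    jitter <- rep(c(0, 0.02, -0.02, 0.01), each = 3)
    L <- rbind(g1 = c(8, 4, 4), g2 = c(8, 8, 4), g3 = c(8, 10, 4))
    L <- L[, rep(1:3, 4)] + rep(jitter, each = 3)
    colnames(L) <- ids
    ee <- ExposureExperiment(rawFromLog2(L), sdf)
    fem <- feminizationAnalysis(list(maleBiased = c("g1", "g2", "g3"),
                                     femaleBiased = character()),
                                ee, exposure = "PM25_CHI", age = "10mo")
    cls <- structure(fem$table$class, names = fem$table$gene)
    expect_identical(unname(cls["g1"]), "toward_female")
    expect_identical(unname(cls["g2"]), "unchanged")
    expect_identical(unname(cls["g3"]), "away_from_female")
    expect_identical(as.integer(fem$counts), c(1L, 1L, 1L))
    expect_error(feminizationAnalysis(list(maleBiased = character(),
                                           femaleBiased = character()),
                                      ee, "PM25_CHI", "10mo"), "empty")
})

test_that("planted feminization shifts counts as planted", {
    cfg <- simConfig(nGenes = 500, exposures = "PM25_CHI",
                     replicatesPerCell = 5, nSexBiased = 60,
                     sexEffectLog2 = 2, nDegShared = 0,
                     exposureEffects = list(PM25_CHI = list(
                         nDegSpecific = 0, feminization = 1)),
                     seed = 43)
    sim <- simulateCohort(cfg)
    truth <- list(maleBiased = sim$truth$maleBiased,
                  femaleBiased = sim$truth$femaleBiased)
    fem <- feminizationAnalysis(truth, sim$experiment,
                                exposure = "PM25_CHI", age = "5mo")
    counts <- as.integer(fem$counts)
    # full feminization: essentially all 60 biased genes move toward female
    expect_gte(counts[1], 56)
    expect_lte(counts[2], 2)
})
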