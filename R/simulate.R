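## Truth-tracked synthetic cohort generator. Emulates the longitudinal
## study design: two sexes x three ages (3wk, 5mo, 10mo) x vehicle control
## plus nine exposure conditions x n replicates, with planted temporal
## patterns, sex-biased genes, exposure DEG/DAR/DMR effects, temporal
## pattern switches and chromatin-state switches. One RNG stream per
## modality, derived from the master seed by fixed offsets, so adding a
## modality never perturbs another's draws.

.streamOffsets <- c(expression = 101L, methylome = 211L,
                    accessibility = 307L, segmentation = 401L,
                    blood = 503L)

#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic cohort
#' generator. Defaults encode the emulated study conditions: 2,000 genes,
#' 5 replicates per design cell, planted age-interval steps of 2.0 log2
#' units with Gaussian log2 noise sd 0.25, 60 sex-biased genes (30
#' male-biased, 30 female-biased) at 2.0 log2 units, and per-exposure
#' differential signatures of 40 exposure-specific genes plus a 90-gene
#' multi-response pool perturbed by every exposure (a planted
#' multi-response fraction of 0.20 of the union over the nine exposures,
#' matching the 15-24% multi-response band reported for real cohorts).
#' Methylation defaults plant 100 regions shifted by |0.3| beta with 90%
#' hypomethylation, emulating the strongly hypomethylation-skewed DMR
#' responses seen in blood.
#'
#' @param nGenes number of genes.
#' @param replicatesPerCell replicates per (tissue, sex, age, exposure).
#' @param patternQuota named integer vector, pattern id ("1".."9") ->
#'   number of genes planted with that temporal pattern; must sum to
#'   <= nGenes (leftover genes default to the flat pattern 9).
#' @param baselineLog2Mean mean baseline log2 expression.
#' @param noiseSdLog2 Gaussian noise sd on log2 scale; 0 gives a
#'   noiseless fixture.
#' @param intervalEffectLog2 magnitude of a planted up/down step per age
#'   interval (log2 units).
#' @param nSexBiased number of sex-biased genes (split evenly male/female
#'   biased); `sexEffectLog2` their constant log2 offset (males relative
#'   to females), applied at all ages.
#' @param sexEffectLog2 see `nSexBiased`.
#' @param exposures character vector of exposure conditions to simulate
#'   (default: all nine registry conditions). Control is always present.
#' @param exposureEffects named list (exposure -> list) overriding, per
#'   exposure: `nDegSpecific`, `degLog2fc`, `nPatternSwitch`,
#'   `switchTarget` (pattern id, NA = random different pattern), and
#'   `feminization` (fraction of the sex-biased offset removed in exposed
#'   animals, 0 = none).
#' @param nDegShared size of the multi-response gene pool perturbed by
#'   every simulated exposure.
#' @param nRegions number of genomic regions (accessibility/methylation/
#'   segmentation units).
#' @param nDar planted differentially accessible regions per exposure;
#'   `darLog2fc` their effect; `darUpFraction` the fraction more
#'   accessible.
#' @param darLog2fc,darUpFraction see `nDar`.
#' @param nDmr planted differentially methylated regions per exposure;
#'   `dmrDeltaBeta` the absolute beta shift in (0,1); `dmrHypoFraction`
#'   the fraction shifted down; `betaNoiseSd` Gaussian beta noise sd.
#' @param dmrDeltaBeta,dmrHypoFraction,betaNoiseSd see `nDmr`.
#' @param nStateSwitch planted chromatin-state class switches (must be
#'   <= nRegions).
#' @param tissue tissue label of the cohort.
#' @param seed master RNG seed, recorded in the output manifest.
#' @return validated list of class `SimConfig`.
#' @export
simConfig <- function(nGenes = 2000,
                      replicatesPerCell = 5,
                      patternQuota = NULL,
                      baselineLog2Mean = 5,
                      noiseSdLog2 = 0.25,
                      intervalEffectLog2 = 2,
                      nSexBiased = 60,
                      sexEffectLog2 = 2,
                      exposures = exposureRegistry()$exposure,
                      exposureEffects = list(),
                      nDegShared = 90,
                      nRegions = 1000,
                      nDar = 100,
                      darLog2fc = 2,
                      darUpFraction = 0.5,
                      nDmr = 100,
                      dmrDeltaBeta = 0.3,
                      dmrHypoFraction = 0.9,
                      betaNoiseSd = 0.05,
                      nStateSwitch = 20,
                      tissue = "liver",
                      seed = 1) {
    if (is.null(patternQuota)) {
        per <- floor(nGenes * 0.075)   # 7.5% per changing pattern
        patternQuota <- c(rep(per, 8), nGenes - 8 * per)
        names(patternQuota) <- as.character(1:9)
    }
    if (!all(names(patternQuota) %in% as.character(1:9)))
        stop("patternQuota names must be pattern ids '1'..'9'")
    if (sum(patternQuota) > nGenes)
        stop("pattern quotas exceed nGenes")
    if (noiseSdLog2 < 0) stop("noiseSdLog2 must be >= 0")
    if (dmrDeltaBeta <= 0 || dmrDeltaBeta >= 1)
        stop("dmrDeltaBeta must lie in (0, 1)")
    if (nStateSwitch > nRegions)
        stop("nStateSwitch cannot exceed nRegions")
    bad <- setdiff(exposures, exposureRegistry()$exposure)
    if (length(bad))
        stop("unknown exposure(s): ", paste(bad, collapse = ", "))
    defaults <- list(nDegSpecific = 40, degLog2fc = 2, nPatternSwitch = 0,
                     switchTarget = NA_integer_, feminization = 0)
    eff <- lapply(exposures, function(e) {
        o <- exposureEffects[[e]]
        utils::modifyList(defaults, if (is.null(o)) list() else o)
    })
    names(eff) <- exposures
    for (e in exposures) {
        if (eff[[e]]$nDegSpecific < 0 || eff[[e]]$nPatternSwitch < 0)
            stop("exposure effect counts must be >= 0")
        if (eff[[e]]$feminization < 0 || eff[[e]]$feminization > 1)
            stop("feminization must lie in [0, 1]")
    }
    structure(list(nGenes = nGenes, replicatesPerCell = replicatesPerCell,
                   patternQuota = patternQuota,
                   baselineLog2Mean = baselineLog2Mean,
                   noiseSdLog2 = noiseSdLog2,
                   intervalEffectLog2 = intervalEffectLog2,
                   nSexBiased = nSexBiased, sexEffectLog2 = sexEffectLog2,
                   exposures = exposures, exposureEffects = eff,
                   nDegShared = nDegShared, nRegions = nRegions,
                   nDar = nDar, darLog2fc = darLog2fc,
                   darUpFraction = darUpFraction, nDmr = nDmr,
                   dmrDeltaBeta = dmrDeltaBeta,
                   dmrHypoFraction = dmrHypoFraction,
                   betaNoiseSd = betaNoiseSd, nStateSwitch = nStateSwitch,
                   tissue = tissue, seed = as.integer(seed)),
              class = "SimConfig")
}

## (d1, d2) step multipliers for each pattern id; columns s1, s2 hold
## -1/0/+1 factors on intervalEffectLog2 for the 3wk->5mo and 5mo->10mo
## intervals.
.patternSteps <- function() {
    dirs <- patternDirections()
    step <- c(up = 1, down = -1, flat = 0)
    cbind(s1 = step[dirs$d1], s2 = step[dirs$d2])
}

.sampleFrame <- function(config, tissue = config$tissue) {
    grid <- expand.grid(rep = seq_len(config$replicatesPerCell),
                        exposure = c("control", config$exposures),
                        age = ageLevels(), sex = sexLevels(),
                        stringsAsFactors = FALSE)
    data.frame(
        sample_id = sprintf("%s_%s_%s_%s_r%d", tissue, grid$sex, grid$age,
                            grid$exposure, grid$rep),
        tissue = tissue, sex = grid$sex, age = grid$age,
        exposure = grid$exposure,
        animal_id = sprintf("an_%s_%s_%s_r%d", grid$sex, grid$age,
                            grid$exposure, grid$rep),
        litter_id = sprintf("lit_%s_r%d", grid$exposure, grid$rep),
        stringsAsFactors = FALSE)
}

## Core log2-mean builder shared by expression and the paired blood cohort.
## Returns genes x samples matrix of noise-free log2 means.
.log2Means <- function(config, samples, truth) {
    steps <- .patternSteps()
    ageIdx <- match(samples$age, ageLevels())
    n <- config$nGenes
    genes <- truth$genes
    base <- truth$baselines
    M <- matrix(0, n, nrow(samples), dimnames = list(genes,
                                                     samples$sample_id))
    sexSign <- numeric(n)
    sexSign[match(truth$maleBiased, genes)] <- 1
    sexSign[match(truth$femaleBiased, genes)] <- -1
    for (j in seq_len(nrow(samples))) {
        expo <- samples$exposure[j]
        pat <- truth$patterns
        if (expo != "control") {
            sw <- truth$switchSets[[expo]]
            if (!is.null(sw) && nrow(sw))
                pat[match(sw$gene, genes)] <- sw$toPattern
        }
        s1 <- steps[pat, "s1"] * config$intervalEffectLog2
        s2 <- steps[pat, "s2"] * config$intervalEffectLog2
        ageEff <- switch(ageIdx[j], 0, s1, s1 + s2)
        sexEff <- if (samples$sex[j] == "M") sexSign * config$sexEffectLog2
                  else 0
        degEff <- numeric(n)
        if (expo != "control") {
            fem <- config$exposureEffects[[expo]]$feminization
            if (fem > 0 && samples$sex[j] == "M")
                sexEff <- sexEff * (1 - fem)
            ds <- truth$degSets[[expo]]
            if (!is.null(ds) && nrow(ds))
                degEff[match(ds$gene, genes)] <-
                    ifelse(ds$direction == "up", 1, -1) * ds$log2fc
        }
        M[, j] <- base + ageEff + sexEff + degEff
    }
    M
}

.plantTruth <- function(config) {
    n <- config$nGenes
    genes <- sprintf("gene%05d", seq_len(n))
    ## planted temporal patterns by quota; leftover genes are flat
    patterns <- rep(9L, n)
    pool <- sample(n)
    at <- 1L
    for (pid in names(config$patternQuota)) {
        k <- config$patternQuota[[pid]]
        if (k > 0) {
            patterns[pool[at:(at + k - 1L)]] <- as.integer(pid)
            at <- at + k
        }
    }
    baselines <- config$baselineLog2Mean + runif(n, -1, 1)
    ## sex-biased genes
    nsb <- config$nSexBiased
    sb <- sample(genes, nsb)
    maleBiased <- sb[seq_len(nsb %/% 2)]
    femaleBiased <- setdiff(sb, maleBiased)
    ## DEG structure: disjoint exposure-specific sets + one shared pool
    free <- setdiff(genes, sb)
    sharedPool <- sample(free, config$nDegShared)
    free <- setdiff(free, sharedPool)
    sharedDir <- sample(c("up", "down"), config$nDegShared, replace = TRUE)
    degSets <- list()
    switchSets <- list()
    for (e in config$exposures) {
        ee <- config$exposureEffects[[e]]
        spec <- if (ee$nDegSpecific > 0) sample(free, ee$nDegSpecific)
                else character()
        free <- setdiff(free, spec)
        degSets[[e]] <- data.frame(
            gene = c(spec, sharedPool),
            direction = c(sample(c("up", "down"), length(spec),
                                 replace = TRUE), sharedDir),
            log2fc = rep(ee$degLog2fc, length(spec) + length(sharedPool)),
            shared = c(rep(FALSE, length(spec)),
                       rep(TRUE, length(sharedPool))),
            stringsAsFactors = FALSE)
        if (ee$nPatternSwitch > 0) {
            swGenes <- sample(genes, ee$nPatternSwitch)
            from <- patterns[match(swGenes, genes)]
            to <- if (is.na(ee$switchTarget))
                vapply(from, function(f) sample(setdiff(1:9, f), 1L), 0L)
            else rep(as.integer(ee$switchTarget), length(swGenes))
            keep <- to != from
            switchSets[[e]] <- data.frame(gene = swGenes[keep],
                                          fromPattern = from[keep],
                                          toPattern = to[keep],
                                          stringsAsFactors = FALSE)
        }
    }
    list(genes = genes, patterns = patterns, baselines = baselines,
         maleBiased = maleBiased, femaleBiased = femaleBiased,
         degSets = degSets, sharedDegs = sharedPool,
         switchSets = switchSets)
}

#' Simulate a longitudinal expression cohort
#'
#' Generates an expression cohort over the full design (both sexes, three
#' ages, control plus the configured exposures, n replicates per cell).
#' The log2 expression of gene g in a sample is its baseline plus planted
#' pattern steps across the two age intervals, plus the sex offset for
#' sex-biased genes, plus the exposure effect for planted differential
#' genes, plus Gaussian noise; the stored matrix holds `2^value - 1`
#' (clamped at 0). Identical configurations (including seed) yield
#' identical output.
#'
#' @param config a [simConfig()] object.
#' @return list with elements `experiment` (an
#'   [ExposureExperiment-class]), `truth` (planted pattern ids, sex-biased
#'   sets, per-exposure DEG and pattern-switch tables, the shared DEG
#'   pool) and `manifest` (the configuration, seed included).
#' @examples
#' sim <- simulateCohort(simConfig(nGenes = 100, exposures = "As",
#'                                 replicatesPerCell = 3, seed = 7))
#' table(sim$truth$patterns)
#' @export
simulateCohort <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed + .streamOffsets[["expression"]])
    truth <- .plantTruth(config)
    samples <- .sampleFrame(config)
    M <- .log2Means(config, samples, truth)
    if (config$noiseSdLog2 > 0)
        M <- M + matrix(rnorm(length(M), 0, config$noiseSdLog2), nrow(M))
    vals <- pmax(2^M - 1, 0)
    list(experiment = ExposureExperiment(vals, samples), truth = truth,
         manifest = unclass(config))
}

#' Simulate a paired target/surrogate cohort
#'
#' Generates a liver (target) cohort from `config` plus a blood
#' (surrogate) cohort over the same genes in which, per exposure, a
#' configurable fraction of the liver DEGs is also planted in blood and a
#' configurable fraction of those shared genes keeps the liver direction
#' (the remainder is planted anticorrelated). Emulates the cross-tissue
#' concordance structure of target-vs-surrogate comparisons.
#'
#' @param config a [simConfig()].
#' @param bloodDetectableFraction fraction of each exposure's liver DEGs
#'   also differential in blood (default 0.4).
#' @param sameDirectionFraction fraction of the blood-detectable genes
#'   keeping the liver direction (default 0.9).
#' @return list with `liver`, `blood` (each as from [simulateCohort()])
#'   and `concordanceTruth` (per exposure: shared genes and their blood
#'   directions).
#' @export
simulatePairedTissues <- function(config, bloodDetectableFraction = 0.4,
                                  sameDirectionFraction = 0.9) {
    liver <- simulateCohort(config)
    set.seed(config$seed + .streamOffsets[["blood"]])
    bloodTruth <- liver$truth
    bloodTruth$switchSets <- list()        # temporal switches are hepatic
    conc <- list()
    for (e in config$exposures) {
        ds <- liver$truth$degSets[[e]]
        nDet <- round(nrow(ds) * bloodDetectableFraction)
        det <- ds[sample(nrow(ds), nDet), , drop = FALSE]
        nSame <- round(nDet * sameDirectionFraction)
        flip <- seq_len(nDet) > nSame      # sampled rows already random
        det$direction[flip] <- ifelse(det$direction[flip] == "up",
                                      "down", "up")
        bloodTruth$degSets[[e]] <- det
        conc[[e]] <- data.frame(gene = det$gene,
                                liverDirection = ds$direction[
                                    match(det$gene, ds$gene)],
                                bloodDirection = det$direction,
                                stringsAsFactors = FALSE)
    }
    samples <- .sampleFrame(config, tissue = "blood")
    M <- .log2Means(config, samples, bloodTruth)
    if (config$noiseSdLog2 > 0)
        M <- M + matrix(rnorm(length(M), 0, config$noiseSdLog2), nrow(M))
    vals <- pmax(2^M - 1, 0)
    blood <- list(experiment = ExposureExperiment(vals, samples),
                  truth = bloodTruth, manifest = unclass(config))
    list(liver = liver, blood = blood, concordanceTruth = conc)
}

.tileRegions <- function(nRegions, width = 1000L, gap = 1000L) {
    starts <- (seq_len(nRegions) - 1L) * (width + gap) + 1L
    gr <- GRanges("chr1", IRanges(starts, width = width))
    mcols(gr)$name <- sprintf("region%05d", seq_len(nRegions))
    names(gr) <- mcols(gr)$name
    gr
}

#' Simulate a region-level methylome
#'
#' Per-region beta values drawn around region baselines (uniform in
#' 0.35-0.65) with Gaussian noise, truncated to `[0, 1]`. Planted DMRs
#' shift the exposed-group mean by `dmrDeltaBeta`, hypomethylated with
#' probability `dmrHypoFraction`.
#'
#' @param config a [simConfig()].
#' @return list with `betas` (region x sample matrix), `regions`
#'   (GRanges), `samples` (sample table) and `truth` (per-exposure DMR
#'   tables with `hypo`/`hyper` directions).
#' @export
simulateMethylome <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed + .streamOffsets[["methylome"]])
    regions <- .tileRegions(config$nRegions)
    samples <- .sampleFrame(config)
    base <- runif(config$nRegions, 0.35, 0.65)
    dmrSets <- list()
    for (e in config$exposures) {
        idx <- sample(config$nRegions, config$nDmr)
        dirn <- ifelse(runif(config$nDmr) < config$dmrHypoFraction,
                       "hypo", "hyper")
        dmrSets[[e]] <- data.frame(region = names(regions)[idx],
                                   direction = dirn,
                                   deltaBeta = ifelse(dirn == "hypo", -1, 1) *
                                       config$dmrDeltaBeta,
                                   stringsAsFactors = FALSE)
    }
    B <- matrix(base, config$nRegions, nrow(samples),
                dimnames = list(names(regions), samples$sample_id))
    for (j in seq_len(nrow(samples))) {
        e <- samples$exposure[j]
        if (e != "control") {
            d <- dmrSets[[e]]
            B[match(d$region, names(regions)), j] <-
                B[match(d$region, names(regions)), j] + d$deltaBeta
        }
    }
    if (config$betaNoiseSd > 0)
        B <- B + matrix(rnorm(length(B), 0, config$betaNoiseSd), nrow(B))
    B <- pmin(pmax(B, 0), 1)
    list(betas = B, regions = regions, samples = samples,
         truth = list(dmrSets = dmrSets, baselines = base))
}

#' Simulate chromatin accessibility
#'
#' Region-by-sample signal with the same log-additive structure as
#' expression: per-region log2 baselines, planted differentially
#' accessible regions per exposure (more accessible with probability
#' `darUpFraction`), Gaussian log2 noise, values stored as `2^x - 1`.
#'
#' @param config a [simConfig()].
#' @return list with `signal` (region x sample matrix), `regions`,
#'   `samples` and `truth` (per-exposure DAR tables).
#' @export
simulateAccessibility <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed + .streamOffsets[["accessibility"]])
    regions <- .tileRegions(config$nRegions)
    samples <- .sampleFrame(config)
    base <- runif(config$nRegions, 3, 6)
    darSets <- list()
    for (e in config$exposures) {
        idx <- sample(config$nRegions, config$nDar)
        dirn <- ifelse(runif(config$nDar) < config$darUpFraction,
                       "up", "down")
        darSets[[e]] <- data.frame(region = names(regions)[idx],
                                   direction = dirn,
                                   log2fc = config$darLog2fc,
                                   stringsAsFactors = FALSE)
    }
    M <- matrix(base, config$nRegions, nrow(samples),
                dimnames = list(names(regions), samples$sample_id))
    for (j in seq_len(nrow(samples))) {
        e <- samples$exposure[j]
        if (e != "control") {
            d <- darSets[[e]]
            i <- match(d$region, names(regions))
            M[i, j] <- M[i, j] + ifelse(d$direction == "up", 1, -1) *
                d$log2fc
        }
    }
    if (config$noiseSdLog2 > 0)
        M <- M + matrix(rnorm(length(M), 0, config$noiseSdLog2), nrow(M))
    list(signal = pmax(2^M - 1, 0), regions = regions, samples = samples,
         truth = list(darSets = darSets))
}

#' Simulate a paired chromatin-state segmentation
#'
#' Builds a control segmentation tiling the synthetic genome with
#' ChromHMM-like state labels (three active, three inactive) and an
#' exposed segmentation identical except at `nStateSwitch` planted switch
#' regions, where the covering interval's state flips to a state of the
#' opposite class. Regions switching to active carry accessibility
#' direction `up`, to inactive `down`; non-switch regions get a random
#' direction.
#'
#' @param config a [simConfig()].
#' @return list with `control` and `exposed` ([ChromSegmentation-class]),
#'   `regions` (GRanges with a `direction` metadata column) and `truth`
#'   (switch region names, their from/to states and classes).
#' @export
simulateSegmentations <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed + .streamOffsets[["segmentation"]])
    activeStates <- c("TssA", "EnhA", "Tx")
    inactiveStates <- c("ReprPC", "Het", "Quies")
    stateClass <- c(structure(rep("active", 3), names = activeStates),
                    structure(rep("inactive", 3), names = inactiveStates))
    regions <- .tileRegions(config$nRegions)
    ## segmentation blocks: one 2kb block per region slot, covering the
    ## identical genomic extent in both conditions
    nBlocks <- config$nRegions
    blocks <- GRanges("chr1", IRanges((seq_len(nBlocks) - 1L) * 2000L + 1L,
                                      width = 2000L))
    ctrlStates <- sample(names(stateClass), nBlocks, replace = TRUE)
    expStates <- ctrlStates
    swIdx <- sample(nBlocks, config$nStateSwitch)
    for (i in swIdx) {
        opposite <- if (stateClass[[ctrlStates[i]]] == "active")
            inactiveStates else activeStates
        expStates[i] <- sample(opposite, 1L)
    }
    dirn <- sample(c("up", "down"), config$nRegions, replace = TRUE)
    dirn[swIdx] <- ifelse(stateClass[expStates[swIdx]] == "active",
                          "up", "down")
    mcols(regions)$direction <- dirn
    mk <- function(st) {
        gr <- blocks
        mcols(gr)$state <- st
        ChromSegmentation(gr, stateClass)
    }
    truth <- data.frame(region = names(regions)[swIdx],
                        fromState = ctrlStates[swIdx],
                        toState = expStates[swIdx],
                        fromClass = stateClass[ctrlStates[swIdx]],
                        toClass = stateClass[expStates[swIdx]],
                        stringsAsFactors = FALSE)
    list(control = mk(ctrlStates), exposed = mk(expStates),
         regions = regions, truth = truth)
}
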