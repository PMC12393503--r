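## Transcriptome embedding and the sex discrepancy score. The PCA basis
## is fit on controls only (one tissue, both sexes, all ages) and exposed
## samples are projected, so exposure displacement is measured in a basis
## the exposures themselves did not rotate. The score of a sample is its
## signed projection onto the female-to-male control-centroid axis of its
## age, divided by the centroid span: the female centroid scores exactly
## 0 and the male centroid exactly 1, at every age.

#' Fit a PCA embedding on control samples
#'
#' Principal components of log2(x+1)-transformed, gene-centered fit
#' samples. Column signs are fixed deterministically by making the
#' largest-magnitude loading of each component positive, so orientation
#' is reproducible across runs and platforms.
#'
#' @param x ExposureExperiment or genes x samples matrix.
#' @param fitSamples sample identifiers to fit on (controls of one
#'   tissue, both sexes, all ages); needs at least `nPc + 1` members.
#' @param nPc number of components to retain (must not exceed the rank).
#' @return An [EmbeddingModel-class].
#' @export
fitEmbedding <- function(x, fitSamples, nPc = 3) {
    vals <- exprValues(x)
    miss <- setdiff(fitSamples, colnames(vals))
    if (length(miss))
        stop("unknown fit sample(s): ", paste(miss, collapse = ", "))
    if (length(fitSamples) < nPc + 1)
        stop("need >= nPc + 1 fit samples")
    X <- log2(vals[, fitSamples, drop = FALSE] + 1)
    maxRank <- min(nrow(X), length(fitSamples) - 1L)
    if (nPc > maxRank)
        stop("nPc = ", nPc, " exceeds the rank bound ", maxRank)
    pc <- prcomp(t(X), center = TRUE, scale. = FALSE)
    L <- pc$rotation[, seq_len(nPc), drop = FALSE]
    flip <- vapply(seq_len(nPc), function(j)
        L[which.max(abs(L[, j])), j] < 0, TRUE)
    L[, flip] <- -L[, flip]
    ve <- pc$sdev^2 / sum(pc$sdev^2)
    new("EmbeddingModel", center = pc$center, loadings = L,
        varExplained = ve[seq_len(nPc)], fitSamples = fitSamples)
}

#' Project samples into a fitted embedding
#'
#' Coordinates are `(log2(x+1) - center) %*% loadings`; genes must match
#' the model (reordered by name when named).
#'
#' @param model an [EmbeddingModel-class].
#' @param x ExposureExperiment or matrix.
#' @param sampleIds samples to project (default: all columns).
#' @return samples x nPc coordinate matrix.
#' @export
projectSamples <- function(model, x, sampleIds = NULL) {
    vals <- exprValues(x)
    if (is.null(sampleIds)) sampleIds <- colnames(vals)
    genes <- rownames(model@loadings)
    if (!is.null(genes)) {
        if (!all(genes %in% rownames(vals)))
            stop("matrix is missing genes present in the embedding model")
        vals <- vals[genes, , drop = FALSE]
    } else if (nrow(vals) != nrow(model@loadings))
        stop("gene dimension does not match the embedding model")
    X <- log2(vals[, sampleIds, drop = FALSE] + 1)
    t(X - model@center) %*% model@loadings
}

#' Euclidean distance to an age-matched control centroid
#'
#' Per-sample Euclidean distance from the control centroid in the first
#' `nPcUsed` embedding coordinates (three by convention, matching a 3D
#' PCA view of exposure displacement).
#'
#' @param coords samples x nPc coordinate matrix.
#' @param controlCentroid centroid of the age- and sex-matched controls.
#' @param nPcUsed number of leading coordinates used (default 3).
#' @return named numeric vector of nonnegative distances.
#' @export
distanceToControl <- function(coords, controlCentroid, nPcUsed = 3) {
    if (!length(controlCentroid)) stop("empty control centroid")
    nPcUsed <- min(nPcUsed, ncol(coords))
    d2 <- sweep(coords[, seq_len(nPcUsed), drop = FALSE], 2,
                controlCentroid[seq_len(nPcUsed)])
    sqrt(rowSums(d2^2))
}

#' Control centroid in embedding space
#'
#' @param coords samples x nPc coordinate matrix (rownames = sample ids).
#' @param samples sample table.
#' @param age,sex,tissue design coordinates of the control group.
#' @return centroid coordinate vector.
#' @export
controlCentroid <- function(coords, samples, age, sex, tissue = "liver") {
    ids <- samples$sample_id[samples$tissue == tissue &
                             samples$sex == sex & samples$age == age &
                             samples$exposure == "control"]
    if (!length(ids)) stop("no control samples for that cell")
    colMeans(coords[ids, , drop = FALSE])
}

#' Female-to-male control axis at one age
#'
#' @param coords samples x nPc coordinates (rownames = sample ids).
#' @param samples sample table.
#' @param age age level of the axis.
#' @param tissue tissue of the controls.
#' @return A [SexAxis-class].
#' @export
sexAxis <- function(coords, samples, age, tissue = "liver") {
    ctrl <- samples[samples$tissue == tissue & samples$age == age &
                    samples$exposure == "control", , drop = FALSE]
    if (!all(sexLevels() %in% ctrl$sex))
        stop("both sexes' controls are required at age ", age)
    f <- colMeans(coords[ctrl$sample_id[ctrl$sex == "F"], , drop = FALSE])
    m <- colMeans(coords[ctrl$sample_id[ctrl$sex == "M"], , drop = FALSE])
    span <- sqrt(sum((m - f)^2))
    new("SexAxis", age = age, origin = f, direction = (m - f) / span,
        span = span)
}

#' Sex discrepancy score
#'
#' Signed scalar projection of each sample onto the female-to-male
#' control-centroid axis of its age, normalized by the centroid span.
#' Female control centroid scores 0, male control centroid 1; exposure
#' deviations below a sample's own-sex control mean indicate feminization
#' (for males) and above, masculinization.
#'
#' @param coords samples x nPc coordinates.
#' @param axis a [SexAxis-class].
#' @param unsigned if TRUE, return instead the Euclidean distance to the
#'   female centroid divided by the span (an unsigned variant).
#' @return named numeric vector of scores.
#' @export
sexDiscrepancyScore <- function(coords, axis, unsigned = FALSE) {
    d <- sweep(coords, 2, axis@origin)
    if (unsigned) return(sqrt(rowSums(d^2)) / axis@span)
    drop(d %*% axis@direction) / axis@span
}

#' Exposure-induced score deviation with permutation test
#'
#' `delta` is the mean exposed score minus the mean matched-control score
#' (same sex and age). The two-sided p-value comes from shuffling the
#' exposed/control labels; the add-one estimator keeps p in (0, 1].
#'
#' @param exposedScores,controlScores numeric score vectors.
#' @param nPerm number of permutations (>= 100; default 1000).
#' @param seed optional RNG seed for the permutations.
#' @return list with `delta`, `p`, `nPerm`.
#' @export
scoreDeviation <- function(exposedScores, controlScores, nPerm = 1000,
                           seed = NULL) {
    if (nPerm < 100) stop("nPerm must be >= 100")
    if (!length(exposedScores) || !length(controlScores))
        stop("both score groups must be non-empty")
    if (!is.null(seed)) set.seed(seed)
    delta <- mean(exposedScores) - mean(controlScores)
    pool <- c(exposedScores, controlScores)
    ne <- length(exposedScores)
    null <- vapply(seq_len(nPerm), function(i) {
        idx <- sample(length(pool), ne)
        mean(pool[idx]) - mean(pool[-idx])
    }, 0)
    p <- (1 + sum(abs(null) >= abs(delta))) / (nPerm + 1)
    list(delta = delta, p = p, nPerm = nPerm)
}

#' Sex-biased genes among controls
#'
#' Male-vs-female differential expression among control samples at one
#' age; male-biased genes are significantly higher in males, female-biased
#' significantly higher in females.
#'
#' @param x ExposureExperiment.
#' @param age age level.
#' @param tissue tissue of the controls.
#' @param qMax,effectMin thresholds as in [callDifferential()].
#' @return list with `maleBiased`, `femaleBiased` (character vectors) and
#'   `result` (the underlying [DifferentialResult-class], effect = male
#'   minus female).
#' @export
sexBiasedGenes <- function(x, age, tissue = "liver", qMax = 0.05,
                           effectMin = 1) {
    sd <- sampleData(x)
    pick <- function(sx)
        sd$sample_id[sd$tissue == tissue & sd$age == age &
                     sd$exposure == "control" & sd$sex == sx]
    stats <- twoGroupTest(x, pick("F"), pick("M"))
    res <- callDifferential(stats, qMax = qMax, effectMin = effectMin,
                            contrast = list(tissue = tissue, sex = "MvsF",
                                            age = age,
                                            exposure = "control"))
    tb <- resultTable(res)
    list(maleBiased = tb$feature[tb$significant & tb$effect > 0],
         femaleBiased = tb$feature[tb$significant & tb$effect < 0],
         result = res)
}

#' Feminization analysis of sex-biased genes
#'
#' For each sex-biased gene, tests its exposed-vs-control change within
#' one sex (default males) at one age and classifies it as
#' `toward_female` (significant change moving the exposed mean toward the
#' female control mean), `away_from_female` (significant change in the
#' opposite sense) or `unchanged`. Female-biased genes are handled
#' symmetrically: in males, a significant increase toward the (higher)
#' female mean is toward_female.
#'
#' @param sexBiased list with `maleBiased` and `femaleBiased` gene sets
#'   (as from [sexBiasedGenes()]).
#' @param x ExposureExperiment.
#' @param exposure exposure condition.
#' @param age age level.
#' @param sex sex analyzed (default "M").
#' @param tissue tissue.
#' @param qMax FDR ceiling for the per-gene change (default 0.05).
#' @return list with `table` (gene, bias, effect, q, class) and `counts`
#'   (toward_female, away_from_female, unchanged).
#' @export
feminizationAnalysis <- function(sexBiased, x, exposure, age, sex = "M",
                                 tissue = "liver", qMax = 0.05) {
    genes <- c(sexBiased$maleBiased, sexBiased$femaleBiased)
    if (!length(genes)) stop("empty sex-biased gene input")
    sd <- sampleData(x)
    vals <- exprValues(x)[genes, , drop = FALSE]
    pick <- function(sx, expo)
        sd$sample_id[sd$tissue == tissue & sd$age == age &
                     sd$sex == sx & sd$exposure == expo]
    stats <- twoGroupTest(vals, pick(sex, "control"), pick(sex, exposure))
    q <- bhAdjust(stats$p)
    otherSex <- setdiff(sexLevels(), sex)
    log2m <- function(ids) rowMeans(log2(vals[, ids, drop = FALSE] + 1))
    ownCtrl <- log2m(pick(sex, "control"))
    otherCtrl <- log2m(pick(otherSex, "control"))
    towardOther <- sign(otherCtrl - ownCtrl)   # direction toward the
    sig <- q < qMax                            # other sex's control mean
    ## class names are anchored to the opposite sex: toward_female /
    ## away_from_female when analyzing males, toward_male / away_from_male
    ## when analyzing females
    lbl <- if (sex == "M") c("toward_female", "away_from_female")
           else c("toward_male", "away_from_male")
    cls <- ifelse(!sig, "unchanged",
                  ifelse(sign(stats$effect) == towardOther, lbl[1], lbl[2]))
    tb <- data.frame(gene = stats$feature,
                     bias = ifelse(stats$feature %in% sexBiased$maleBiased,
                                   "male", "female"),
                     effect = stats$effect, q = q, class = cls,
                     stringsAsFactors = FALSE)
    lv <- c(lbl, "unchanged")
    list(table = tb, counts = table(factor(cls, levels = lv)))
}
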