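## Differential feature calling. Row-wise Welch unequal-variance t tests
## on log2(x + pseudocount) (expression/accessibility) or raw beta
## (methylation), BH adjustment per contrast, directionality summaries,
## exposure-signature decomposition and cross-tissue concordance.

#' Row-wise Welch two-group test
#'
#' For every feature (row), the effect is
#' `mean(transform(b)) - mean(transform(a))` with `transform` either
#' `log2(x + pseudocount)` or the identity (for beta values), and the
#' p-value comes from Welch's unequal-variance t test. Degenerate rows
#' (both groups zero-variance) get p = 1 when the means are equal and
#' p = 0 with `degenerate = TRUE` when they differ.
#'
#' @param x numeric matrix (features x samples) or ExposureExperiment.
#' @param groupA,groupB disjoint character vectors of sample identifiers;
#'   each must have at least `minReplicates` members. Effects are oriented
#'   B minus A.
#' @param pseudocount added before log2 (default 1); ignored on the
#'   identity scale.
#' @param scale `"log2"` or `"identity"`.
#' @param minReplicates minimum group size (default 3).
#' @return data.frame with columns feature, effect, p, degenerate.
#' @examples
#' m <- matrix(rpois(60, 20), 6,
#'             dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
#' twoGroupTest(m, paste0("s", 1:5), paste0("s", 6:10))
#' @export
twoGroupTest <- function(x, groupA, groupB, pseudocount = 1,
                         scale = c("log2", "identity"),
                         minReplicates = 3) {
    scale <- match.arg(scale)
    x <- exprValues(x)
    miss <- setdiff(c(groupA, groupB), colnames(x))
    if (length(miss))
        stop("unknown sample id(s): ", paste(miss, collapse = ", "))
    if (length(intersect(groupA, groupB)))
        stop("groups must be disjoint")
    if (length(groupA) < minReplicates || length(groupB) < minReplicates)
        stop("each group needs >= ", minReplicates, " samples")
    tf <- if (scale == "log2") function(v) log2(v + pseudocount) else
        identity
    A <- tf(x[, groupA, drop = FALSE])
    B <- tf(x[, groupB, drop = FALSE])
    na <- ncol(A); nb <- ncol(B)
    ma <- rowMeans(A); mb <- rowMeans(B)
    va <- rowSums((A - ma)^2) / (na - 1)
    vb <- rowSums((B - mb)^2) / (nb - 1)
    effect <- mb - ma
    se2 <- va / na + vb / nb
    tt <- effect / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * pt(-abs(tt), df)
    degen <- se2 == 0
    p[degen & effect == 0] <- 1
    p[degen & effect != 0] <- 0
    feats <- rownames(x)
    if (is.null(feats)) feats <- as.character(seq_len(nrow(x)))
    data.frame(feature = feats, effect = effect, p = p,
               degenerate = degen & effect != 0, row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values via `p.adjust(method = "BH")`, after a
#' domain check that all inputs lie in `[0, 1]`.
#'
#' @param pvals numeric vector of p-values.
#' @return q-values in `[0, 1]`, same order as input.
#' @export
bhAdjust <- function(pvals) {
    if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
        stop("p-values must lie in [0, 1]")
    p.adjust(pvals, method = "BH")
}

#' Call differential features for one contrast
#'
#' Attaches BH q-values, directions and significance flags to the output
#' of [twoGroupTest()]. A feature is significant iff `q < qMax` and
#' `|effect| >= effectMin`; direction follows the effect sign (`up`/`down`
#' for expression and accessibility, `hyper`/`hypo` for methylation).
#'
#' @param stats data.frame from [twoGroupTest()] over one contrast.
#' @param qMax FDR ceiling (default 0.05).
#' @param effectMin minimum absolute effect: 1.0 log2 units by convention
#'   for expression/accessibility, 0.1 delta-beta for methylation.
#' @param contrast named list describing the contrast.
#' @param type `"expression"`, `"accessibility"` or `"methylation"`.
#' @return A [DifferentialResult-class].
#' @export
callDifferential <- function(stats, qMax = 0.05,
                             effectMin = if (type == "methylation") 0.1
                                         else 1,
                             contrast = list(),
                             type = c("expression", "accessibility",
                                      "methylation")) {
    type <- match.arg(type)
    q <- bhAdjust(stats$p)
    up <- if (type == "methylation") "hyper" else "up"
    dn <- if (type == "methylation") "hypo" else "down"
    tb <- data.frame(feature = stats$feature, effect = stats$effect,
                     p = stats$p, q = q,
                     direction = ifelse(stats$effect > 0, up,
                                        ifelse(stats$effect < 0, dn, "none")),
                     significant = q < qMax & abs(stats$effect) >= effectMin,
                     degenerate = if (is.null(stats$degenerate)) FALSE
                                  else stats$degenerate,
                     stringsAsFactors = FALSE)
    new("DifferentialResult", contrast = contrast, table = tb,
        thresholds = list(qMax = qMax, effectMin = effectMin), type = type)
}

#' Contrast an exposure against its matched control
#'
#' Convenience wrapper selecting the (tissue, sex, age) cell's exposed and
#' control samples from an [ExposureExperiment-class] and running
#' [twoGroupTest()] + [callDifferential()].
#'
#' @param x an ExposureExperiment.
#' @param tissue,sex,age,exposure design coordinates of the contrast.
#' @param ... passed on to [callDifferential()] (`qMax`, `effectMin`,
#'   `type`).
#' @param pseudocount,scale,minReplicates passed to [twoGroupTest()].
#' @return A [DifferentialResult-class].
#' @export
exposureContrast <- function(x, tissue, sex, age, exposure,
                             pseudocount = 1, scale = "log2",
                             minReplicates = 3, ...) {
    sd <- sampleData(x)
    pick <- function(expo)
        sd$sample_id[sd$tissue == tissue & sd$sex == sex &
                     sd$age == age & sd$exposure == expo]
    stats <- twoGroupTest(x, pick("control"), pick(exposure),
                          pseudocount = pseudocount, scale = scale,
                          minReplicates = minReplicates)
    callDifferential(stats,
                     contrast = list(tissue = tissue, sex = sex, age = age,
                                     exposure = exposure), ...)
}

#' Directionality summary of significant features
#'
#' Fractions of up- versus down-regulated (or hyper- versus
#' hypomethylated) features among the significant features only; the two
#' fractions sum to one. With zero significant features the summary is
#' explicitly undefined rather than 0/0.
#'
#' @param result a [DifferentialResult-class].
#' @return list with `defined` (logical) and, when defined, the two
#'   fractions named `fraction_up`/`fraction_down` (or
#'   `fraction_hyper`/`fraction_hypo`) and `n_significant`.
#' @export
summarizeDirection <- function(result) {
    tb <- resultTable(result)
    sig <- tb[tb$significant, , drop = FALSE]
    up <- if (result@type == "methylation") "hyper" else "up"
    dn <- if (result@type == "methylation") "hypo" else "down"
    if (!nrow(sig))
        return(list(defined = FALSE))
    out <- list(defined = TRUE, n_significant = nrow(sig))
    out[[paste0("fraction_", up)]] <- mean(sig$direction == up)
    out[[paste0("fraction_", dn)]] <- mean(sig$direction == dn)
    out
}

#' Decompose per-exposure signatures into specific and multi-response sets
#'
#' A feature significant in exactly one exposure is exposure-specific; a
#' feature significant in two or more is multi-response. The two groups
#' partition the union of significant features.
#'
#' @param results named list (exposure -> [DifferentialResult-class]),
#'   all sharing tissue, sex and age.
#' @return A [SignatureDecomposition-class].
#' @export
decomposeSignatures <- function(results) {
    if (!length(results) || is.null(names(results)))
        stop("need a named list of DifferentialResult objects")
    meta <- lapply(results, function(r)
        contrastInfo(r)[c("tissue", "sex", "age")])
    if (length(unique(meta)) > 1L)
        stop("results mix tissue/sex/age; decomposition is within one cell")
    sigSets <- lapply(results, significantFeatures)
    counts <- table(unlist(sigSets, use.names = FALSE))
    specific <- lapply(sigSets, function(s)
        s[counts[s] == 1L])
    sharedIds <- names(counts)[counts >= 2L]
    shared <- lapply(sharedIds, function(f)
        names(results)[vapply(sigSets, function(s) f %in% s, TRUE)])
    names(shared) <- sharedIds
    new("SignatureDecomposition", specific = specific, shared = shared,
        union = as.character(names(counts)))
}

#' Multi-response fraction of a signature decomposition
#'
#' The fraction of the union of significant features that responds to two
#' or more exposures.
#'
#' @param decomp a [SignatureDecomposition-class].
#' @return a number in `[0, 1]`, or `NA` (with a warning) for an empty
#'   union.
#' @export
multiResponseFraction <- function(decomp) {
    if (!length(featureUnion(decomp))) {
        warning("empty feature union; multi-response fraction undefined")
        return(NA_real_)
    }
    length(sharedFeatures(decomp)) / length(featureUnion(decomp))
}

#' Cross-tissue concordance of differential genes
#'
#' Partitions the significant genes of a target-tissue (liver) and
#' surrogate-tissue (blood) result for the same sex, age and exposure by
#' joint significance and direction agreement: commonly increased,
#' commonly decreased, anticorrelated (significant in both, opposite
#' directions), or tissue-exclusive.
#'
#' @param liver,blood [DifferentialResult-class] objects of type
#'   `"expression"` for the same sex, age and exposure.
#' @return list of character vectors `common_up`, `common_down`,
#'   `anticorrelated`, `liver_only`, `blood_only`.
#' @export
crossTissueConcordance <- function(liver, blood) {
    if (liver@type != "expression" || blood@type != "expression")
        stop("cross-tissue concordance is defined for gene features only")
    keyL <- contrastInfo(liver)[c("sex", "age", "exposure")]
    keyB <- contrastInfo(blood)[c("sex", "age", "exposure")]
    if (length(keyL) && length(keyB) && !identical(keyL, keyB))
        stop("contrasts differ in sex/age/exposure")
    dirOf <- function(r) {
        tb <- resultTable(r)
        structure(tb$direction[tb$significant],
                  names = tb$feature[tb$significant])
    }
    dl <- dirOf(liver); db <- dirOf(blood)
    both <- intersect(names(dl), names(db))
    list(common_up = both[dl[both] == "up" & db[both] == "up"],
         common_down = both[dl[both] == "down" & db[both] == "down"],
         anticorrelated = both[dl[both] != db[both]],
         liver_only = setdiff(names(dl), names(db)),
         blood_only = setdiff(names(db), names(dl)))
}

#' Aggregate CpG methylation to region level
#'
#' Unweighted mean of the beta values of the CpGs contained in each
#' region. Regions containing fewer than `minCpg` CpGs are dropped with a
#' message.
#'
#' @param betas CpG x sample matrix of beta values.
#' @param cpgPositions GRanges of CpG sites, parallel to `betas` rows and
#'   sorted by position within chromosome.
#' @param regions GRanges of target regions with unique names.
#' @param minCpg minimum CpGs per retained region (default 3).
#' @return region x sample matrix of mean betas (retained regions only).
#' @export
regionLevelMethylation <- function(betas, cpgPositions, regions,
                                   minCpg = 3) {
    if (length(cpgPositions) != nrow(betas))
        stop("cpgPositions must parallel the rows of betas")
    bySeq <- split(start(cpgPositions), as.character(seqnames(cpgPositions)))
    if (any(vapply(bySeq, is.unsorted, TRUE)))
        stop("CpG positions must be sorted within chromosome")
    hits <- findOverlaps(cpgPositions, regions)
    byRegion <- split(S4Vectors::queryHits(hits),
                      S4Vectors::subjectHits(hits))
    nC <- lengths(byRegion)
    keep <- names(byRegion)[nC >= minCpg]
    dropped <- setdiff(as.character(seq_along(regions)), keep)
    if (length(dropped))
        message(length(dropped), " region(s) with < ", minCpg,
                " CpGs dropped")
    out <- do.call(rbind, lapply(byRegion[keep], function(i)
        colMeans(betas[i, , drop = FALSE])))
    dimnames(out) <- list(names(regions)[as.integer(keep)],
                          colnames(betas))
    out
}
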