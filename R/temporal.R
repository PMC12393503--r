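## Temporal trajectory classification over the three collection ages.
## A gene's trajectory is summarized by the direction of change (up, down,
## flat) over each of the two age intervals (3wk -> 5mo, 5mo -> 10mo); the
## nine direction pairs map bijectively onto pattern ids 1-9. Patterns
## 1, 6, 8 have net-decreasing and 2, 5, 7 net-increasing semantics;
## pattern 9 is flat throughout.

#' Canonical direction-pair to pattern-id mapping
#'
#' The fixed bijection between the nine (d1, d2) direction combinations
#' and pattern ids: 1 = (down, down), 2 = (up, up), 3 = (up, down),
#' 4 = (down, up), 5 = (up, flat), 6 = (down, flat), 7 = (flat, up),
#' 8 = (flat, down), 9 = (flat, flat). Net-decrease patterns are
#' \{1, 6, 8\}, net-increase \{2, 5, 7\}.
#'
#' @return data.frame with columns `pattern`, `d1`, `d2`.
#' @examples
#' patternDirections()
#' @export
patternDirections <- function() {
    data.frame(pattern = 1:9,
               d1 = c("down", "up", "up", "down", "up", "down", "flat",
                      "flat", "flat"),
               d2 = c("down", "up", "down", "up", "flat", "flat", "up",
                      "down", "flat"),
               stringsAsFactors = FALSE)
}

#' Map interval directions to a pattern id
#'
#' Vectorized total function applying the canonical bijection of
#' [patternDirections()].
#'
#' @param d1,d2 character vectors over \{"up", "down", "flat"\}: direction
#'   of change over the first (weaning to young adulthood) and second
#'   (young to later adulthood) age interval.
#' @return integer pattern ids in 1..9.
#' @examples
#' assignPattern("flat", "flat")   # 9
#' assignPattern("up", "down")     # 3
#' @export
assignPattern <- function(d1, d2) {
    ok <- c("up", "down", "flat")
    if (!all(d1 %in% ok) || !all(d2 %in% ok))
        stop("directions must be 'up', 'down' or 'flat'")
    map <- patternDirections()
    map$pattern[match(paste(d1, d2), paste(map$d1, map$d2))]
}

.conditionSamples <- function(samples, condition, age) {
    samples$sample_id[samples$tissue == condition$tissue &
                      samples$sex == condition$sex &
                      samples$exposure == condition$exposure &
                      samples$age == age]
}

#' Classify per-gene direction over one age interval
#'
#' Direction is `up` iff the interval log2 change passes both a BH-adjusted
#' significance test (q < `qMaxDir`, adjusted across genes within the
#' interval) and an effect floor (`effect >= effectMinDir`); `down`
#' symmetrically; `flat` otherwise. Coupling the test with an effect floor
#' keeps "flat" from collapsing into a pure sample-size artifact.
#'
#' @param x ExposureExperiment or matrix with design `samples`.
#' @param condition named list (tissue, sex, exposure).
#' @param agePair two age levels, younger first.
#' @param qMaxDir per-interval FDR ceiling (default 0.05).
#' @param effectMinDir minimum |log2 change| (default log2(1.5)).
#' @param samples sample table, required when `x` is a bare matrix.
#' @param pseudocount,minReplicates passed to [twoGroupTest()].
#' @return data.frame with columns gene, effect, q, direction.
#' @export
classifyIntervalDirection <- function(x, condition,
                                      agePair = c("3wk", "5mo"),
                                      qMaxDir = 0.05,
                                      effectMinDir = log2(1.5),
                                      samples = NULL, pseudocount = 1,
                                      minReplicates = 3) {
    if (is.null(samples)) samples <- sampleData(x)
    g1 <- .conditionSamples(samples, condition, agePair[1])
    g2 <- .conditionSamples(samples, condition, agePair[2])
    if (!length(g1) || !length(g2))
        stop("missing age group ", paste(agePair[!c(length(g1),
                                                    length(g2))],
                                         collapse = ", "),
             " for the requested condition")
    stats <- twoGroupTest(x, g1, g2, pseudocount = pseudocount,
                          minReplicates = minReplicates)
    q <- bhAdjust(stats$p)
    direction <- rep("flat", nrow(stats))
    direction[q < qMaxDir & stats$effect >= effectMinDir] <- "up"
    direction[q < qMaxDir & stats$effect <= -effectMinDir] <- "down"
    data.frame(gene = stats$feature, effect = stats$effect, q = q,
               direction = direction, stringsAsFactors = FALSE)
}

#' Classify temporal expression patterns for one condition
#'
#' Composes the two interval classifications and [assignPattern()] over
#' all three ages of one (tissue, sex, exposure) condition. Genes below
#' the expression floor (mean value < `exprFloor` at every age) are
#' marked unclassified, never defaulted to a pattern.
#'
#' @inheritParams classifyIntervalDirection
#' @param exprFloor RPKM-like floor (default 1).
#' @return A [PatternAssignment-class].
#' @examples
#' sim <- simulateCohort(simConfig(nGenes = 200, exposures = "As",
#'                                 replicatesPerCell = 3, seed = 2))
#' pa <- classifyPatterns(sim$experiment,
#'                        list(tissue = "liver", sex = "F",
#'                             exposure = "control"))
#' pa
#' @export
classifyPatterns <- function(x, condition, qMaxDir = 0.05,
                             effectMinDir = log2(1.5), exprFloor = 1,
                             samples = NULL, pseudocount = 1,
                             minReplicates = 3) {
    if (is.null(samples)) samples <- sampleData(x)
    vals <- exprValues(x)
    ageGroups <- lapply(ageLevels(), function(a)
        .conditionSamples(samples, condition, a))
    if (any(lengths(ageGroups) == 0))
        stop("all three ages are required; missing: ",
             paste(ageLevels()[lengths(ageGroups) == 0], collapse = ", "))
    i1 <- classifyIntervalDirection(vals, condition,
                                    agePair = ageLevels()[1:2],
                                    qMaxDir = qMaxDir,
                                    effectMinDir = effectMinDir,
                                    samples = samples,
                                    pseudocount = pseudocount,
                                    minReplicates = minReplicates)
    i2 <- classifyIntervalDirection(vals, condition,
                                    agePair = ageLevels()[2:3],
                                    qMaxDir = qMaxDir,
                                    effectMinDir = effectMinDir,
                                    samples = samples,
                                    pseudocount = pseudocount,
                                    minReplicates = minReplicates)
    ageMeans <- vapply(ageGroups, function(g)
        rowMeans(vals[, g, drop = FALSE]), numeric(nrow(vals)))
    classified <- apply(ageMeans >= exprFloor, 1L, any)
    pattern <- ifelse(classified, assignPattern(i1$direction,
                                                i2$direction),
                      NA_integer_)
    tb <- data.frame(gene = i1$gene,
                     d1 = i1$direction, d2 = i2$direction,
                     pattern = as.integer(pattern),
                     effect1 = i1$effect, q1 = i1$q,
                     effect2 = i2$effect, q2 = i2$q,
                     classified = classified, row.names = NULL,
                     stringsAsFactors = FALSE)
    new("PatternAssignment",
        condition = condition[c("tissue", "sex", "exposure")], table = tb)
}

.coClassified <- function(control, exposed) {
    if (!identical(conditionInfo(control)[c("tissue", "sex")],
                   conditionInfo(exposed)[c("tissue", "sex")]))
        stop("control and exposed assignments must share tissue and sex")
    tc <- patternTable(control); te <- patternTable(exposed)
    genes <- intersect(tc$gene[tc$classified], te$gene[te$classified])
    if (!length(genes))
        stop("no co-classified genes between control and exposed")
    data.frame(gene = genes,
               control = tc$pattern[match(genes, tc$gene)],
               exposed = te$pattern[match(genes, te$gene)],
               stringsAsFactors = FALSE)
}

#' Per-pattern disruption summary
#'
#' A gene is disrupted iff its exposed-condition pattern differs from its
#' control pattern; percentages are computed within each control pattern
#' over the co-classified gene universe.
#'
#' @param control,exposed [PatternAssignment-class] objects for the same
#'   tissue and sex.
#' @return list with `perPattern` (data.frame: pattern, nGenes,
#'   nDisrupted, percentDisrupted) and `overall` (the same three numbers
#'   over all co-classified genes).
#' @export
disruptionSummary <- function(control, exposed) {
    cc <- .coClassified(control, exposed)
    disrupted <- cc$control != cc$exposed
    per <- data.frame(pattern = 1:9,
                      nGenes = as.integer(table(factor(cc$control, 1:9))),
                      nDisrupted = as.integer(
                          table(factor(cc$control[disrupted], 1:9))))
    per$percentDisrupted <- ifelse(per$nGenes > 0,
                                   100 * per$nDisrupted / per$nGenes, NA)
    list(perPattern = per,
         overall = list(nGenes = nrow(cc), nDisrupted = sum(disrupted),
                        percentDisrupted = 100 * mean(disrupted)))
}

#' Pattern transition matrix
#'
#' 9 x 9 count matrix of control pattern (rows) against exposed pattern
#' (columns) over the co-classified genes; the diagonal holds undisrupted
#' genes and row sums equal the per-pattern gene counts.
#'
#' @inheritParams disruptionSummary
#' @return integer matrix with dimnames `P1..P9`.
#' @export
transitionMatrix <- function(control, exposed) {
    cc <- .coClassified(control, exposed)
    m <- table(factor(cc$control, 1:9), factor(cc$exposed, 1:9))
    m <- matrix(as.integer(m), 9, 9,
                dimnames = list(control = paste0("P", 1:9),
                                exposed = paste0("P", 1:9)))
    m
}

#' Genes disrupted across multiple exposures
#'
#' Counts, per gene, the number of exposures under which its temporal
#' pattern differs from control, and returns the genes disrupted in at
#' least `k` exposures together with the per-count histogram.
#'
#' @param assignments named list (exposure -> [PatternAssignment-class]).
#' @param control the control [PatternAssignment-class].
#' @param k minimum number of disrupting exposures (>= 1).
#' @return list with `genes` (disrupted in >= k exposures), `counts`
#'   (named integer vector, per gene) and `histogram` (table of counts).
#' @export
multiExposureDisruption <- function(assignments, control, k = 4) {
    if (k < 1) stop("k must be >= 1")
    if (length(assignments) < k)
        stop("need at least k = ", k, " exposure assignments")
    tc <- patternTable(control)
    counts <- integer(0)
    for (a in assignments) {
        cc <- .coClassified(control, a)
        dis <- cc$gene[cc$control != cc$exposed]
        counts[dis] <- ifelse(is.na(counts[dis]), 0L, counts[dis]) + 1L
    }
    names(counts) -> gn
    list(genes = gn[counts >= k], counts = counts,
         histogram = table(disruptingExposures = counts))
}

#' Cross-sex intersection of disrupted gene sets
#'
#' @param female,male gene identifier vectors (e.g. the `genes` element
#'   of [multiExposureDisruption()] run per sex).
#' @return character vector of genes disrupted in both sexes.
#' @export
crossSexIntersection <- function(female, male) intersect(female, male)
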