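#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @import SummarizedExperiment
#' @importFrom stats prcomp pt phyper p.adjust rnorm runif
#' @importFrom utils read.delim write.table modifyList
NULL

## Enumerated design domains. Age is an ordered factor everywhere;
## the order is fixed here, never inferred from the strings.

#' Design factor domains
#'
#' The fixed categorical domains of the longitudinal exposure design:
#' two tissues (target liver, surrogate blood), two sexes, three collection
#' ages (weaning at 3 weeks, young adulthood at 5 months, later adulthood
#' at 10 months) and the vehicle control plus nine exposure conditions.
#'
#' @return Character vector of the allowed level names, in canonical order.
#' @examples
#' ageLevels()
#' exposureLevels()
#' @export
ageLevels <- function() c("3wk", "5mo", "10mo")

#' @rdname ageLevels
#' @export
tissueLevels <- function() c("liver", "blood")

#' @rdname ageLevels
#' @export
sexLevels <- function() c("F", "M")

#' @rdname ageLevels
#' @export
exposureLevels <- function() c("control", exposureRegistry()$exposure)

#' Canonical exposure registry
#'
#' The nine exposure conditions of the study design: seven toxicants, with
#' bisphenol A carried at two doses and concentrated ambient particulate
#' matter produced by two collection sites, each with its administration
#' route and dose text.
#'
#' @return A data.frame with columns `exposure` (condition name used in
#'   sample tables), `toxicant`, `route` and `dose`.
#' @examples
#' exposureRegistry()
#' @export
exposureRegistry <- function() {
    data.frame(
        exposure = c("As", "BPA10ug", "BPA10mg", "DEHP", "Pb",
                     "PM25_CHI", "PM25_JHU", "TBT", "TCDD"),
        toxicant = c("arsenic", "bisphenol A", "bisphenol A",
                     "di-2-ethylhexyl phthalate", "lead",
                     "particulate matter <2.5um",
                     "particulate matter <2.5um", "tributyltin",
                     "tetrachlorodibenzo-p-dioxin"),
        route = c("drinking water", "chow food", "chow food", "chow food",
                  "drinking water", "air inhalation", "air inhalation",
                  "drinking water", "oral gavage"),
        dose = c("10 ug/L q.o.d.", "10 ug/kg bw/day", "10 mg/kg bw/day",
                 "25 mg/kg", "32 ppm", "135 ug/m3, 40 h/week",
                 "150 ug/m3, 40 h/week", "0.5 mg/kg bw/day", "1 ug/kg"),
        stringsAsFactors = FALSE
    )
}

## ---------------------------------------------------------------------------
## ExposureExperiment: expression-like values + validated design metadata
## ---------------------------------------------------------------------------

#' ExposureExperiment: assay values plus validated design factors
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay holds
#' nonnegative expression-like values (RPKM-like for RNA, signal for
#' accessibility, beta fractions for methylation) and whose `colData`
#' carries the seven design columns `sample_id`, `tissue`, `sex`, `age`,
#' `exposure`, `animal_id`, `litter_id`, each validated against the
#' enumerated domains ([ageLevels()] and friends).
#'
#' @slot .. inherited from SummarizedExperiment.
#' @export
setClass("ExposureExperiment", contains = "SummarizedExperiment")

.designColumns <- c("sample_id", "tissue", "sex", "age", "exposure",
                    "animal_id", "litter_id")

.validSampleData <- function(df) {
    missing <- setdiff(.designColumns, colnames(df))
    if (length(missing))
        return(sprintf("missing sample column(s): %s",
                       paste(missing, collapse = ", ")))
    if (anyDuplicated(df$sample_id))
        return("duplicated sample_id values")
    checks <- list(tissue = tissueLevels(), sex = sexLevels(),
                   age = ageLevels(), exposure = exposureLevels())
    for (col in names(checks)) {
        vals <- as.character(df[[col]])
        bad <- setdiff(unique(vals), checks[[col]])
        if (length(bad))
            return(sprintf("invalid %s value(s) %s; allowed: %s", col,
                           paste(sQuote(bad), collapse = ", "),
                           paste(checks[[col]], collapse = ", ")))
    }
    TRUE
}

setValidity("ExposureExperiment", function(object) {
    msgs <- character()
    v <- assay(object)
    if (anyNA(v) || !is.numeric(v))
        msgs <- c(msgs, "assay values must be numeric and non-missing")
    else if (any(v < 0))
        msgs <- c(msgs, "assay values must be nonnegative")
    if (anyDuplicated(rownames(object)))
        msgs <- c(msgs, "duplicated feature identifiers")
    ok <- .validSampleData(as.data.frame(colData(object)))
    if (!isTRUE(ok)) msgs <- c(msgs, ok)
    if (length(msgs)) msgs else TRUE
})

#' Construct an ExposureExperiment
#'
#' @param values numeric matrix, features x samples, nonnegative, with
#'   feature identifiers as rownames and sample identifiers as colnames.
#' @param sampleData data.frame with the seven design columns; rows are
#'   matched to `colnames(values)` by `sample_id`.
#' @return A validated [ExposureExperiment-class] object.
#' @examples
#' sim <- simulateCohort(simConfig(nGenes = 50, exposures = "As",
#'                                 replicatesPerCell = 3, seed = 1))
#' sim$experiment
#' @export
ExposureExperiment <- function(values, sampleData) {
    if (is.null(rownames(values)) || is.null(colnames(values)))
        stop("'values' needs feature rownames and sample colnames")
    sampleData <- as.data.frame(sampleData)
    idx <- match(colnames(values), sampleData$sample_id)
    if (anyNA(idx))
        stop("sample_id missing from sampleData for: ",
             paste(colnames(values)[is.na(idx)], collapse = ", "))
    sampleData <- sampleData[idx, , drop = FALSE]
    cd <- DataFrame(sampleData, row.names = sampleData$sample_id)
    cd$age <- factor(as.character(cd$age), levels = ageLevels(),
                     ordered = TRUE)
    new("ExposureExperiment",
        SummarizedExperiment(assays = list(values = values), colData = cd))
}

#' Design metadata of an ExposureExperiment
#'
#' @param x an ExposureExperiment.
#' @return `sampleData()`: the design columns as a plain data.frame;
#'   `exprValues()`: the assay matrix.
#' @export
sampleData <- function(x) as.data.frame(colData(x))

#' @rdname sampleData
#' @export
exprValues <- function(x) {
    if (is(x, "SummarizedExperiment")) assay(x) else x
}

## ---------------------------------------------------------------------------
## ChromSegmentation
## ---------------------------------------------------------------------------

#' Chromatin-state segmentation
#'
#' Non-overlapping genome intervals labelled with chromatin-state names
#' (e.g. a ChromHMM segmentation), together with a map from every state
#' label to an `active`/`inactive` class used for switch counting.
#'
#' @slot states a `GRanges` with metadata column `state`.
#' @slot stateClass named character vector mapping each state label to
#'   `"active"` or `"inactive"`.
#' @export
setClass("ChromSegmentation",
         representation(states = "GRanges", stateClass = "character"))

setValidity("ChromSegmentation", function(object) {
    msgs <- character()
    gr <- object@states
    if (is.null(mcols(gr)$state))
        msgs <- c(msgs, "states GRanges needs a 'state' metadata column")
    else {
        unmapped <- setdiff(unique(mcols(gr)$state), names(object@stateClass))
        if (length(unmapped))
            msgs <- c(msgs, sprintf("state label(s) absent from class map: %s",
                                    paste(unmapped, collapse = ", ")))
    }
    if (!all(object@stateClass %in% c("active", "inactive")))
        msgs <- c(msgs, "state classes must be 'active' or 'inactive'")
    hits <- findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
    if (length(hits))
        msgs <- c(msgs, "segmentation intervals overlap within a chromosome")
    if (length(msgs)) msgs else TRUE
})

#' @rdname ChromSegmentation-class
#' @param states GRanges with a `state` metadata column.
#' @param stateClass named character, state label -> "active"/"inactive".
#' @export
ChromSegmentation <- function(states, stateClass) {
    new("ChromSegmentation", states = states, stateClass = stateClass)
}

setMethod("show", "ChromSegmentation", function(object) {
    cat("ChromSegmentation with", length(object@states), "intervals,",
        length(unique(mcols(object@states)$state)), "states (",
        sum(object@stateClass == "active"), "active /",
        sum(object@stateClass == "inactive"), "inactive labels )\n")
})

#' Accessors for ChromSegmentation
#' @param x a ChromSegmentation.
#' @return `segStates()`: the labelled GRanges; `stateClassMap()`: the
#'   named class vector.
#' @export
segStates <- function(x) x@states

#' @rdname segStates
#' @export
stateClassMap <- function(x) x@stateClass

## ---------------------------------------------------------------------------
## GeneSetCollection (GMT)
## ---------------------------------------------------------------------------

#' Gene set collection
#'
#' Named gene sets with free-text descriptions, as carried by GMT files.
#' Used as the annotation input of over-representation analysis.
#'
#' @slot sets named list of character vectors (gene identifiers).
#' @slot descriptions named character vector, parallel to `sets`.
#' @export
setClass("GeneSetCollection",
         representation(sets = "list", descriptions = "character"))

setValidity("GeneSetCollection", function(object) {
    msgs <- character()
    if (anyDuplicated(names(object@sets)))
        msgs <- c(msgs, "duplicated set names")
    if (any(lengths(object@sets) == 0))
        msgs <- c(msgs, "empty gene sets are not allowed")
    if (!identical(names(object@sets), names(object@descriptions)))
        msgs <- c(msgs, "descriptions must parallel sets")
    if (length(msgs)) msgs else TRUE
})

#' @rdname GeneSetCollection-class
#' @param sets named list of character vectors.
#' @param descriptions optional named character vector of descriptions.
#' @export
GeneSetCollection <- function(sets, descriptions = NULL) {
    if (is.null(descriptions)) {
        descriptions <- rep("", length(sets))
        names(descriptions) <- names(sets)
    }
    new("GeneSetCollection", sets = sets, descriptions = descriptions)
}

setMethod("show", "GeneSetCollection", function(object) {
    cat("GeneSetCollection with", length(object@sets), "sets; sizes",
        paste(range(lengths(object@sets)), collapse = "-"), "\n")
})

#' @rdname GeneSetCollection-class
#' @param x a GeneSetCollection.
#' @export
geneSets <- function(x) x@sets

#' @rdname GeneSetCollection-class
#' @export
setDescriptions <- function(x) x@descriptions

## ---------------------------------------------------------------------------
## DifferentialResult
## ---------------------------------------------------------------------------

#' Differential test result for one contrast
#'
#' Per-feature effect sizes (log2 fold change for expression/accessibility,
#' delta-beta for methylation), Welch p-values, BH-adjusted q-values,
#' directions and significance flags for a single exposure-vs-control (or
#' male-vs-female) contrast.
#'
#' @slot contrast named list describing the contrast (tissue, sex, age,
#'   exposure, ...).
#' @slot table data.frame with columns feature, effect, p, q, direction,
#'   significant, degenerate.
#' @slot thresholds list with `qMax` and `effectMin`.
#' @slot type `"expression"`, `"accessibility"` or `"methylation"`.
#' @export
setClass("DifferentialResult",
         representation(contrast = "list", table = "data.frame",
                        thresholds = "list", type = "character"))

setValidity("DifferentialResult", function(object) {
    tb <- object@table
    need <- c("feature", "effect", "p", "q", "direction", "significant")
    if (!all(need %in% colnames(tb)))
        return(sprintf("table must have columns: %s",
                       paste(need, collapse = ", ")))
    if (nrow(tb)) {
        if (any(tb$q < 0 | tb$q > 1, na.rm = TRUE))
            return("q-values outside [0, 1]")
        sig <- tb$significant
        if (any(sig & (tb$q >= object@thresholds$qMax |
                       abs(tb$effect) < object@thresholds$effectMin)))
            return("significance flags inconsistent with thresholds")
        up <- if (object@type == "methylation") "hyper" else "up"
        dn <- if (object@type == "methylation") "hypo" else "down"
        bad <- (tb$effect > 0 & tb$direction == dn) |
               (tb$effect < 0 & tb$direction == up)
        if (any(bad)) return("direction inconsistent with effect sign")
    }
    TRUE
})

setMethod("show", "DifferentialResult", function(object) {
    tb <- object@table
    cat(sprintf("DifferentialResult [%s] %s: %d features, %d significant (%d %s / %d %s) at q<%g, |effect|>=%g\n",
                object@type,
                paste(unlist(object@contrast), collapse = "/"),
                nrow(tb), sum(tb$significant),
                sum(tb$significant & tb$effect > 0),
                if (object@type == "methylation") "hyper" else "up",
                sum(tb$significant & tb$effect < 0),
                if (object@type == "methylation") "hypo" else "down",
                object@thresholds$qMax, object@thresholds$effectMin))
})

#' @rdname DifferentialResult-class
#' @param x a DifferentialResult.
#' @return `resultTable()`: the per-feature data.frame;
#'   `significantFeatures()`: identifiers of significant features;
#'   `contrastInfo()`: the contrast descriptor list.
#' @export
resultTable <- function(x) x@table

#' @rdname DifferentialResult-class
#' @export
significantFeatures <- function(x) x@table$feature[x@table$significant]

#' @rdname DifferentialResult-class
#' @export
contrastInfo <- function(x) x@contrast

## ---------------------------------------------------------------------------
## SignatureDecomposition
## ---------------------------------------------------------------------------

#' Exposure-signature decomposition
#'
#' Partition of the union of significant features across exposures into
#' exposure-specific sets (significant in exactly one exposure) and a
#' multi-response map (feature -> the >= 2 exposures sharing it).
#'
#' @slot specific named list (exposure -> character vector of features).
#' @slot shared named list (feature -> character vector of exposures).
#' @slot union character vector, all significant features.
#' @export
setClass("SignatureDecomposition",
         representation(specific = "list", shared = "list",
                        union = "character"))

setValidity("SignatureDecomposition", function(object) {
    spec <- unlist(object@specific, use.names = FALSE)
    shared <- names(object@shared)
    if (length(intersect(spec, shared)))
        return("specific and shared sets must be disjoint")
    if (!setequal(c(spec, shared), object@union))
        return("specific + shared must partition the union")
    if (any(lengths(object@shared) < 2))
        return("shared features must belong to >= 2 exposures")
    TRUE
})

setMethod("show", "SignatureDecomposition", function(object) {
    cat(sprintf("SignatureDecomposition: %d features (%d specific, %d multi-response) across %d exposures\n",
                length(object@union),
                sum(lengths(object@specific)), length(object@shared),
                length(object@specific)))
})

#' @rdname SignatureDecomposition-class
#' @param x a SignatureDecomposition.
#' @export
specificSets <- function(x) x@specific

#' @rdname SignatureDecomposition-class
#' @export
sharedFeatures <- function(x) x@shared

#' @rdname SignatureDecomposition-class
#' @export
featureUnion <- function(x) x@union

## ---------------------------------------------------------------------------
## PatternAssignment
## ---------------------------------------------------------------------------

#' Temporal pattern assignment for one condition
#'
#' Per-gene interval directions over the two age intervals (weaning to
#' young adulthood, young to later adulthood) and the derived pattern id
#' 1-9 for one (tissue, sex, exposure) condition. Genes failing the
#' expression floor are retained with `classified = FALSE` and NA pattern.
#'
#' @slot condition named list (tissue, sex, exposure).
#' @slot table data.frame with columns gene, d1, d2, pattern, effect1, q1,
#'   effect2, q2, classified.
#' @export
setClass("PatternAssignment",
         representation(condition = "list", table = "data.frame"))

setValidity("PatternAssignment", function(object) {
    tb <- object@table
    need <- c("gene", "d1", "d2", "pattern", "classified")
    if (!all(need %in% colnames(tb)))
        return(sprintf("table must have columns: %s",
                       paste(need, collapse = ", ")))
    cls <- tb$classified
    if (any(cls & (is.na(tb$pattern) | !(tb$pattern %in% 1:9))))
        return("classified genes must carry a pattern id in 1..9")
    if (any(!cls & !is.na(tb$pattern)))
        return("unclassified genes must have NA pattern, not a default")
    TRUE
})

setMethod("show", "PatternAssignment", function(object) {
    tb <- object@table
    cat(sprintf("PatternAssignment %s: %d genes, %d classified\n",
                paste(unlist(object@condition), collapse = "/"),
                nrow(tb), sum(tb$classified)))
    if (any(tb$classified))
        print(table(pattern = tb$pattern[tb$classified]))
})

#' @rdname PatternAssignment-class
#' @param x a PatternAssignment.
#' @export
patternTable <- function(x) x@table

#' @rdname PatternAssignment-class
#' @export
conditionInfo <- function(x) x@condition

## ---------------------------------------------------------------------------
## EmbeddingModel / SexAxis
## ---------------------------------------------------------------------------

#' PCA embedding model
#'
#' Principal-component basis fit on log2(x+1)-transformed control samples.
#' Exposed samples are projected into this basis rather than refit, so the
#' basis is not rotated by the exposures being measured.
#'
#' @slot center named numeric, per-gene centering vector (log2 scale).
#' @slot loadings genes x nPc orthonormal loading matrix, column signs
#'   fixed by the largest-magnitude-loading-positive rule.
#' @slot varExplained fraction of variance per retained component.
#' @slot fitSamples sample identifiers the basis was fit on.
#' @export
setClass("EmbeddingModel",
         representation(center = "numeric", loadings = "matrix",
                        varExplained = "numeric", fitSamples = "character"))

setValidity("EmbeddingModel", function(object) {
    L <- object@loadings
    if (nrow(L) != length(object@center))
        return("center length must match loading rows")
    ctc <- crossprod(L)
    if (max(abs(ctc - diag(ncol(L)))) > 1e-8)
        return("loading columns must be orthonormal")
    ve <- object@varExplained
    if (any(diff(ve) > 1e-12) || sum(ve) > 1 + 1e-8)
        return("explained-variance fractions must be non-increasing, sum <= 1")
    TRUE
})

setMethod("show", "EmbeddingModel", function(object) {
    cat(sprintf("EmbeddingModel: %d genes, %d components (%.1f%% variance), fit on %d samples\n",
                nrow(object@loadings), ncol(object@loadings),
                100 * sum(object@varExplained), length(object@fitSamples)))
})

#' Sex axis in embedding space
#'
#' The female-to-male control-centroid axis at one age: origin at the
#' female control centroid, unit direction toward the male control
#' centroid, and the centroid span in embedding units. Sex discrepancy
#' scores are signed projections onto this axis divided by the span, so
#' the female centroid scores 0 and the male centroid scores 1.
#'
#' @slot age the age level the axis belongs to.
#' @slot origin female control centroid coordinates.
#' @slot direction unit vector from female toward male centroid.
#' @slot span distance between the two centroids.
#' @export
setClass("SexAxis",
         representation(age = "character", origin = "numeric",
                        direction = "numeric", span = "numeric"))

setValidity("SexAxis", function(object) {
    if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-8)
        return("direction must be a unit vector")
    if (object@span <= 0) return("span must be positive")
    TRUE
})

setMethod("show", "SexAxis", function(object) {
    cat(sprintf("SexAxis at %s: span %.3f over %d dimensions\n",
                object@age, object@span, length(object@direction)))
})
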