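## Readers and writers for the canonical file dialects: TSV matrices and
## sample tables, BED4/BED5 region sets, BED4 segmentations with a
## two-column state->class map, GMT gene-set collections. BED files keep
## BED (0-based half-open) semantics on disk; in memory regions live in
## GRanges (1-based) as everywhere in Bioconductor.

#' Read an expression-like matrix from TSV
#'
#' The canonical matrix dialect: tab-separated, a header row of sample
#' identifiers, first column `feature` holding feature identifiers, all
#' remaining cells nonnegative numbers (RPKM-like values, accessibility
#' signal, or methylation fractions).
#'
#' @param path file path.
#' @return numeric matrix with feature rownames and sample colnames.
#' @seealso [writeExpressionMatrix()], [ExposureExperiment()]
#' @export
readExpressionMatrix <- function(path) {
    first <- readLines(path, n = 1L)
    if (length(first) == 0L || !nzchar(first))
        stop("empty file: missing header row of sample identifiers in ",
             path)
    df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
        stop("matrix TSV needs a feature column plus >= 1 sample column")
    features <- as.character(df[[1L]])
    if (anyDuplicated(features))
        stop("duplicated feature identifier(s): ",
             paste(unique(features[duplicated(features)]), collapse = ", "))
    samples <- colnames(df)[-1L]
    if (anyDuplicated(samples))
        stop("duplicated sample identifier(s) in header")
    vals <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(vals) || anyNA(vals))
        stop("non-numeric or missing cell(s) in expression matrix")
    if (any(vals < 0))
        stop("negative value(s) in expression matrix; values must be >= 0")
    dimnames(vals) <- list(features, samples)
    vals
}

#' @rdname readExpressionMatrix
#' @param x numeric matrix with dimnames.
#' @export
writeExpressionMatrix <- function(x, path) {
    df <- data.frame(feature = rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read and validate a sample table
#'
#' Tab-separated with the seven design columns `sample_id`, `tissue`,
#' `sex`, `age`, `exposure`, `animal_id`, `litter_id`. Categorical values
#' are validated against the enumerated domains; an unknown level is a
#' domain error listing the allowed values.
#'
#' @param path file path.
#' @return data.frame of the seven columns (all character).
#' @export
readSampleTable <- function(path) {
    df <- read.delim(path, header = TRUE, sep = "\t",
                     colClasses = "character", check.names = FALSE)
    ok <- .validSampleData(df)
    if (!isTRUE(ok)) stop(ok)
    df[, .designColumns]
}

#' @rdname readSampleTable
#' @param x sample table data.frame.
#' @export
writeSampleTable <- function(x, path) {
    write.table(x[, .designColumns], path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Read a BED region set
#'
#' BED4/BED5 (chrom, 0-based start, end, name, optional score) via
#' `rtracklayer`. Region names must be unique within a set.
#'
#' @param path BED file path.
#' @return GRanges with `name` (and possibly `score`) metadata columns.
#' @export
readRegions <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    if (is.null(mcols(gr)$name) || anyNA(mcols(gr)$name))
        stop("BED region set needs a name in column 4")
    if (anyDuplicated(mcols(gr)$name))
        stop("duplicated region name(s): ",
             paste(unique(mcols(gr)$name[duplicated(mcols(gr)$name)]),
                   collapse = ", "))
    names(gr) <- mcols(gr)$name
    gr
}

#' @rdname readRegions
#' @param gr GRanges with a `name` metadata column (optionally `score`).
#' @export
writeRegions <- function(gr, path) {
    ## rtracklayer::export pads BED4 to BED6; format the lines directly so
    ## written files round-trip byte-identically.
    fields <- list(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                   mcols(gr)$name)
    if (!is.null(mcols(gr)$score)) fields <- c(fields, list(mcols(gr)$score))
    writeLines(do.call(paste, c(fields, sep = "\t")), path)
    invisible(path)
}

#' Read a chromatin-state segmentation
#'
#' BED4 whose name column carries chromatin-state labels, plus a
#' two-column headerless TSV mapping every state label to `active` or
#' `inactive`. Intervals must be non-overlapping within a chromosome and
#' every state label present in the class map.
#'
#' @param path segmentation BED path.
#' @param classMapPath state->class TSV path.
#' @return A [ChromSegmentation-class].
#' @export
readSegmentation <- function(path, classMapPath) {
    gr <- rtracklayer::import(path, format = "BED")
    if (is.null(mcols(gr)$name))
        stop("segmentation BED needs state labels in column 4")
    mcols(gr)$state <- mcols(gr)$name
    mcols(gr)$name <- NULL
    cm <- read.delim(classMapPath, header = FALSE, sep = "\t",
                     colClasses = "character")
    if (ncol(cm) < 2L) stop("class map needs two columns: state, class")
    stateClass <- structure(cm[[2L]], names = cm[[1L]])
    ChromSegmentation(gr, stateClass)
}

#' @rdname readSegmentation
#' @param seg a ChromSegmentation.
#' @export
writeSegmentation <- function(seg, path, classMapPath) {
    gr <- segStates(seg)
    writeLines(paste(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                     mcols(gr)$state, sep = "\t"), path)
    writeLines(paste(names(stateClassMap(seg)), stateClassMap(seg),
                     sep = "\t"), classMapPath)
    invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then member gene identifiers,
#' tab-separated. Set names must be unique and sets non-empty.
#'
#' @param path GMT file path.
#' @return A [GeneSetCollection-class].
#' @export
readGeneSets <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) < 3L))
        stop("GMT line with fewer than 3 fields (name, description, genes)")
    nm <- vapply(parts, `[[`, "", 1L)
    if (anyDuplicated(nm))
        stop("duplicated gene-set name(s): ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
    sets <- lapply(parts, function(p) p[-(1:2)])
    names(sets) <- nm
    desc <- vapply(parts, `[[`, "", 2L)
    names(desc) <- nm
    GeneSetCollection(sets, desc)
}

#' @rdname readGeneSets
#' @param gsc a GeneSetCollection.
#' @export
writeGeneSets <- function(gsc, path) {
    nm <- names(geneSets(gsc))
    writeLines(vapply(nm, function(n) {
        paste(c(n, setDescriptions(gsc)[[n]], geneSets(gsc)[[n]]),
              collapse = "\t")
    }, ""), path)
    invisible(path)
}

#' Summarize replicate coverage of a design
#'
#' Enumerates every (tissue, sex, age, exposure) cell over the tissues
#' present in the table and the full sex/age/exposure domains, reporting
#' the replicate count and a status: `ok`, `underpowered` (below
#' `minReplicates`) or `absent`. Reporting only; the input is never
#' modified.
#'
#' @param samples sample table data.frame (or ExposureExperiment).
#' @param minReplicates minimum replicates per analyzed cell (default 3).
#' @return data.frame with columns tissue, sex, age, exposure, n, status.
#' @export
validateDesign <- function(samples, minReplicates = 3) {
    if (is(samples, "SummarizedExperiment")) samples <- sampleData(samples)
    if (!nrow(samples)) stop("empty sample table")
    cells <- expand.grid(tissue = unique(samples$tissue), sex = sexLevels(),
                         age = ageLevels(), exposure = exposureLevels(),
                         stringsAsFactors = FALSE)
    key <- function(d) paste(d$tissue, d$sex, d$age, d$exposure, sep = "|")
    counts <- table(key(samples))
    cells$n <- as.integer(counts[key(cells)])
    cells$n[is.na(cells$n)] <- 0L
    cells$status <- ifelse(cells$n == 0L, "absent",
                           ifelse(cells$n < minReplicates, "underpowered",
                                  "ok"))
    cells[order(cells$tissue, cells$sex, match(cells$age, ageLevels()),
                cells$exposure), , drop = FALSE]
}
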