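## Chromatin-state switch annotation. Each differential region is assigned
## the state covering the largest number of its bases in each of the two
## segmentations (ties broken by the state covering the leftmost
## overlapped base); a region switches when the labels differ and
## class-switches when the active/inactive classes differ.

#' Majority chromatin state of regions
#'
#' For each region, the segmentation state with the largest overlapped
#' base count; ties are broken by the state covering the leftmost
#' overlapped base. Regions overlapping no interval get `NA`
#' ("unannotated") rather than being dropped.
#'
#' @param regions GRanges of regions.
#' @param segmentation a [ChromSegmentation-class].
#' @return character vector of state labels, parallel to `regions`, with
#'   `NA` for unannotated regions.
#' @export
majorityState <- function(regions, segmentation) {
    seg <- segStates(segmentation)
    hits <- findOverlaps(regions, seg)
    out <- rep(NA_character_, length(regions))
    if (!length(hits)) return(out)
    ov <- pintersect(regions[S4Vectors::queryHits(hits)],
                     seg[S4Vectors::subjectHits(hits)])
    q <- S4Vectors::queryHits(hits)
    w <- width(ov)
    st <- mcols(seg)$state[S4Vectors::subjectHits(hits)]
    ## widest overlap first; among ties, the leftmost overlapped base wins
    o <- order(q, -w, start(ov))
    first <- !duplicated(q[o])
    out[q[o][first]] <- st[o][first]
    out
}

#' Chromatin-state switch table and summary
#'
#' Annotates each region with its majority state in the control and
#' exposed segmentations and summarizes switching: a label change is a
#' switch; an active/inactive class change is a class switch (label-only
#' changes within a class are reported but not counted as class
#' switches). Among regions gaining accessibility ("up") the fraction
#' switching to active chromatin is reported, and symmetrically for
#' "down" regions; unannotated regions are counted separately, never
#' silently dropped.
#'
#' @param regions GRanges with a `direction` metadata column
#'   (`up`/`down`) and unique names.
#' @param segControl,segExposed [ChromSegmentation-class] objects sharing
#'   one state->class map.
#' @return list with `records` (per-region data.frame: region,
#'   controlState, exposedState, controlClass, exposedClass, direction,
#'   switched, classSwitched) and `summary` (nRegions, nAnnotated,
#'   nUnannotated, nSwitched, nClassSwitched, fractionToActiveAmongUp,
#'   fractionToInactiveAmongDown).
#' @export
stateSwitchTable <- function(regions, segControl, segExposed) {
    cmC <- stateClassMap(segControl)
    cmE <- stateClassMap(segExposed)
    if (!identical(cmC[order(names(cmC))], cmE[order(names(cmE))]))
        stop("the two segmentations must share the state->class map")
    dirn <- mcols(regions)$direction
    if (is.null(dirn))
        stop("regions need a 'direction' metadata column (up/down)")
    sC <- majorityState(regions, segControl)
    sE <- majorityState(regions, segExposed)
    annotated <- !is.na(sC) & !is.na(sE)
    clC <- unname(cmC[sC])
    clE <- unname(cmC[sE])
    switched <- annotated & sC != sE
    classSwitched <- annotated & clC != clE
    rec <- data.frame(region = if (!is.null(names(regions))) names(regions)
                               else as.character(seq_along(regions)),
                      controlState = sC, exposedState = sE,
                      controlClass = clC, exposedClass = clE,
                      direction = dirn, switched = switched,
                      classSwitched = classSwitched,
                      stringsAsFactors = FALSE)
    toActive <- classSwitched & clE == "active"
    toInactive <- classSwitched & clE == "inactive"
    upAnn <- annotated & dirn == "up"
    dnAnn <- annotated & dirn == "down"
    list(records = rec,
         summary = list(
             nRegions = length(regions),
             nAnnotated = sum(annotated),
             nUnannotated = sum(!annotated),
             nSwitched = sum(switched),
             nClassSwitched = sum(classSwitched),
             fractionToActiveAmongUp =
                 if (sum(upAnn)) sum(toActive & upAnn) / sum(upAnn)
                 else NA_real_,
             fractionToInactiveAmongDown =
                 if (sum(dnAnn)) sum(toInactive & dnAnn) / sum(dnAnn)
                 else NA_real_))
}
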