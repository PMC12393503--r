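## Hypergeometric over-representation analysis of gene sets against a
## user-supplied GMT collection, conditioned on an explicit universe.

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for X hypergeometric: `k` of the `n` drawn genes fall in a
#' set of `K` among a universe of `N`. Computed via `phyper`, which works
#' on log scale internally, so small tails are stable.
#'
#' @param k overlap count.
#' @param K set size within the universe.
#' @param n query size.
#' @param N universe size.
#' @return upper-tail probability in (0, 1].
#' @examples
#' hypergeomTail(5, 5, 5, 10)  # 1 / choose(10, 5)
#' @export
hypergeomTail <- function(k, K, n, N) {
    if (any(k < 0 | K < 0 | n < 0 | N < 0) || any(k > pmin(K, n)) ||
        any(K > N) || any(n > N))
        stop("inconsistent counts: need 0 <= k <= min(K, n) <= N")
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis
#'
#' One-sided hypergeometric enrichment of a query gene set against every
#' collection set, conditioned on an explicit universe (conventionally
#' the classified/testable genes of the upstream analysis, not the whole
#' genome). Collection sets are intersected with the universe before
#' testing; sets smaller than `minSetSize` after intersection are
#' skipped. BH adjustment is applied across the tested sets.
#'
#' @param query character vector of genes; must be a subset of
#'   `universe`.
#' @param universe character vector of testable genes.
#' @param collection a [GeneSetCollection-class].
#' @param qMax FDR ceiling used for the `enriched` flag (default 0.05).
#' @param minSetSize minimum in-universe set size (default 5).
#' @return data.frame sorted by p with columns set, description, k, K, n,
#'   N, p, q, enriched, overlapGenes (comma-separated).
#' @export
ora <- function(query, universe, collection, qMax = 0.05, minSetSize = 5) {
    query <- unique(query)
    universe <- unique(universe)
    out <- setdiff(query, universe)
    if (length(out))
        stop("query gene(s) outside the universe: ",
             paste(head(out, 10), collapse = ", "))
    sets <- lapply(geneSets(collection), intersect, y = universe)
    keep <- lengths(sets) >= minSetSize
    sets <- sets[keep]
    if (!length(sets))
        return(data.frame(set = character(), description = character(),
                          k = integer(), K = integer(), n = integer(),
                          N = integer(), p = numeric(), q = numeric(),
                          enriched = logical(),
                          overlapGenes = character()))
    N <- length(universe)
    n <- length(query)
    K <- lengths(sets)
    overlaps <- lapply(sets, intersect, y = query)
    k <- lengths(overlaps)
    p <- hypergeomTail(k, K, n, N)
    q <- bhAdjust(p)
    res <- data.frame(set = names(sets),
                      description = setDescriptions(collection)[names(sets)],
                      k = k, K = K, n = n, N = N, p = p, q = q,
                      enriched = q < qMax,
                      overlapGenes = vapply(overlaps, paste, "",
                                            collapse = ","),
                      row.names = NULL, stringsAsFactors = FALSE)
    res[order(res$p, res$set), , drop = FALSE]
}
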