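# Consensus meta-analysis across screens: cumulative -log10 p ranking and
# set-overlap summaries.

.pFloor <- 1e-300   # applied before any -log transform

#' Consensus ranking of terms across several enrichment reports
#'
#' Builds the term x screen matrix of \eqn{-\log_{10} p} scores (raw p by
#' default, floored at 1e-300), sums each term's scores across screens and
#' ranks terms by the cumulative score — the procedure used to pool
#' independent screens that share a mechanism despite low hit overlap. A
#' term missing from a screen's report contributes 0, equivalent to p = 1:
#' absence of evidence adds nothing to the sum. Ties in the cumulative
#' score are broken by the number of screens with p < 0.05, then term.
#'
#' @param reports named list of [EnrichmentReport-class] objects (names =
#'   screen labels), or a list of \code{list(label=, report=)} pairs.
#'   Mixed term vocabularies take the union.
#' @param topK number of top terms retained (default 20).
#' @param useQ score -log10 of the BH-adjusted values instead of raw p.
#' @param significanceMask zero out contributions with p (or q) above this
#'   threshold before summing; \code{NULL} (default) sums all terms.
#' @return a [ConsensusTable-class] with at most \code{topK} rows, ordered
#'   by rank.
#' @export
consensusScores <- function(reports, topK = 20L, useQ = FALSE,
                            significanceMask = NULL) {
    if (topK < 1L) stop("domain error: topK must be >= 1")
    if (length(reports) == 0L) stop("at least one report is required")
    labels <- names(reports)
    if (is.null(labels) || any(!nzchar(labels)))
        stop("reports must be a named list (screen labels)")
    if (anyDuplicated(labels)) stop("duplicate screen labels")

    terms <- sort(unique(unlist(lapply(reports,
        function(r) r@results$term), use.names = FALSE)))
    scores <- matrix(0, length(terms), length(reports),
        dimnames = list(terms, labels))
    pmat <- matrix(1, length(terms), length(reports),
        dimnames = list(terms, labels))
    for (s in labels) {
        res <- reports[[s]]@results
        p <- if (useQ) res$q_value else res$p_value
        if (!is.null(significanceMask)) p[p > significanceMask] <- 1
        pmat[res$term, s] <- p
        scores[res$term, s] <- -log10(pmax(p, .pFloor))
    }

    cumulative <- rowSums(scores)
    nSig <- rowSums(pmat < 0.05)
    ord <- order(-cumulative, -nSig, terms, method = "radix")
    keep <- utils::head(ord, topK)
    scores <- scores[keep, , drop = FALSE]
    cumulative <- cumulative[keep]
    rnk <- as.integer(match(cumulative, sort(unique(cumulative),
        decreasing = TRUE)))
    new("ConsensusTable", scores = scores, cumulative = cumulative,
        rank = rnk)
}

#' Pairwise and exclusive-region overlap of labeled drug sets
#'
#' Summarizes the overlap structure of several hit lists: per-set sizes,
#' all pairwise intersection sizes, and the count of members in every
#' exclusive intersection pattern (the regions an UpSet plot displays).
#'
#' @param drugSets named list (>= 2 elements) of character vectors.
#' @return list with \code{sizes} (named integer), \code{pairwise}
#'   (symmetric matrix of intersection sizes; diagonal = set sizes),
#'   \code{exclusive} (data.frame \code{pattern} — \code{&}-joined labels —
#'   and \code{count}), and \code{jaccard} (pairwise Jaccard matrix).
#' @examples
#' overlapMatrix(list(s1 = c("A", "B"), s2 = c("B", "C")))
#' @export
overlapMatrix <- function(drugSets) {
    stopifnot(is.list(drugSets), length(drugSets) >= 2L)
    labels <- names(drugSets)
    if (is.null(labels) || any(!nzchar(labels)))
        stop("drug sets must be labeled")
    if (anyDuplicated(labels)) stop("duplicate set labels")
    drugSets <- lapply(drugSets, function(s) unique(as.character(s)))

    sizes <- vapply(drugSets, length, integer(1))
    k <- length(drugSets)
    pairwise <- matrix(0L, k, k, dimnames = list(labels, labels))
    jaccard <- matrix(1, k, k, dimnames = list(labels, labels))
    for (i in seq_len(k)) for (j in seq_len(k)) {
        inter <- length(intersect(drugSets[[i]], drugSets[[j]]))
        pairwise[i, j] <- inter
        uni <- length(union(drugSets[[i]], drugSets[[j]]))
        jaccard[i, j] <- if (uni == 0L) 1 else inter / uni
    }

    members <- unique(unlist(drugSets, use.names = FALSE))
    membership <- vapply(drugSets, function(s) members %in% s,
        logical(length(members)))
    if (length(members) == 1L) membership <- matrix(membership, nrow = 1L)
    pattern <- apply(membership, 1L, function(row)
        paste(labels[row], collapse = "&"))
    tab <- table(pattern)
    exclusive <- data.frame(pattern = names(tab),
        count = as.integer(tab), stringsAsFactors = FALSE)
    exclusive <- exclusive[order(-exclusive$count, exclusive$pattern), ,
        drop = FALSE]
    rownames(exclusive) <- NULL

    list(sizes = sizes, pairwise = pairwise, exclusive = exclusive,
        jaccard = jaccard)
}

#' Export per-screen score contributions in long format
#'
#' Writes one row per (term, screen) for the terms of a consensus table —
#' the layout a stacked bar chart of per-screen contributions is drawn
#' from. Per-term sums of the exported scores equal the cumulative scores.
#'
#' @param tbl a [ConsensusTable-class].
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
exportStackedContributions <- function(tbl, path) {
    stopifnot(is(tbl, "ConsensusTable"))
    sc <- tbl@scores
    df <- data.frame(
        term = rep(rownames(sc), times = ncol(sc)),
        screen = rep(colnames(sc), each = nrow(sc)),
        score = as.vector(sc),
        stringsAsFactors = FALSE)
    ord <- order(match(df$term, rownames(sc)), match(df$screen, colnames(sc)))
    df <- df[ord, , drop = FALSE]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
        row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}
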