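# Construction of drug set libraries from fingerprint bits and from
# per-drug gene-expression signatures.

#' Build a drug set library from fingerprint bits
#'
#' Molecules sharing a set bit share the structural feature that bit
#' encodes, so every bit position yields one candidate drug set (the rows
#' with that bit set). Candidate sets smaller than \code{minSize} are then
#' dropped, mirroring the minimum-set-size rule applied to all libraries.
#' The universe is the full list of successfully fingerprinted tokens.
#'
#' @param fp a [FingerprintMatrix-class].
#' @param keyLabels optional character vector of length \code{nBits} with
#'   human-readable key names; defaults to the fingerprint's column labels
#'   (\code{maccs_<k>} / \code{morgan_<k>} / \code{bit_<k>}).
#' @param minSize minimum members per retained set (default 5).
#' @param name library name.
#' @return a [DrugSetLibrary-class].
#' @examples
#' fp <- customFingerprints(matrix(c(1, 1, 1, 0, 0, 1), ncol = 2,
#'     dimnames = list(c("r1", "r2", "r3"), NULL)))
#' fingerprintLibrary(fp, minSize = 2)
#' @export
fingerprintLibrary <- function(fp, keyLabels = NULL, minSize = 5L,
                               name = fp@dictionaryName) {
    stopifnot(is(fp, "FingerprintMatrix"))
    if (is.null(keyLabels)) {
        keyLabels <- colnames(fp@bits)
        if (is.null(keyLabels))
            keyLabels <- sprintf("bit_%d", seq_len(fp@nBits) - 1L)
    }
    if (length(keyLabels) != fp@nBits)
        stop("keyLabels must have one label per bit position")
    sets <- list()
    for (j in seq_len(fp@nBits)) {
        members <- fp@rowKeys[fp@bits[, j] == 1]
        if (length(members)) sets[[keyLabels[j]]] <- members
    }
    lib <- DrugSetLibrary(sets, name = name, universe = fp@rowKeys)
    filterMinSize(lib, minSize)
}

#' Build up/down signature-derived libraries (GO/pathway style)
#'
#' For each drug, its chosen-direction gene set is tested for enrichment
#' against every term gene set with the one-sided Fisher's exact test over
#' the gene universe; the p-values are BH-adjusted across terms within
#' that drug's query (the query being the unit of correction). Term–drug
#' pairs with \code{q <= qThreshold} are inverted into term -> drug sets,
#' and the minimum-set-size rule is applied. Up and down libraries come
#' from separate calls, matching the separate querying of the two
#' directions.
#'
#' @param sigs a [SignatureCollection-class].
#' @param termGeneSets named list of gene-symbol vectors (term -> genes),
#'   or a [DrugSetLibrary-class] read from a gene GMT.
#' @param geneUniverse character vector of all assayable gene symbols;
#'   must cover every gene appearing in the term sets.
#' @param direction \code{"up"} or \code{"down"}.
#' @param qThreshold BH-adjusted significance cutoff (default 0.01).
#' @param minSize minimum drugs per retained term set (default 5).
#' @param name library name.
#' @return a [DrugSetLibrary-class] whose universe is all drugs in
#'   \code{sigs}. Drugs with an empty direction set are skipped with a
#'   warning.
#' @export
signatureLibrary <- function(sigs, termGeneSets, geneUniverse,
                             direction = c("up", "down"),
                             qThreshold = 0.01, minSize = 5L,
                             name = paste0("signature_", direction[1L])) {
    stopifnot(is(sigs, "SignatureCollection"))
    direction <- match.arg(direction)
    if (is(termGeneSets, "DrugSetLibrary")) termGeneSets <- termGeneSets@sets
    termGeneSets <- lapply(termGeneSets, function(g) unique(toupper(g)))
    geneUniverse <- unique(toupper(as.character(geneUniverse)))
    allTermGenes <- unique(unlist(termGeneSets, use.names = FALSE))
    if (!all(allTermGenes %in% geneUniverse))
        stop("gene universe must cover every gene in the term sets")
    N <- length(geneUniverse)

    perDrug <- signatureGenes(sigs, direction)
    drugs <- union(names(sigs@up), names(sigs@down))
    termDrugs <- stats::setNames(vector("list", length(termGeneSets)),
        names(termGeneSets))
    for (drug in drugs) {
        genes <- intersect(perDrug[[drug]], geneUniverse)
        if (length(genes) == 0L) {
            warning(sprintf("drug '%s' has an empty %s set; skipped",
                drug, direction))
            next
        }
        a <- vapply(termGeneSets, function(ts) length(intersect(genes, ts)), 0L)
        k <- vapply(termGeneSets, length, 0L)
        p <- fisherExactGreater(a, length(genes) - a, k - a,
            N - length(genes) - k + a)
        q <- bhAdjust(p)
        pass <- which(q <= qThreshold & a > 0L)
        for (ti in pass)
            termDrugs[[ti]] <- c(termDrugs[[ti]], drug)
    }
    termDrugs <- termDrugs[vapply(termDrugs, length, 0L) > 0L]
    lib <- DrugSetLibrary(termDrugs, name = name, universe = drugs)
    filterMinSize(lib, minSize)
}
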