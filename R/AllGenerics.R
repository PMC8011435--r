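# Generics, accessors and show methods for the S4 containers.

#' @rdname DrugSetLibrary-class
#' @param x,object a DrugSetLibrary.
#' @export
setGeneric("nSets", function(x) standardGeneric("nSets"))

#' @rdname DrugSetLibrary-class
#' @export
setGeneric("setTerms", function(x) standardGeneric("setTerms"))

#' @rdname DrugSetLibrary-class
#' @param term optional term; when given, returns that set's members.
#' @export
setGeneric("setMembers", function(x, term) standardGeneric("setMembers"))

#' @rdname DrugSetLibrary-class
#' @export
setGeneric("setSizes", function(x) standardGeneric("setSizes"))

#' @rdname DrugSetLibrary-class
#' @export
setGeneric("drugUniverse", function(x) standardGeneric("drugUniverse"))

#' @rdname DrugSetLibrary-class
#' @export
setGeneric("libraryName", function(x) standardGeneric("libraryName"))

#' @rdname DrugSetLibrary-class
#' @export
setGeneric("setDescriptions", function(x) standardGeneric("setDescriptions"))

setMethod("nSets", "DrugSetLibrary", function(x) length(x@sets))
setMethod("setTerms", "DrugSetLibrary", function(x) names(x@sets))
setMethod("setMembers", "DrugSetLibrary", function(x, term) {
    if (missing(term)) return(x@sets)
    if (!term %in% names(x@sets)) stop(sprintf("no set with term '%s'", term))
    x@sets[[term]]
})
setMethod("setSizes", "DrugSetLibrary",
    function(x) vapply(x@sets, length, integer(1)))
setMethod("drugUniverse", "DrugSetLibrary", function(x) x@universe)
setMethod("libraryName", "DrugSetLibrary", function(x) x@name)
setMethod("setDescriptions", "DrugSetLibrary",
    function(x) stats::setNames(x@descriptions, names(x@sets)))

#' @rdname DrugSetLibrary-class
#' @export
setMethod("length", "DrugSetLibrary", function(x) length(x@sets))

#' Subset a library by term or position (universe is kept unchanged)
#' @rdname DrugSetLibrary-class
#' @param i term names, positions or a logical mask.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "DrugSetLibrary", function(x, i, j, ..., drop = FALSE) {
    idx <- if (is.character(i)) match(i, names(x@sets)) else seq_along(x@sets)[i]
    if (anyNA(idx)) stop("unknown term in subset")
    new("DrugSetLibrary", name = x@name, sets = x@sets[idx],
        descriptions = x@descriptions[idx], universe = x@universe)
})

setMethod("show", "DrugSetLibrary", function(object) {
    cat(sprintf("DrugSetLibrary '%s': %d set(s), universe of %d token(s)\n",
        object@name, length(object@sets), length(object@universe)))
    if (length(object@sets)) {
        sz <- vapply(object@sets, length, integer(1))
        cat(sprintf("  set sizes: min %d, median %s, max %d\n",
            min(sz), format(stats::median(sz)), max(sz)))
        shown <- utils::head(names(object@sets), 5L)
        cat("  terms: ", paste(shown, collapse = ", "),
            if (length(object@sets) > 5L) ", ..." else "", "\n", sep = "")
    }
})

#' @rdname DrugMetadataTable-class
#' @param x,object a DrugMetadataTable.
#' @export
setGeneric("entityRecords", function(x) standardGeneric("entityRecords"))
setMethod("entityRecords", "DrugMetadataTable", function(x) x@records)

#' @rdname DrugMetadataTable-class
#' @export
setGeneric("entitySynonyms", function(x) standardGeneric("entitySynonyms"))
setMethod("entitySynonyms", "DrugMetadataTable", function(x) x@synonyms)

setMethod("length", "DrugMetadataTable", function(x) nrow(x@records))

setMethod("show", "DrugMetadataTable", function(object) {
    cat(sprintf("DrugMetadataTable: %d record(s)\n", nrow(object@records)))
    cat(sprintf("  with InChIKey: %d; with SMILES: %d\n",
        sum(nzchar(object@records$inchikey)),
        sum(nzchar(object@records$smiles))))
    if (length(object@xrefs))
        cat("  xref namespaces: ", paste(names(object@xrefs), collapse = ", "),
            "\n", sep = "")
})

#' @rdname ResolutionReport-class
#' @param x,object a ResolutionReport.
#' @export
setGeneric("matchedTokens", function(x) standardGeneric("matchedTokens"))
setMethod("matchedTokens", "ResolutionReport", function(x) x@matched)

#' @rdname ResolutionReport-class
#' @export
setGeneric("unmatchedTokens", function(x) standardGeneric("unmatchedTokens"))
setMethod("unmatchedTokens", "ResolutionReport", function(x) x@unmatched)

#' @rdname ResolutionReport-class
#' @export
setGeneric("ambiguousTokens", function(x) standardGeneric("ambiguousTokens"))
setMethod("ambiguousTokens", "ResolutionReport", function(x) x@ambiguous)

setMethod("show", "ResolutionReport", function(object) {
    cat(sprintf("ResolutionReport: %d matched, %d unmatched, %d ambiguous\n",
        nrow(object@matched), nrow(object@unmatched), nrow(object@ambiguous)))
})

#' Extract the ranked result table of a report
#' @param x an EnrichmentReport.
#' @param row.names,optional,... passed on (unused).
#' @return data.frame of per-term statistics, in ranked order.
#' @export
setMethod("as.data.frame", "EnrichmentReport",
    function(x, row.names = NULL, optional = FALSE, ...) x@results)

setMethod("show", "EnrichmentReport", function(object) {
    cat(sprintf(
        "EnrichmentReport: library '%s', %d term(s), input %d of universe %d (%d dropped)\n",
        object@libraryName, nrow(object@results), object@inputSize,
        object@universeSize, object@nDroppedInput))
    if (nrow(object@results)) {
        top <- utils::head(object@results, 5L)
        cat("  top terms:\n")
        for (i in seq_len(nrow(top)))
            cat(sprintf("    %s  overlap %d/%d  p=%.3g q=%.3g\n",
                top$term[i], top$n_overlap[i], top$set_size[i],
                top$p_value[i], top$q_value[i]))
    }
})

#' @rdname FingerprintMatrix-class
#' @param x,object a FingerprintMatrix.
#' @export
setGeneric("fingerprintBits", function(x) standardGeneric("fingerprintBits"))
setMethod("fingerprintBits", "FingerprintMatrix", function(x) x@bits)

#' @rdname FingerprintMatrix-class
#' @export
setGeneric("fingerprintFailures", function(x) standardGeneric("fingerprintFailures"))
setMethod("fingerprintFailures", "FingerprintMatrix", function(x) x@failures)

#' @rdname FingerprintMatrix-class
#' @export
setGeneric("rowKeys", function(x) standardGeneric("rowKeys"))
setMethod("rowKeys", "FingerprintMatrix", function(x) x@rowKeys)
setMethod("rowKeys", "FeatureSpace", function(x) x@rowKeys)

setMethod("show", "FingerprintMatrix", function(object) {
    cat(sprintf("FingerprintMatrix (%s): %d molecule(s) x %d bits, %d failure(s)\n",
        object@dictionaryName, length(object@rowKeys), object@nBits,
        nrow(object@failures)))
})

#' @rdname SignatureCollection-class
#' @param x,object a SignatureCollection.
#' @param direction "up" or "down".
#' @export
setGeneric("signatureGenes", function(x, direction) standardGeneric("signatureGenes"))
setMethod("signatureGenes", "SignatureCollection", function(x, direction) {
    direction <- match.arg(direction, c("up", "down"))
    slot(x, direction)
})

setMethod("length", "SignatureCollection",
    function(x) length(union(names(x@up), names(x@down))))

setMethod("show", "SignatureCollection", function(object) {
    cat(sprintf("SignatureCollection: %d drug(s) (%d up sets, %d down sets)\n",
        length(object), length(object@up), length(object@down)))
})

#' @rdname ConsensusTable-class
#' @param x,object a ConsensusTable.
#' @export
setGeneric("consensusRanking", function(x) standardGeneric("consensusRanking"))
setMethod("consensusRanking", "ConsensusTable", function(x) {
    data.frame(term = rownames(x@scores), cumulative = unname(x@cumulative),
        rank = unname(x@rank), stringsAsFactors = FALSE)
})

#' @rdname ConsensusTable-class
#' @export
setGeneric("screenScores", function(x) standardGeneric("screenScores"))
setMethod("screenScores", "ConsensusTable", function(x) x@scores)

setMethod("show", "ConsensusTable", function(object) {
    cat(sprintf("ConsensusTable: %d term(s) x %d screen(s)\n",
        nrow(object@scores), ncol(object@scores)))
    top <- utils::head(rownames(object@scores), 5L)
    if (length(top))
        cat("  top: ", paste(sprintf("%s (%.2f)", top,
            object@cumulative[seq_along(top)]), collapse = ", "), "\n", sep = "")
})

#' Combined design matrix of a FeatureSpace
#' @param x a FeatureSpace.
#' @return numeric matrix, rows = drugs, columns = all block columns.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
setMethod("featureMatrix", "FeatureSpace", function(x) {
    m <- do.call(cbind, x@blocks)
    rownames(m) <- x@rowKeys
    m
})

#' @rdname FeatureSpace-class
#' @param x,object a FeatureSpace.
#' @export
setGeneric("featureBlocks", function(x) standardGeneric("featureBlocks"))
setMethod("featureBlocks", "FeatureSpace", function(x) x@blocks)

setMethod("show", "FeatureSpace", function(object) {
    w <- vapply(object@blocks, ncol, integer(1))
    cat(sprintf("FeatureSpace: %d drug(s), %d block(s), combined width %d\n",
        length(object@rowKeys), length(object@blocks), sum(w)))
    for (b in names(object@blocks))
        cat(sprintf("  %s: %d column(s)\n", b, ncol(object@blocks[[b]])))
})
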