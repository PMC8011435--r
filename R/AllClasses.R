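#' @import methods
NULL

#' DrugSetLibrary: a named collection of term -> drug-set associations
#'
#' The central container of the package: an ordered collection of drug sets,
#' each identified by a unique term, together with a member universe. The
#' on-disk representation is the tab-delimited DMT format (the drug analogue
#' of GMT): one line per set holding the term, a free-text description and
#' the member tokens.
#'
#' @slot name library name (single string; may be empty).
#' @slot sets named list; each element is a character vector of unique,
#'   nonempty member tokens, named by its term.
#' @slot descriptions character vector parallel to \code{sets}.
#' @slot universe character vector of member tokens forming the enrichment
#'   background. Defaults to the union of all set members; every set member
#'   must belong to it.
#'
#' @seealso [readDMT()], [writeDMT()], [filterMinSize()], [enrichDrugs()]
#' @export
setClass("DrugSetLibrary",
    representation(
        name = "character",
        sets = "list",
        descriptions = "character",
        universe = "character"
    )
)

setValidity("DrugSetLibrary", function(object) {
    msg <- character()
    terms <- names(object@sets)
    if (length(object@sets) > 0L) {
        if (is.null(terms) || any(is.na(terms)) || any(!nzchar(terms)))
            msg <- c(msg, "every set must have a nonempty term")
        if (anyDuplicated(terms))
            msg <- c(msg, sprintf("duplicate term(s): %s",
                paste(unique(terms[duplicated(terms)]), collapse = ", ")))
        for (i in seq_along(object@sets)) {
            m <- object@sets[[i]]
            if (!is.character(m) || length(m) == 0L)
                msg <- c(msg, sprintf("set '%s' has no members", terms[i]))
            else {
                if (any(!nzchar(m)))
                    msg <- c(msg, sprintf("set '%s' contains an empty member token", terms[i]))
                if (anyDuplicated(m))
                    msg <- c(msg, sprintf("set '%s' contains duplicate members", terms[i]))
            }
        }
        if (length(object@descriptions) != length(object@sets))
            msg <- c(msg, "descriptions must be parallel to sets")
        allm <- unique(unlist(object@sets, use.names = FALSE))
        if (length(allm) && !all(allm %in% object@universe))
            msg <- c(msg, "every set member must belong to the universe")
    }
    if (anyDuplicated(object@universe))
        msg <- c(msg, "universe contains duplicate tokens")
    if (length(object@name) != 1L)
        msg <- c(msg, "name must be a single string")
    if (length(msg)) msg else TRUE
})

#' Construct a DrugSetLibrary
#'
#' @param sets named list of character vectors (term -> members). Members
#'   are deduplicated; empty tokens are an error.
#' @param descriptions optional character vector parallel to \code{sets}
#'   (recycled empty strings by default).
#' @param name library name.
#' @param universe optional explicit background. When omitted it is the
#'   union of all members, so the object is self-contained.
#' @return a [DrugSetLibrary-class] object.
#' @examples
#' lib <- DrugSetLibrary(list(ringA = c("d1", "d2", "d3")), name = "toy")
#' nSets(lib)
#' @export
DrugSetLibrary <- function(sets, descriptions = NULL, name = "", universe = NULL) {
    stopifnot(is.list(sets))
    sets <- lapply(sets, function(m) unique(as.character(m)))
    if (is.null(descriptions)) descriptions <- rep("", length(sets))
    descriptions <- as.character(descriptions)
    if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
    if (is.null(universe)) universe <- character()
    new("DrugSetLibrary",
        name = as.character(name), sets = sets,
        descriptions = descriptions, universe = unique(as.character(universe)))
}

#' DrugMetadataTable: the master small-molecule metadata table
#'
#' Canonical identity records for small molecules, plus the lookup indexes
#' used to resolve heterogeneous input tokens: case-folded names/synonyms
#' (one-to-many), complete 27-character InChIKeys (one-to-one), canonical
#' SMILES, and per-namespace cross-references (e.g. DrugBank and Broad IDs).
#'
#' @slot records data.frame with columns \code{canonical_id},
#'   \code{primary_name}, \code{inchikey}, \code{smiles} (empty string =
#'   absent).
#' @slot synonyms named list: canonical_id -> character vector of synonyms.
#' @slot xrefs named list: namespace -> named character vector mapping
#'   uppercased external identifier -> canonical_id.
#' @slot nameIndex named list: lowercased name/synonym -> character vector
#'   of canonical_ids (collisions across stereoisomers are preserved).
#' @slot inchikeyIndex named character: InChIKey -> canonical_id.
#' @slot smilesIndex named character: canonical SMILES -> canonical_id.
#' @seealso [readDrugMetadata()], [resolveDrugs()]
#' @export
setClass("DrugMetadataTable",
    representation(
        records = "data.frame",
        synonyms = "list",
        xrefs = "list",
        nameIndex = "list",
        inchikeyIndex = "character",
        smilesIndex = "character"
    )
)

setValidity("DrugMetadataTable", function(object) {
    msg <- character()
    req <- c("canonical_id", "primary_name", "inchikey", "smiles")
    if (!all(req %in% colnames(object@records)))
        msg <- c(msg, "records must have canonical_id, primary_name, inchikey, smiles")
    else {
        ids <- object@records$canonical_id
        if (anyDuplicated(ids))
            msg <- c(msg, "canonical_id must be unique")
        keys <- object@records$inchikey
        keys <- keys[nzchar(keys)]
        if (anyDuplicated(keys))
            msg <- c(msg, "at most one record per full InChIKey")
        bad <- keys[!grepl(.inchikeyRegex, keys)]
        if (length(bad))
            msg <- c(msg, sprintf("malformed InChIKey(s): %s", paste(bad, collapse = ", ")))
        idx <- unique(unlist(object@nameIndex, use.names = FALSE))
        if (length(idx) && !all(idx %in% ids))
            msg <- c(msg, "name index points to a missing record")
        if (length(object@inchikeyIndex) && !all(object@inchikeyIndex %in% ids))
            msg <- c(msg, "inchikey index points to a missing record")
        for (ns in names(object@xrefs))
            if (length(object@xrefs[[ns]]) && !all(object@xrefs[[ns]] %in% ids))
                msg <- c(msg, sprintf("xref index '%s' points to a missing record", ns))
    }
    if (length(msg)) msg else TRUE
})

.inchikeyRegex <- "^[A-Z]{14}-[A-Z]{10}-[A-Z]$"

#' ResolutionReport: outcome of resolving input tokens against a table
#'
#' The three slots partition the input tokens: each token is matched to
#' exactly one record, reported unmatched with a reason, or reported
#' ambiguous with its candidate records.
#'
#' @slot matched data.frame: \code{token}, \code{canonical_id},
#'   \code{channel} (one of name, inchikey, smiles, drugbank, brd).
#' @slot unmatched data.frame: \code{token}, \code{reason}.
#' @slot ambiguous data.frame: \code{token}, \code{candidates}
#'   (list column of canonical_id vectors).
#' @export
setClass("ResolutionReport",
    representation(
        matched = "data.frame",
        unmatched = "data.frame",
        ambiguous = "data.frame"
    )
)

#' EnrichmentReport: ranked per-term overlap statistics
#'
#' One row per library set, sorted by ascending p-value with ties broken by
#' larger overlap then term. Columns: term, n_overlap, set_size, input_size,
#' universe_size, p_value, q_value, odds_ratio, overlap_members (list
#' column).
#'
#' @slot results the data.frame described above.
#' @slot libraryName name of the library queried.
#' @slot universeSize background size used for every contingency table.
#' @slot inputSize size of the input after intersection with the universe.
#' @slot nDroppedInput number of input members outside the universe.
#' @slot provenance free-text description of the input.
#' @seealso [enrichDrugs()]
#' @export
setClass("EnrichmentReport",
    representation(
        results = "data.frame",
        libraryName = "character",
        universeSize = "integer",
        inputSize = "integer",
        nDroppedInput = "integer",
        provenance = "character"
    )
)

#' FingerprintMatrix: binary structural fingerprints for a set of molecules
#'
#' @slot rowKeys drug tokens (one per successfully fingerprinted structure).
#' @slot dictionaryName "maccs166", "morgan" or "custom".
#' @slot nBits number of key positions (166 for maccs166; parameterized for
#'   morgan, default 2048 at radius 4).
#' @slot bits binary matrix |rowKeys| x nBits.
#' @slot failures data.frame (\code{input}, \code{reason}) of structures
#'   that could not be parsed; these do not appear among the rows.
#' @seealso [maccsFingerprints()], [morganFingerprints()],
#'   [fingerprintLibrary()]
#' @export
setClass("FingerprintMatrix",
    representation(
        rowKeys = "character",
        dictionaryName = "character",
        nBits = "integer",
        bits = "matrix",
        failures = "data.frame"
    )
)

setValidity("FingerprintMatrix", function(object) {
    msg <- character()
    if (nrow(object@bits) != length(object@rowKeys))
        msg <- c(msg, "bit matrix rows must match rowKeys")
    if (ncol(object@bits) != object@nBits)
        msg <- c(msg, "bit matrix width must match nBits")
    if (length(object@bits) && !all(object@bits %in% c(0, 1)))
        msg <- c(msg, "all fingerprint entries must be 0 or 1")
    if (anyDuplicated(object@rowKeys))
        msg <- c(msg, "duplicate row keys")
    if (length(msg)) msg else TRUE
})

#' SignatureCollection: per-drug up/down gene signatures
#'
#' Holds, for each drug token, the sets of up- and downregulated gene
#' symbols (uppercased). Genes listed in both directions for the same drug
#' are contradictory and are removed from both sides with a warning at
#' construction.
#'
#' @slot up named list: drug token -> character vector of gene symbols.
#' @slot down named list: drug token -> character vector of gene symbols.
#' @seealso [signatureLibrary()], [readSignatureGMT()]
#' @export
setClass("SignatureCollection",
    representation(up = "list", down = "list")
)

setValidity("SignatureCollection", function(object) {
    msg <- character()
    drugs <- union(names(object@up), names(object@down))
    for (d in drugs) {
        both <- intersect(object@up[[d]], object@down[[d]])
        if (length(both))
            msg <- c(msg, sprintf("drug '%s' lists gene(s) in both directions", d))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a SignatureCollection
#'
#' @param up,down named lists of gene-symbol vectors keyed by drug token.
#'   Symbols are uppercased and deduplicated; genes appearing in both
#'   directions for one drug are dropped from both with a warning.
#' @return a [SignatureCollection-class].
#' @export
SignatureCollection <- function(up = list(), down = list()) {
    up <- lapply(up, function(g) unique(toupper(as.character(g))))
    down <- lapply(down, function(g) unique(toupper(as.character(g))))
    for (d in intersect(names(up), names(down))) {
        both <- intersect(up[[d]], down[[d]])
        if (length(both)) {
            warning(sprintf(
                "drug '%s': %d gene(s) in both up and down sets; removed from both",
                d, length(both)))
            up[[d]] <- setdiff(up[[d]], both)
            down[[d]] <- setdiff(down[[d]], both)
        }
    }
    new("SignatureCollection", up = up, down = down)
}

#' ConsensusTable: term x screen matrix of -log10 p with cumulative ranking
#'
#' @slot scores matrix of -log10(p) scores (terms x screens); 0 where a
#'   term was untested in a screen or had p = 1.
#' @slot cumulative named numeric: per-term row sums.
#' @slot rank named integer: dense rank by decreasing cumulative score.
#' @seealso [consensusScores()], [exportStackedContributions()]
#' @export
setClass("ConsensusTable",
    representation(
        scores = "matrix",
        cumulative = "numeric",
        rank = "integer"
    )
)

setValidity("ConsensusTable", function(object) {
    msg <- character()
    if (length(object@scores) && any(object@scores < 0))
        msg <- c(msg, "scores must be nonnegative")
    if (nrow(object@scores) != length(object@cumulative))
        msg <- c(msg, "cumulative must be parallel to score rows")
    if (length(object@cumulative) &&
        max(abs(object@cumulative - rowSums(object@scores))) > 1e-8)
        msg <- c(msg, "cumulative must equal row sums of scores")
    if (length(object@rank) && object@rank[1L] != 1L)
        msg <- c(msg, "first row must hold rank 1")
    if (length(msg)) msg else TRUE
})

#' FeatureSpace: row-aligned drug feature blocks
#'
#' An ordered list of named feature blocks (e.g. a 978-column expression
#' block and a 2048-column fingerprint block) sharing one set of row keys
#' (complete InChIKeys by convention). The combined design matrix is the
#' column binding of all blocks.
#'
#' @slot rowKeys drug tokens; unique, shared by every block.
#' @slot blocks named list of numeric matrices with |rowKeys| rows.
#' @slot dropped named list: per block, the row keys discarded by the
#'   inner join at assembly.
#' @seealso [assembleFeatures()], [featureMatrix()]
#' @export
setClass("FeatureSpace",
    representation(rowKeys = "character", blocks = "list", dropped = "list")
)

setValidity("FeatureSpace", function(object) {
    msg <- character()
    if (anyDuplicated(object@rowKeys))
        msg <- c(msg, "duplicate row keys")
    if (length(object@blocks) == 0L)
        msg <- c(msg, "at least one feature block is required")
    for (b in names(object@blocks))
        if (nrow(object@blocks[[b]]) != length(object@rowKeys))
            msg <- c(msg, sprintf("block '%s' rows do not match rowKeys", b))
    if (length(msg)) msg else TRUE
})
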