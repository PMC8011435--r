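# Entity harmonization: the master metadata table and token resolution.

.kindLevels <- c("inchikey", "drugbank", "brd", "smiles", "name")

#' Read a master small-molecule metadata table
#'
#' Reads a UTF-8, tab-delimited table of small-molecule identity records.
#' Required column: \code{name}. Recognized optional columns:
#' \code{inchikey}, \code{smiles}, \code{synonyms} (\code{|}-delimited) and
#' an optional \code{id} column supplying canonical identifiers. Every
#' other column is treated as a cross-reference namespace (e.g.
#' \code{drugbank}, \code{brd}, \code{pubchem_cid}). Empty strings mean
#' "absent".
#'
#' Rows sharing one complete InChIKey describe the same entity and are
#' collapsed into a single record: the first row supplies the primary name
#' and structure, later rows contribute their names and synonyms as
#' synonyms. Malformed InChIKeys are dropped (with a warning) rather than
#' indexed, so one bad key cannot shadow a record.
#'
#' @param path TSV file path.
#' @param canonicalizeSmiles canonicalize table SMILES for the SMILES
#'   lookup index (needs OpenBabel; default TRUE).
#' @return a [DrugMetadataTable-class] with all lookup indexes built.
#' @examples
#' tab <- readDrugMetadata(system.file("extdata", "drug_fixture_table.tsv",
#'     package = "drugsets"))
#' tab
#' @export
readDrugMetadata <- function(path, canonicalizeSmiles = TRUE) {
    if (!file.exists(path)) stop(sprintf("no such file: %s", path))
    df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
        comment.char = "", colClasses = "character", check.names = FALSE,
        na.strings = NULL, fileEncoding = "UTF-8")
    if (ncol(df) == 0L)
        stop("metadata format error: file has no header")
    colnames(df) <- tolower(trimws(colnames(df)))
    if (!"name" %in% colnames(df))
        stop("metadata format error: missing required column 'name'")
    for (opt in c("inchikey", "smiles", "synonyms", "id"))
        if (!opt %in% colnames(df)) df[[opt]] <- rep("", nrow(df))
    df[] <- lapply(df, trimws)

    badKey <- nzchar(df$inchikey) & !grepl(.inchikeyRegex, df$inchikey)
    if (any(badKey)) {
        warning(sprintf("%d malformed InChIKey(s) ignored (e.g. '%s')",
            sum(badKey), df$inchikey[which(badKey)[1L]]))
        df$inchikey[badKey] <- ""
    }

    xrefCols <- setdiff(colnames(df), c("name", "inchikey", "smiles", "synonyms", "id"))

    # Collapse duplicate InChIKeys: one entity per complete key.
    groups <- ifelse(nzchar(df$inchikey), df$inchikey,
        sprintf(".row%06d", seq_len(nrow(df))))
    first <- !duplicated(groups)
    ord <- which(first)
    synonyms <- vector("list", length(ord))
    keep <- df[ord, , drop = FALSE]
    rowOf <- match(groups, groups[ord])
    for (g in seq_along(ord)) {
        rows <- which(rowOf == g)
        syn <- unlist(strsplit(df$synonyms[rows], "|", fixed = TRUE),
            use.names = FALSE)
        syn <- c(df$name[rows[-1L]], syn)           # merged rows' names
        syn <- trimws(syn)
        syn <- syn[nzchar(syn)]
        syn <- syn[!duplicated(tolower(syn))]
        syn <- syn[tolower(syn) != tolower(df$name[rows[1L]])]
        synonyms[[g]] <- syn
        for (xc in xrefCols) {
            vals <- df[[xc]][rows]
            vals <- vals[nzchar(vals)]
            if (length(vals)) keep[[xc]][g] <- vals[1L]
        }
    }

    canonicalId <- keep$id
    if (!all(nzchar(canonicalId)))
        canonicalId <- ifelse(nzchar(keep$id), keep$id,
            sprintf("E%05d", seq_len(nrow(keep))))
    if (anyDuplicated(canonicalId))
        stop("metadata format error: duplicate canonical ids")
    names(synonyms) <- canonicalId

    records <- data.frame(canonical_id = canonicalId,
        primary_name = keep$name, inchikey = keep$inchikey,
        smiles = keep$smiles, stringsAsFactors = FALSE)

    nameIndex <- list()
    for (i in seq_len(nrow(records))) {
        for (nm in unique(tolower(c(records$primary_name[i], synonyms[[i]])))) {
            if (!nzchar(nm)) next
            nameIndex[[nm]] <- c(nameIndex[[nm]], canonicalId[i])
        }
    }

    haveKey <- nzchar(records$inchikey)
    inchikeyIndex <- stats::setNames(canonicalId[haveKey], records$inchikey[haveKey])

    smilesIndex <- character()
    haveSmi <- which(nzchar(records$smiles))
    if (canonicalizeSmiles && length(haveSmi)) {
        canon <- .canonicalSmiles(records$smiles[haveSmi])
        ok <- !is.na(canon)
        canon <- canon[ok]
        ids <- canonicalId[haveSmi][ok]
        dup <- duplicated(canon)
        smilesIndex <- stats::setNames(ids[!dup], canon[!dup])
    }

    xrefs <- list()
    for (xc in xrefCols) {
        vals <- keep[[xc]]
        haveX <- nzchar(vals)
        if (any(haveX))
            xrefs[[xc]] <- stats::setNames(canonicalId[haveX], toupper(vals[haveX]))
    }

    new("DrugMetadataTable", records = records, synonyms = synonyms,
        xrefs = xrefs, nameIndex = nameIndex, inchikeyIndex = inchikeyIndex,
        smilesIndex = smilesIndex)
}

#' Classify an input token as an identifier kind
#'
#' Deterministic classification with fixed precedence: a complete
#' 27-character InChIKey, then a DrugBank ID (\code{DB} + 5 digits), then a
#' Broad Institute ID (\code{BRD-} prefix), then a SMILES string (must
#' parse as a valid molecule), and finally a plain name as the fallback.
#'
#' @param token a single nonempty string.
#' @return one of \code{"inchikey"}, \code{"drugbank"}, \code{"brd"},
#'   \code{"smiles"}, \code{"name"}.
#' @examples
#' detectTokenKind("JURKNVYFZMSNLP-UHFFFAOYSA-N")
#' detectTokenKind("CCO")
#' @export
detectTokenKind <- function(token) {
    stopifnot(is.character(token), length(token) == 1L, nzchar(token))
    token <- trimws(token)
    if (grepl(.inchikeyRegex, token)) return("inchikey")
    if (grepl("^DB\\d{5}$", token, ignore.case = TRUE)) return("drugbank")
    if (grepl("^BRD-", token, ignore.case = TRUE)) return("brd")
    if (.looksLikeSmiles(token) && .isValidSmiles(token)) return("smiles")
    "name"
}

#' Resolve input tokens against a metadata table
#'
#' Each token is matched through the channel of its detected kind (or a
#' forced kind). Name matching is case-insensitive over primary names and
#' synonyms; a name matching more than one record (e.g. stereoisomers that
#' share a name) is reported ambiguous, not silently assigned, unless
#' \code{firstMatch = TRUE} downgrades it to the lexicographically smallest
#' canonical id. InChIKey matching always uses the complete 27-character
#' key; there is no skeleton-block fallback. SMILES are canonicalized on
#' both sides before comparison.
#'
#' @param tokens character vector of input tokens (one entity per element).
#' @param table a [DrugMetadataTable-class].
#' @param kind optional forced channel for every token (one of
#'   \code{inchikey}, \code{drugbank}, \code{brd}, \code{smiles},
#'   \code{name}); tokens failing that channel's syntax go to unmatched.
#' @param firstMatch deterministic pick for ambiguous name matches.
#' @return a [ResolutionReport-class]; its matched/unmatched/ambiguous
#'   parts partition the input tokens.
#' @export
resolveDrugs <- function(tokens, table, kind = NULL, firstMatch = FALSE) {
    stopifnot(is(table, "DrugMetadataTable"))
    if (!is.null(kind)) kind <- match.arg(kind, .kindLevels)
    tokens <- as.character(tokens)

    matched <- list(); unmatched <- list(); ambiguous <- list()
    for (tok in tokens) {
        tk <- trimws(tok)
        if (!nzchar(tk)) {
            unmatched[[length(unmatched) + 1L]] <- list(token = tok,
                reason = "empty token")
            next
        }
        k <- if (is.null(kind)) detectTokenKind(tk) else kind
        res <- .resolveOne(tk, k, table, forced = !is.null(kind),
            firstMatch = firstMatch)
        slot <- res$status
        if (slot == "matched")
            matched[[length(matched) + 1L]] <- list(token = tok,
                canonical_id = res$id, channel = k)
        else if (slot == "ambiguous")
            ambiguous[[length(ambiguous) + 1L]] <- list(token = tok,
                candidates = res$candidates)
        else
            unmatched[[length(unmatched) + 1L]] <- list(token = tok,
                reason = res$reason)
    }

    m <- if (length(matched)) data.frame(
        token = vapply(matched, `[[`, "", "token"),
        canonical_id = vapply(matched, `[[`, "", "canonical_id"),
        channel = vapply(matched, `[[`, "", "channel"),
        stringsAsFactors = FALSE)
    else data.frame(token = character(), canonical_id = character(),
        channel = character(), stringsAsFactors = FALSE)
    u <- if (length(unmatched)) data.frame(
        token = vapply(unmatched, `[[`, "", "token"),
        reason = vapply(unmatched, `[[`, "", "reason"),
        stringsAsFactors = FALSE)
    else data.frame(token = character(), reason = character(),
        stringsAsFactors = FALSE)
    a <- data.frame(token = if (length(ambiguous))
        vapply(ambiguous, `[[`, "", "token") else character(),
        stringsAsFactors = FALSE)
    a$candidates <- if (length(ambiguous))
        lapply(ambiguous, `[[`, "candidates") else list()

    new("ResolutionReport", matched = m, unmatched = u, ambiguous = a)
}

.resolveOne <- function(token, k, table, forced, firstMatch) {
    fail <- function(reason) list(status = "unmatched", reason = reason)
    hit <- function(id) list(status = "matched", id = id)
    switch(k,
        inchikey = {
            if (!grepl(.inchikeyRegex, token))
                return(fail("does not match InChIKey syntax"))
            id <- table@inchikeyIndex[token]
            if (is.na(id)) fail("InChIKey not in table") else hit(unname(id))
        },
        drugbank = {
            if (forced && !grepl("^DB\\d{5}$", token, ignore.case = TRUE))
                return(fail("does not match DrugBank ID syntax"))
            id <- table@xrefs[["drugbank"]][toupper(token)]
            if (is.null(id) || is.na(id)) fail("DrugBank ID not in table")
            else hit(unname(id))
        },
        brd = {
            if (forced && !grepl("^BRD-", token, ignore.case = TRUE))
                return(fail("does not match BRD ID syntax"))
            id <- table@xrefs[["brd"]][toupper(token)]
            if (is.null(id) || is.na(id)) fail("BRD ID not in table")
            else hit(unname(id))
        },
        smiles = {
            canon <- .canonicalSmiles(token)
            if (is.na(canon))
                return(fail("SMILES fails to canonicalize"))
            id <- table@smilesIndex[canon]
            if (is.na(id)) fail("structure not in table") else hit(unname(id))
        },
        name = {
            ids <- table@nameIndex[[tolower(token)]]
            if (is.null(ids) || length(ids) == 0L)
                fail("name not in table")
            else if (length(ids) == 1L)
                hit(ids)
            else if (firstMatch)
                hit(sort(ids)[1L])
            else
                list(status = "ambiguous", candidates = sort(ids))
        })
}
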