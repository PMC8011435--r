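# Structural fingerprints via OpenBabel (ChemmineOB).

.fingerprintFromSmiles <- function(smilesTable, obType, nBits, dictionaryName,
                                   keep = NULL) {
    if (is.data.frame(smilesTable)) {
        stopifnot(ncol(smilesTable) >= 2L)
        tokens <- as.character(smilesTable[[1L]])
        smiles <- as.character(smilesTable[[2L]])
    } else {
        stopifnot(is.character(smilesTable), !is.null(names(smilesTable)))
        tokens <- names(smilesTable)
        smiles <- unname(smilesTable)
    }
    if (length(tokens) == 0L) stop("empty SMILES table")
    if (anyDuplicated(tokens)) stop("duplicate drug tokens in SMILES table")

    canon <- .canonicalSmiles(smiles)
    ok <- !is.na(canon)
    failures <- data.frame(input = tokens[!ok],
        reason = rep("SMILES failed to parse", sum(!ok)),
        stringsAsFactors = FALSE)
    if (!any(ok)) stop("no valid structures")

    raw <- .obFingerprintMatrix(smiles[ok], obType)
    bits <- keep(raw)
    rownames(bits) <- NULL
    new("FingerprintMatrix", rowKeys = tokens[ok],
        dictionaryName = dictionaryName, nBits = as.integer(nBits),
        bits = bits, failures = failures)
}

#' MACCS structural key fingerprints
#'
#' Computes the 166-position Molecular ACCess System (MACCS) key
#' fingerprint for each structure via OpenBabel's MACCS SMARTS dictionary.
#' OpenBabel exposes the keys in a 256-bit vector indexed by key number;
#' the 166 defined key positions are extracted, so the resulting matrix
#' has exactly 166 columns (no dummy position).
#'
#' @param smilesTable a two-column data.frame (token, SMILES) or a named
#'   character vector of SMILES keyed by token.
#' @return a [FingerprintMatrix-class] with \code{nBits = 166};
#'   unparseable structures are routed to its \code{failures} slot.
#' @examples
#' fp <- maccsFingerprints(c(benzene = "c1ccccc1", ethanol = "CCO"))
#' fp
#' @export
maccsFingerprints <- function(smilesTable) {
    .fingerprintFromSmiles(smilesTable, "MACCS", 166L, "maccs166",
        keep = function(raw) {
            m <- raw[, 1:166, drop = FALSE]
            colnames(m) <- sprintf("maccs_%d", 1:166)
            m
        })
}

#' Circular (Morgan/ECFP) fingerprints
#'
#' Hashed circular substructure fingerprints with the conventional
#' defaults radius 4 and 2048 bits. The extended-connectivity environments
#' are computed by OpenBabel (radius r corresponds to its ECFP2r
#' fingerprint, a 4096-bit hashed vector) and folded to \code{nBits}
#' positions by OR-ing bit \eqn{j} into position \eqn{j \bmod nBits} — the
#' standard fold for hashed fingerprints.
#'
#' @inheritParams maccsFingerprints
#' @param radius circular neighborhood radius (1 to 5).
#' @param nBits folded width (8 to 4096).
#' @return a [FingerprintMatrix-class] with \code{nBits} columns.
#' @export
morganFingerprints <- function(smilesTable, radius = 4L, nBits = 2048L) {
    stopifnot(radius >= 1L, radius <= 5L, nBits >= 8L, nBits <= 4096L)
    obType <- sprintf("ECFP%d", 2L * as.integer(radius))
    .fingerprintFromSmiles(smilesTable, obType, nBits, "morgan",
        keep = function(raw) {
            folded <- matrix(0, nrow(raw), nBits)
            for (j in seq_len(ncol(raw))) {
                tgt <- ((j - 1L) %% nBits) + 1L
                folded[, tgt] <- pmax(folded[, tgt], raw[, j])
            }
            colnames(folded) <- sprintf("morgan_%d", seq_len(nBits) - 1L)
            folded
        })
}

#' Wrap a precomputed binary matrix as a FingerprintMatrix
#'
#' For externally computed dictionaries (e.g. the 881-bit PubChem
#' fingerprint, whose key semantics are an external specification and are
#' accepted only as a precomputed matrix).
#'
#' @param bits binary matrix with row names = drug tokens (or supply
#'   \code{rowKeys}).
#' @param rowKeys optional explicit drug tokens.
#' @param dictionaryName recorded dictionary label.
#' @return a [FingerprintMatrix-class].
#' @export
customFingerprints <- function(bits, rowKeys = rownames(bits),
                               dictionaryName = "custom") {
    bits <- as.matrix(bits)
    storage.mode(bits) <- "double"
    stopifnot(!is.null(rowKeys), length(rowKeys) == nrow(bits))
    rk <- as.character(rowKeys)
    rownames(bits) <- NULL
    new("FingerprintMatrix", rowKeys = rk, dictionaryName = dictionaryName,
        nBits = ncol(bits), bits = bits,
        failures = data.frame(input = character(), reason = character(),
            stringsAsFactors = FALSE))
}
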