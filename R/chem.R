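# Thin wrappers around ChemmineOB / OpenBabel for SMILES handling.
# All structure parsing in the package funnels through these helpers so the
# rest of the code never touches molecule objects directly.

.obNoOptions <- function() data.frame(names = character(), args = character())

# Canonicalize SMILES strings one at a time (a batch call would silently
# drop failed molecules and misalign the output). Returns NA for strings
# OpenBabel cannot parse. OpenBabel reports parse failures on stderr; that
# output is informational only.
.canonicalSmiles <- function(smiles) {
    vapply(as.character(smiles), function(s) {
        if (is.na(s) || !nzchar(s)) return(NA_character_)
        out <- tryCatch(
            ChemmineOB::convertFormat("SMI", "CAN", s, options = .obNoOptions()),
            error = function(e) "")
        out <- sub("\t.*$", "", trimws(out))
        if (nzchar(out)) out else NA_character_
    }, character(1), USE.NAMES = FALSE)
}

.isValidSmiles <- function(smiles) !is.na(.canonicalSmiles(smiles))

# Quick syntactic screen so obviously non-SMILES tokens (e.g. names with
# spaces or characters outside the SMILES alphabet) never reach the parser.
.smilesCharset <- "^[A-Za-z0-9@+\\-\\[\\]()=#$%/\\\\.:*]+$"
.looksLikeSmiles <- function(token) grepl(.smilesCharset, token, perl = TRUE)

# Binary fingerprint matrix for pre-validated SMILES via an OpenBabel
# fingerprint type ("MACCS", "ECFP8", ...). Rows align with the input.
.obFingerprintMatrix <- function(smiles, type) {
    stopifnot(length(smiles) >= 1L)
    mols <- ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"),
        identity)
    if (!is.list(mols)) mols <- list(mols)
    if (length(mols) != length(smiles))
        stop("internal error: fingerprint parse count mismatch")
    fp <- ChemmineOB::fingerprint_OB(mols, type)
    # a single molecule comes back as a bare vector
    if (is.null(dim(fp))) fp <- matrix(fp, nrow = 1L)
    fp <- unname(as.matrix(fp))
    if (nrow(fp) != length(smiles) && ncol(fp) == length(smiles))
        fp <- t(fp)
    storage.mode(fp) <- "double"
    fp[fp != 0] <- 1
    fp
}
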