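# DMT/GMT set-library input/output and basic library operations.
#
# DMT adopts the GMT dialect exactly: one line per set, tab-delimited, with
# term, description (may be empty) and then the member tokens. This keeps
# drug set libraries interoperable with existing gene-set tooling.

#' Read a DMT/GMT set-library file
#'
#' @param path file path.
#' @param name library name recorded in the result (defaults to the file
#'   name without extension).
#' @param noDescription tolerate 2-field lines by treating every field
#'   after the term as a member (for libraries written without the
#'   description column).
#' @return a [DrugSetLibrary-class]. Duplicate members within a line are
#'   deduplicated with a warning; blank lines are skipped. A duplicate term
#'   across lines, or a line with fewer than 3 fields (2 with
#'   \code{noDescription}), is a format error naming the term / line.
#' @examples
#' f <- tempfile(fileext = ".dmt")
#' writeLines("ringkey\t\tA\tB\tC", f)
#' lib <- readDMT(f)
#' setMembers(lib, "ringkey")
#' @export
readDMT <- function(path, name = NULL, noDescription = FALSE) {
    if (!file.exists(path)) stop(sprintf("no such file: %s", path))
    if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    sets <- list(); descriptions <- character()
    minFields <- if (noDescription) 2L else 3L
    for (ln in seq_along(lines)) {
        line <- lines[[ln]]
        if (!nzchar(trimws(line))) next
        fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
        if (length(fields) < minFields)
            stop(sprintf("DMT format error at line %d: expected at least %d tab-delimited fields, got %d",
                ln, minFields, length(fields)))
        term <- trimws(fields[1L])
        if (!nzchar(term))
            stop(sprintf("DMT format error at line %d: empty term", ln))
        if (term %in% names(sets))
            stop(sprintf("DMT format error: duplicate term '%s' (line %d)", term, ln))
        if (noDescription) {
            desc <- ""
            members <- fields[-1L]
        } else {
            desc <- fields[2L]
            members <- fields[-(1:2)]
        }
        members <- members[nzchar(members)]
        if (length(members) == 0L)
            stop(sprintf("DMT format error at line %d: set '%s' has no members", ln, term))
        if (anyDuplicated(members)) {
            warning(sprintf("set '%s' (line %d): %d duplicate member(s) removed",
                term, ln, sum(duplicated(members))))
            members <- unique(members)
        }
        sets[[term]] <- members
        descriptions <- c(descriptions, desc)
    }
    DrugSetLibrary(sets, descriptions = descriptions, name = name)
}

#' Write a library as a DMT/GMT file
#'
#' One line per set in library order; \code{readDMT(writeDMT(lib))} is the
#' identity on (term, description, member set).
#'
#' @param lib a [DrugSetLibrary-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeDMT <- function(lib, path) {
    stopifnot(is(lib, "DrugSetLibrary"))
    bad <- grepl("\t", names(lib@sets), fixed = TRUE)
    if (any(bad))
        stop(sprintf("term contains a TAB: '%s'", names(lib@sets)[which(bad)[1L]]))
    lines <- vapply(seq_along(lib@sets), function(i) {
        paste(c(names(lib@sets)[i], lib@descriptions[i], lib@sets[[i]]),
            collapse = "\t")
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
    invisible(path)
}

#' Filter a library by minimum set size
#'
#' Retains exactly the sets with at least \code{k} members — the default
#' of 5 being the minimum set size a contingency-table test can sensibly
#' work with. The universe and set order are unchanged, so filtering is
#' idempotent and monotone in \code{k}.
#'
#' @param lib a [DrugSetLibrary-class].
#' @param k minimum number of members (>= 1).
#' @return the filtered [DrugSetLibrary-class].
#' @export
filterMinSize <- function(lib, k = 5L) {
    stopifnot(is(lib, "DrugSetLibrary"), k >= 1L)
    keep <- vapply(lib@sets, length, integer(1)) >= k
    new("DrugSetLibrary", name = lib@name, sets = lib@sets[keep],
        descriptions = lib@descriptions[keep], universe = lib@universe)
}

#' Summary statistics of a library
#'
#' @param lib a [DrugSetLibrary-class].
#' @return list with \code{n_sets}, \code{n_unique_members} and
#'   \code{mean_members_per_set} (0 for an empty library; the mean is
#'   rounded to 2 decimals in CLI output only).
#' @export
libraryStats <- function(lib) {
    stopifnot(is(lib, "DrugSetLibrary"))
    if (length(lib@sets) == 0L)
        return(list(n_sets = 0L, n_unique_members = 0L,
            mean_members_per_set = 0))
    sz <- vapply(lib@sets, length, integer(1))
    list(n_sets = length(sz),
        n_unique_members = length(unique(unlist(lib@sets, use.names = FALSE))),
        mean_members_per_set = mean(sz))
}

#' Read per-drug up/down signatures from a GMT file
#'
#' Terms are expected as \code{<drug>_up} and \code{<drug>_down}; lines
#' with any other suffix are rejected.
#'
#' @param path GMT file path.
#' @return a [SignatureCollection-class].
#' @export
readSignatureGMT <- function(path) {
    lib <- readDMT(path, noDescription = FALSE)
    up <- list(); down <- list()
    for (term in names(lib@sets)) {
        if (grepl("_up$", term))
            up[[sub("_up$", "", term)]] <- lib@sets[[term]]
        else if (grepl("_down$", term))
            down[[sub("_down$", "", term)]] <- lib@sets[[term]]
        else
            stop(sprintf("signature GMT term '%s' lacks an _up/_down suffix", term))
    }
    SignatureCollection(up = up, down = down)
}
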