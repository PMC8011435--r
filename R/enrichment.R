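# Drug set enrichment: one-sided Fisher's exact overlap test, BH
# correction, odds ratios and ranked reports.

#' One-sided Fisher's exact p-value for a 2x2 overlap table
#'
#' For the contingency table with overlap \code{a}, input-only \code{b},
#' set-only \code{c} and remainder \code{d}, computes the enrichment
#' (upper-tail) probability \eqn{P(X \ge a)} where \eqn{X} follows the
#' hypergeometric distribution with population \eqn{a+b+c+d}, successes
#' \eqn{a+c} and draws \eqn{a+b}. This is the probability of observing at
#' least the attained overlap between two independent sets.
#'
#' All four arguments are vectorized and recycled.
#'
#' @param a,b,c,d nonnegative integer cell counts.
#' @return numeric p-value(s) in (0, 1].
#' @examples
#' fisherExactGreater(3, 2, 2, 13)   # universe 20, set 5, input 5, overlap 3
#' @export
fisherExactGreater <- function(a, b, c, d) {
    n <- max(length(a), length(b), length(c), length(d))
    a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
    c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
    if (any(is.na(c(a, b, c, d))) || any(c(a, b, c, d) < 0))
        stop("domain error: contingency cells must be nonnegative")
    if (any(c(a, b, c, d) != floor(c(a, b, c, d))))
        stop("domain error: contingency cells must be integers")
    # P(X >= a) with successes a+c among a+b+c+d, drawing a+b
    stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment: for sorted p-values,
#' \eqn{q_{(i)} = \min_{j \ge i} \min(p_{(j)} m / j, 1)}, returned in the
#' input order. The adjusted values are monotone in p, never smaller than
#' p, and equal p when \code{m = 1}.
#'
#' @param p numeric vector of p-values, all in (0, 1].
#' @return numeric vector of q-values, same order as the input.
#' @export
bhAdjust <- function(p) {
    p <- as.numeric(p)
    if (length(p) == 0L) return(numeric())
    if (any(is.na(p)) || any(p <= 0) || any(p > 1))
        stop("domain error: p-values must lie in (0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Odds ratio of a 2x2 overlap table
#'
#' \eqn{(a d)/(b c)}, with the Haldane-Anscombe correction of +0.5 on
#' every cell whenever any cell is zero, so the ratio is always finite.
#'
#' @inheritParams fisherExactGreater
#' @return numeric odds ratio(s), >= 0.
#' @export
oddsRatio <- function(a, b, c, d) {
    n <- max(length(a), length(b), length(c), length(d))
    a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
    c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
    if (any(c(a, b, c, d) < 0))
        stop("domain error: contingency cells must be nonnegative")
    zero <- a == 0 | b == 0 | c == 0 | d == 0
    a[zero] <- a[zero] + 0.5; b[zero] <- b[zero] + 0.5
    c[zero] <- c[zero] + 0.5; d[zero] <- d[zero] + 0.5
    (a * d) / (b * c)
}

#' Drug set enrichment analysis of an input set against a library
#'
#' Tests the input drug set against every set in the library with the
#' one-sided Fisher's exact test over a common universe, adjusts the
#' p-values across the library's sets with Benjamini-Hochberg, and returns
#' a ranked report. Input members outside the universe are dropped (their
#' count is reported in the result and as a message). Rows are sorted by
#' ascending p, ties broken by larger overlap and then term, so the output
#' is fully deterministic regardless of library set order.
#'
#' The universe defaults to the library's own universe (the union of its
#' members when none was supplied explicitly) so an analysis is
#' self-contained; pass the master metadata entity list to widen the
#' background. With a user universe, set members outside it are likewise
#' excluded from the contingency tables.
#'
#' @param input character vector of input drug tokens.
#' @param lib a [DrugSetLibrary-class].
#' @param universe optional explicit background token set.
#' @param alternative \code{"greater"} (enrichment; default, the gene-set
#'   analysis convention) or \code{"two.sided"} (via
#'   \code{stats::fisher.test}).
#' @param provenance free-text description of the input recorded in the
#'   report.
#' @return an [EnrichmentReport-class].
#' @examples
#' lib <- DrugSetLibrary(list(t1 = c("a", "b", "c", "d", "e"),
#'                            t2 = c("d", "e", "f", "g", "h")))
#' as.data.frame(enrichDrugs(c("a", "b", "c"), lib))
#' @export
enrichDrugs <- function(input, lib, universe = NULL,
                        alternative = c("greater", "two.sided"),
                        provenance = "") {
    stopifnot(is(lib, "DrugSetLibrary"))
    alternative <- match.arg(alternative)
    input <- unique(as.character(input))
    if (is.null(universe)) universe <- lib@universe
    universe <- unique(as.character(universe))
    N <- length(universe)

    inputIn <- intersect(input, universe)
    nDropped <- length(input) - length(inputIn)
    if (nDropped > 0L)
        message(sprintf("%d input member(s) outside the universe dropped", nDropped))
    if (length(inputIn) == 0L)
        stop("no resolvable overlap with universe: every input member is outside the background")

    terms <- names(lib@sets)
    nIn <- length(inputIn)
    rows <- lapply(seq_along(lib@sets), function(i) {
        set <- intersect(lib@sets[[i]], universe)
        ov <- intersect(inputIn, set)
        list(term = terms[i], a = length(ov), setSize = length(set), overlap = ov)
    })
    a <- vapply(rows, `[[`, 0L, "a")
    setSize <- vapply(rows, `[[`, 0L, "setSize")
    b <- nIn - a
    cc <- setSize - a
    d <- N - a - b - cc

    if (alternative == "greater") {
        p <- fisherExactGreater(a, b, cc, d)
    } else {
        p <- vapply(seq_along(a), function(i) {
            stats::fisher.test(matrix(c(a[i], b[i], cc[i], d[i]), 2L),
                alternative = "two.sided")$p.value
        }, numeric(1))
        p <- pmin(p, 1)
    }
    q <- if (length(p)) bhAdjust(p) else numeric()
    or <- oddsRatio(a, b, cc, d)

    res <- data.frame(term = terms, n_overlap = a, set_size = setSize,
        input_size = rep(nIn, length(a)), universe_size = rep(N, length(a)),
        p_value = p, q_value = q, odds_ratio = or, stringsAsFactors = FALSE)
    res$overlap_members <- lapply(rows, `[[`, "overlap")
    ord <- order(res$p_value, -res$n_overlap, res$term, method = "radix")
    res <- res[ord, , drop = FALSE]
    rownames(res) <- NULL

    new("EnrichmentReport", results = res, libraryName = lib@name,
        universeSize = as.integer(N), inputSize = as.integer(nIn),
        nDroppedInput = as.integer(nDropped),
        provenance = as.character(provenance))
}

#' Write an enrichment report as TSV
#'
#' Columns: term, n_overlap, set_size, input_size, universe_size, p_value,
#' q_value, odds_ratio, overlap_members (\code{;}-joined).
#'
#' @param report an [EnrichmentReport-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeEnrichmentTSV <- function(report, path) {
    stopifnot(is(report, "EnrichmentReport"))
    df <- report@results
    df$overlap_members <- vapply(df$overlap_members, paste, "", collapse = ";")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
        row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}
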