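# Seeded synthetic-data generators: a no-download test surface with known
# ground truth for every other module. Each generator is a pure function
# of its arguments — identical seeds give bitwise-identical outputs.

#' Random drug set library
#'
#' Draws \code{nTerms} sets uniformly from a universe of \code{nDrugs}
#' tokens, with sizes uniform in \code{setSizeRange}.
#'
#' @param nDrugs universe size (default 500).
#' @param nTerms number of sets (default 100; 0 gives an empty library
#'   over the full universe).
#' @param setSizeRange inclusive (min, max) set size (default c(5, 50));
#'   the max must not exceed \code{nDrugs}.
#' @param seed integer seed.
#' @param name library name.
#' @return a [DrugSetLibrary-class] whose universe is all \code{nDrugs}
#'   tokens.
#' @export
synthLibrary <- function(nDrugs = 500L, nTerms = 100L,
                         setSizeRange = c(5L, 50L), seed = 1L,
                         name = "synthetic") {
    stopifnot(nDrugs >= 1L, nTerms >= 0L, length(setSizeRange) == 2L,
        setSizeRange[1L] >= 1L)
    if (setSizeRange[2L] > nDrugs)
        stop("set size range exceeds the universe size")
    universe <- sprintf("drug_%05d", seq_len(nDrugs))
    sets <- withr::with_seed(seed, {
        out <- list()
        for (t in seq_len(nTerms)) {
            sz <- sample(seq(setSizeRange[1L], setSizeRange[2L]), 1L)
            out[[sprintf("term_%04d", t)]] <- sample(universe, sz)
        }
        out
    })
    DrugSetLibrary(sets, name = name, universe = universe)
}

#' Input drug set with a planted enrichment
#'
#' Builds an input of \code{inputSize} tokens of which
#' \code{ceiling(overlapFraction * inputSize)} are drawn from the chosen
#' term's set and the remainder uniformly from the rest of the universe,
#' so the term's true overlap is known by construction.
#'
#' @param lib a [DrugSetLibrary-class].
#' @param term the planted term (must exist in \code{lib}).
#' @param overlapFraction fraction of the input taken from the term's set,
#'   in [0, 1].
#' @param inputSize total input size (at most the universe size).
#' @param seed integer seed.
#' @return character vector of input tokens.
#' @export
synthEnrichedInput <- function(lib, term, overlapFraction = 0.8,
                               inputSize = 20L, seed = 1L) {
    stopifnot(is(lib, "DrugSetLibrary"),
        overlapFraction >= 0, overlapFraction <= 1)
    if (!term %in% names(lib@sets)) stop(sprintf("no term '%s' in library", term))
    if (inputSize > length(lib@universe))
        stop("inputSize exceeds the universe size")
    set <- lib@sets[[term]]
    nPlanted <- ceiling(overlapFraction * inputSize)
    if (nPlanted > length(set))
        stop(sprintf("term '%s' has only %d members; cannot plant %d",
            term, length(set), nPlanted))
    withr::with_seed(seed, {
        planted <- sample(set, nPlanted)
        rest <- setdiff(lib@universe, set)
        filler <- sample(rest, inputSize - nPlanted)
        sample(c(planted, filler))
    })
}

#' Independent screens sharing planted mechanism terms
#'
#' Emulates the structure of a multi-screen meta-analysis: each screen's
#' hit list independently samples members of the same planted mechanism
#' terms plus uniform filler, so the screens share enrichment signal while
#' their pairwise hit overlap stays low. Screens whose pairwise Jaccard
#' similarity with an earlier screen reaches \code{maxJaccard} are
#' resampled (logged via message); exceeding \code{maxResample} attempts
#' is an error.
#'
#' @param lib a [DrugSetLibrary-class].
#' @param plantedTerms terms shared by all screens.
#' @param screenCount number of screens (>= 2; default 12).
#' @param inputSize hits per screen (default 30).
#' @param overlapFraction total fraction of each screen drawn from the
#'   planted term sets (split evenly across them; default 0.5, keeping
#'   pairwise hit overlap low while sharing mechanism-level signal).
#' @param maxJaccard pairwise Jaccard bound enforced by construction
#'   (default 0.2).
#' @param seed integer seed.
#' @param maxResample resampling budget (default 100).
#' @return named list of hit-list character vectors (screen_01, ...).
#' @export
synthScreens <- function(lib, plantedTerms, screenCount = 12L,
                         inputSize = 30L, overlapFraction = 0.5,
                         maxJaccard = 0.2, seed = 1L, maxResample = 100L) {
    stopifnot(is(lib, "DrugSetLibrary"), screenCount >= 2L,
        length(plantedTerms) >= 1L)
    missing <- setdiff(plantedTerms, names(lib@sets))
    if (length(missing))
        stop(sprintf("planted term(s) not in library: %s",
            paste(missing, collapse = ", ")))
    nPer <- ceiling(overlapFraction * inputSize / length(plantedTerms))
    for (tm in plantedTerms)
        if (nPer > length(lib@sets[[tm]]))
            stop(sprintf("term '%s' too small to plant %d hits per screen",
                tm, nPer))
    plantedUnion <- unique(unlist(lib@sets[plantedTerms], use.names = FALSE))
    filler <- setdiff(lib@universe, plantedUnion)
    nFill <- inputSize - nPer * length(plantedTerms)
    if (nFill < 0L) stop("overlapFraction and inputSize are inconsistent")
    if (nFill > length(filler)) stop("universe too small for the filler draw")

    withr::with_seed(seed, {
        screens <- list()
        resamples <- 0L
        drawOne <- function() {
            hits <- unlist(lapply(plantedTerms, function(tm)
                sample(lib@sets[[tm]], nPer)), use.names = FALSE)
            unique(c(hits, sample(filler, nFill)))
        }
        for (s in seq_len(screenCount)) {
            repeat {
                cand <- drawOne()
                ok <- all(vapply(screens, function(prev) {
                    length(intersect(cand, prev)) /
                        length(union(cand, prev)) < maxJaccard
                }, logical(1)))
                if (ok) break
                resamples <- resamples + 1L
                message(sprintf("screen %d resampled (Jaccard >= %.2f)",
                    s, maxJaccard))
                if (resamples > maxResample)
                    stop("infeasible Jaccard constraint: resampling budget exhausted")
            }
            screens[[sprintf("screen_%02d", s)]] <- cand
        }
        screens
    })
}

# Synthetic 27-character InChIKey-shaped row keys (labelled synthetic;
# they index rows, they do not encode structures).
.synthKeys <- function(n) {
    block <- function(k) paste(sample(LETTERS, k, replace = TRUE), collapse = "")
    keys <- character(n)
    for (i in seq_len(n))
        keys[i] <- paste(block(14L), block(10L), block(1L), sep = "-")
    while (anyDuplicated(keys)) {
        dup <- which(duplicated(keys))
        for (i in dup) keys[i] <- paste(block(14L), block(10L), block(1L), sep = "-")
    }
    keys
}

#' Synthetic drug-attribute learning dataset
#'
#' Emulates the shape of an expression + fingerprint learning problem at
#' desk scale: an expression block of \code{nExpr} columns distributed
#' Normal(0, \code{noiseSd}) with a mean shift of \code{exprShift} on the
#' informative columns for positives, and a binary fingerprint block of
#' \code{nFp} columns with Bernoulli rate \code{bitRateNeg} elevated to
#' \code{bitRatePos} on the informative bits for positives. Labels are
#' assigned at the stated prevalence. The defaults (2000 compounds, 200
#' expression columns, 256 bits, prevalence 0.011) reproduce the heavy
#' class imbalance of a realistic side-effect prediction task.
#'
#' @param nCompounds number of compounds (default 2000).
#' @param nExpr expression columns (default 200; the full-scale shape is
#'   978).
#' @param nFp fingerprint bits (default 256; the full-scale shape is
#'   2048).
#' @param prevalence positive fraction in (0, 0.5] (default 0.011).
#' @param nInformativeExpr,nInformativeBits informative columns per block
#'   (default 16 each; 0 removes that block's signal).
#' @param exprShift positive-class mean shift on informative expression
#'   columns (default 1).
#' @param bitRatePos,bitRateNeg Bernoulli rates for informative bits in
#'   positives / all other cells (defaults 0.35 / 0.05).
#' @param noiseSd expression noise standard deviation (default 1; 0 with
#'   a nonzero shift gives a perfectly separable dataset).
#' @param nFolds stratification requirement: \code{prevalence *
#'   nCompounds} must be at least this many positives (default 10).
#' @param seed integer seed.
#' @return list with \code{features} (a [FeatureSpace-class] with blocks
#'   \code{expression} and \code{fingerprints}, keyed by synthetic
#'   InChIKey-shaped tokens), \code{labels} (named 0/1 vector), and
#'   \code{recipe} (the full generative configuration).
#' @export
synthMlDataset <- function(nCompounds = 2000L, nExpr = 200L, nFp = 256L,
                           prevalence = 0.011, nInformativeExpr = 16L,
                           nInformativeBits = 16L, exprShift = 1,
                           bitRatePos = 0.35, bitRateNeg = 0.05,
                           noiseSd = 1, nFolds = 10L, seed = 1L) {
    stopifnot(prevalence > 0, prevalence <= 0.5,
        nInformativeBits <= nFp, nInformativeExpr <= nExpr)
    nPos <- round(prevalence * nCompounds)
    if (nPos < nFolds)
        stop(sprintf(
            "unstratifiable: %d positives at this prevalence but %d folds",
            nPos, nFolds))
    withr::with_seed(seed, {
        keys <- .synthKeys(nCompounds)
        labels <- integer(nCompounds)
        labels[sample(nCompounds, nPos)] <- 1L
        pos <- labels == 1L

        expr <- matrix(stats::rnorm(nCompounds * nExpr, sd = noiseSd),
            nCompounds, nExpr)
        infExpr <- seq_len(nInformativeExpr)
        if (nInformativeExpr > 0L)
            expr[pos, infExpr] <- expr[pos, infExpr] + exprShift
        colnames(expr) <- sprintf("gene_%03d", seq_len(nExpr))

        fp <- matrix(stats::rbinom(nCompounds * nFp, 1L, bitRateNeg),
            nCompounds, nFp)
        infBits <- seq_len(nInformativeBits)
        if (nInformativeBits > 0L)
            fp[pos, infBits] <- stats::rbinom(sum(pos) * nInformativeBits,
                1L, bitRatePos)
        colnames(fp) <- sprintf("bit_%04d", seq_len(nFp) - 1L)

        rownames(expr) <- keys
        rownames(fp) <- keys
        fs <- assembleFeatures(list(expression = expr, fingerprints = fp))
        names(labels) <- keys
        attr(labels, "positiveSource") <- "synthetic_planted"
        attr(labels, "nUnmatchedPositives") <- 0L
        list(features = fs, labels = labels,
            recipe = list(nCompounds = nCompounds, nExpr = nExpr, nFp = nFp,
                prevalence = prevalence, nPos = nPos,
                nInformativeExpr = nInformativeExpr,
                nInformativeBits = nInformativeBits, exprShift = exprShift,
                bitRatePos = bitRatePos, bitRateNeg = bitRateNeg,
                noiseSd = noiseSd, seed = seed))
    })
}

#' Synthetic per-drug signatures with planted term associations
#'
#' Planted (drug, term) pairs receive up-sets containing 80% of the
#' term's genes plus uniform noise genes; all other up/down sets are
#' uniform draws. Down sets never overlap the same drug's up set.
#'
#' @param nDrugs number of drugs.
#' @param geneUniverseSize size of the gene universe (must cover the
#'   largest term set).
#' @param termSets named list of gene sets (term -> genes).
#' @param planted data.frame with columns \code{drug} (index or token) and
#'   \code{term}, or NULL for a pure-noise collection.
#' @param sigSize genes per signature direction (default 30).
#' @param seed integer seed.
#' @return list with \code{signatures} (a [SignatureCollection-class]),
#'   \code{geneUniverse}, and \code{drugs} (the drug tokens).
#' @export
synthSignatures <- function(nDrugs, geneUniverseSize, termSets,
                            planted = NULL, sigSize = 30L, seed = 1L) {
    termSets <- lapply(termSets, function(g) unique(toupper(g)))
    maxTerm <- max(vapply(termSets, length, 0L))
    if (geneUniverseSize < maxTerm)
        stop("gene universe smaller than the largest term set")
    genes <- sprintf("G%05d", seq_len(geneUniverseSize))
    drugs <- sprintf("sdrug_%04d", seq_len(nDrugs))
    if (!is.null(planted)) {
        planted <- as.data.frame(planted)
        if (is.numeric(planted$drug)) planted$drug <- drugs[planted$drug]
        if (!all(planted$term %in% names(termSets)))
            stop("planted pair references an unknown term")
        if (!all(planted$drug %in% drugs))
            stop("planted pair references an unknown drug")
    }
    withr::with_seed(seed, {
        # term sets outside the universe are remapped onto it by a seeded
        # uniform draw of the same size
        termSets <- lapply(termSets, function(g)
            if (all(g %in% genes)) g else sample(genes, length(g)))
        up <- list(); down <- list()
        for (d in drugs) {
            pterms <- if (is.null(planted)) character() else
                planted$term[planted$drug == d]
            core <- character()
            for (tm in pterms) {
                tg <- termSets[[tm]]
                core <- union(core, sample(tg, ceiling(0.8 * length(tg))))
            }
            nNoise <- max(0L, sigSize - length(core))
            upSet <- union(core, sample(setdiff(genes, core), nNoise))
            downSet <- sample(setdiff(genes, upSet), sigSize)
            up[[d]] <- upSet
            down[[d]] <- downSet
        }
        list(signatures = SignatureCollection(up = up, down = down),
            geneUniverse = genes, drugs = drugs)
    })
}

#' Path to the packaged drug fixture table
#'
#' A curated TSV of ~50 well-known approved drugs with names, complete
#' InChIKeys, canonical SMILES, synonyms and DrugBank/Broad
#' cross-references, used as a realistic small metadata table and SMILES
#' source in examples and tests.
#'
#' @return file path of the fixture TSV.
#' @export
drugFixturePath <- function() {
    system.file("extdata", "drug_fixture_table.tsv", package = "drugsets",
        mustWork = TRUE)
}

#' SMILES table of the packaged drug fixtures
#'
#' @return data.frame (token = InChIKey, smiles) for all fixture drugs.
#' @export
drugFixtureSmiles <- function() {
    df <- utils::read.delim(drugFixturePath(), sep = "\t",
        colClasses = "character", check.names = FALSE)
    data.frame(token = df$inchikey, smiles = df$smiles,
        stringsAsFactors = FALSE)
}
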