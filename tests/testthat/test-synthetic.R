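test_that("generators are pure functions of their seed", {
    l1 <- synthLibrary(nDrugs = 60, nTerms = 12, setSizeRange = c(4, 9),
        seed = 8)
    l2 <- synthLibrary(nDrugs = 60, nTerms = 12, setSizeRange = c(4, 9),
        seed = 8)
    expect_identical(setMembers(l1), setMembers(l2))
    s1 <- synthScreens(l1, setTerms(l1)[1L], screenCount = 3,
        inputSize = 8, overlapFraction = 0.5, seed = 2)
    s2 <- synthScreens(l1, setTerms(l1)[1L], screenCount = 3,
        inputSize = 8, overlapFraction = 0.5, seed = 2)
    expect_identical(s1, s2)
    d1 <- synthMlDataset(nCompounds = 120, nExpr = 10, nFp = 16,
        prevalence = 0.2, nInformativeExpr = 4, nInformativeBits = 4,
        seed = 3)
    d2 <- synthMlDataset(nCompounds = 120, nExpr = 10, nFp = 16,
        prevalence = 0.2, nInformativeExpr = 4, nInformativeBits = 4,
        seed = 3)
    expect_identical(featureMatrix(d1$features), featureMatrix(d2$features))
    expect_identical(d1$labels, d2$labels)
    g1 <- synthSignatures(5, 200, list(T1 = sprintf("G%05d", 1:20)),
        seed = 4)
    g2 <- synthSignatures(5, 200, list(T1 = sprintf("G%05d", 1:20)),
        seed = 4)
    expect_identical(signatureGenes(g1$signatures, "up"),
        signatureGenes(g2$signatures, "up"))
})

test_that("library generation respects sizes and validates arguments", {
    lib <- synthLibrary(nDrugs = 50, nTerms = 20, setSizeRange = c(3, 7),
        seed = 5)
    expect_true(all(setSizes(lib) >= 3 & setSizes(lib) <= 7))
    expect_length(drugUniverse(lib), 50L)
    expect_equal(nSets(synthLibrary(nTerms = 0, seed = 1)), 0L)
    expect_error(synthLibrary(nDrugs = 10, setSizeRange = c(5, 20)),
        "universe")
})

test_that("planted input composition matches the requested overlap", {
    lib <- synthLibrary(nDrugs = 200, nTerms = 10, setSizeRange = c(20, 30),
        seed = 9)
    term <- setTerms(lib)[1L]
    inp <- synthEnrichedInput(lib, term, overlapFraction = 1,
        inputSize = length(setMembers(lib, term)), seed = 2)
    expect_setequal(inp, setMembers(lib, term))
    # fraction 0: expected overlap is the hypergeometric mean
    set.seed(31)
    ovs <- vapply(1:200, function(i) {
        x <- synthEnrichedInput(lib, term, overlapFraction = 0,
            inputSize = 20, seed = 1000 + i)
        length(intersect(x, setMembers(lib, term)))
    }, numeric(1))
    expect_equal(mean(ovs), 0, tolerance = 1e-12)  # filler avoids the set
    inp8 <- synthEnrichedInput(lib, term, 0.8, 20, seed = 3)
    expect_equal(length(intersect(inp8, setMembers(lib, term))), 16L)
    expect_error(synthEnrichedInput(lib, term, 0.5, 1000, seed = 1),
        "universe")
    expect_error(synthEnrichedInput(lib, "nope", 0.5, 10, seed = 1), "nope")
})

test_that("the planted term attains the library-minimum p-value", {
    lib <- synthLibrary(nDrugs = 500, nTerms = 100,
        setSizeRange = c(20, 50), seed = 1)
    term <- setTerms(lib)[1L]
    inp <- synthEnrichedInput(lib, term, 0.8, 20, seed = 1)
    df <- as.data.frame(enrichDrugs(inp, lib))
    expect_equal(df$term[1L], term)
    # cross-check the winning p against the independent tail oracle
    a <- df$n_overlap[1L]; b <- df$input_size[1L] - a
    cc <- df$set_size[1L] - a
    d <- df$universe_size[1L] - a - b - cc
    expect_equal(df$p_value[1L], hyperTailOracle(a, b, cc, d),
        tolerance = 1e-12)
})

test_that("synthetic screens keep pairwise Jaccard under the bound", {
    lib <- synthLibrary(nDrugs = 500, nTerms = 50, setSizeRange = c(30, 50),
        seed = 14)
    scr <- suppressMessages(synthScreens(lib, setTerms(lib)[1:2], seed = 14))
    expect_length(scr, 12L)
    jac <- overlapMatrix(scr)$jaccard
    expect_true(all(jac[upper.tri(jac)] < 0.2))
    # minimal case runs
    s2 <- synthScreens(lib, setTerms(lib)[1L], screenCount = 2,
        inputSize = 20, seed = 3)
    expect_length(s2, 2L)
})

test_that("ml dataset shapes, prevalence and stratifiability guard hold", {
    ds <- synthMlDataset(nCompounds = 1000, nExpr = 15, nFp = 32,
        prevalence = 0.011, nInformativeExpr = 5, nInformativeBits = 5,
        seed = 6)
    expect_equal(sum(ds$labels), round(0.011 * 1000))
    expect_equal(dim(featureMatrix(ds$features)), c(1000L, 47L))
    expect_true(all(grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$",
        rowKeys(ds$features))))
    expect_true(all(featureBlocks(ds$features)$fingerprints %in% c(0, 1)))
    expect_error(synthMlDataset(nCompounds = 200, prevalence = 0.011),
        "unstratifiable")
    expect_equal(ds$recipe$prevalence, 0.011)
})

test_that("separable and null ml datasets bracket classifier behaviour", {
    sep <- synthMlDataset(nCompounds = 400, nExpr = 20, nFp = 32,
        prevalence = 0.1, exprShift = 3, noiseSd = 0, seed = 7)
    p <- crossValPredict(modelSpec("logistic_regression"), sep$features,
        sep$labels, cvConfig(5, 1, seed = 7))
    expect_equal(evaluatePredictions(p, sep$labels)$auroc, 1)
    null <- synthMlDataset(nCompounds = 400, nExpr = 20, nFp = 32,
        prevalence = 0.2, nInformativeExpr = 0, nInformativeBits = 0,
        seed = 8)
    pn <- crossValPredict(modelSpec("logistic_regression"), null$features,
        null$labels, cvConfig(5, 1, seed = 8))
    ev <- evaluatePredictions(pn, null$labels)$auroc
    expect_gt(ev, 0.4); expect_lt(ev, 0.6)
})

test_that("synthetic signatures plant recoverable associations", {
    termSets <- list(T1 = sprintf("G%05d", 1:40))
    ss <- synthSignatures(nDrugs = 10, geneUniverseSize = 1000,
        termSets = termSets, planted = data.frame(drug = 1, term = "T1"),
        sigSize = 40, seed = 10)
    genes <- signatureGenes(ss$signatures, "up")[[ss$drugs[1L]]]
    expect_gte(length(intersect(genes, termSets$T1)), 32L)   # >= 80%
    expect_error(synthSignatures(5, 20, termSets, seed = 1), "universe")
})

test_that("null signature collections survive the significance filter empty", {
    termSets <- stats::setNames(lapply(1:4, function(i)
        sprintf("G%05d", ((i - 1) * 40 + 1):(i * 40))), paste0("GO_", 1:4))
    emptyCount <- 0L
    for (s in 1:20) {
        ss <- synthSignatures(nDrugs = 15, geneUniverseSize = 1000,
            termSets = termSets, planted = NULL, seed = 500 + s)
        lib <- signatureLibrary(ss$signatures, termSets, ss$geneUniverse,
            direction = "up", qThreshold = 0.01, minSize = 1)
        if (nSets(lib) == 0L) emptyCount <- emptyCount + 1L
    }
    expect_gte(emptyCount, 19L)       # >= 95% of seeds
})

test_that("the packaged fixture table is well-formed", {
    df <- utils::read.delim(drugFixturePath(), colClasses = "character")
    expect_gte(nrow(df), 50L)
    expect_true(all(grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", df$inchikey)))
    expect_false(anyDuplicated(df$inchikey) > 0)
    # the two reference identities
    expect_equal(df$inchikey[df$name == "Cyclobenzaprine"],
        "JURKNVYFZMSNLP-UHFFFAOYSA-N")
    expect_equal(df$brd[df$name == "Cyclobenzaprine"], "BRD-K42348709")
    expect_equal(df$inchikey[df$name == "Amitriptyline"],
        "KRMDCWKBEZIMAB-UHFFFAOYSA-N")
    expect_equal(df$brd[df$name == "Amitriptyline"], "BRD-K53737926")
    # every SMILES parses
    fp <- maccsFingerprints(drugFixtureSmiles())
    expect_equal(nrow(fingerprintFailures(fp)), 0L)
})
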