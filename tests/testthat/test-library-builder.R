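test_that("MACCS fingerprints expose exactly 166 key positions", {
    fp <- maccsFingerprints(c(benzene = "c1ccccc1", ethanol = "CCO"))
    expect_s4_class(fp, "FingerprintMatrix")
    expect_equal(ncol(fingerprintBits(fp)), 166L)
    expect_equal(fp@nBits, 166L)
    # aromatic benzene sets at least one structural key; H2 sets none of
    # the heavy-atom keys benzene sets
    bits <- fingerprintBits(fp)
    expect_gte(sum(bits["benzene" == rowKeys(fp), ]), 1)
    fp2 <- maccsFingerprints(c(h2 = "[H][H]", benzene = "c1ccccc1"))
    b2 <- fingerprintBits(fp2)
    expect_gt(sum(b2[2L, ]), sum(b2[1L, ]))
})

test_that("unparseable SMILES are routed to failures, all-invalid errors", {
    fp <- maccsFingerprints(c(ok = "CCO", bad = "xx(("))
    expect_equal(rowKeys(fp), "ok")
    expect_equal(fingerprintFailures(fp)$input, "bad")
    expect_error(maccsFingerprints(c(bad = "xx((")), "no valid structures")
    expect_error(maccsFingerprints(data.frame(token = character(),
        smiles = character())), "empty")
})

test_that("circular fingerprints default to radius 4 and 2048 bits", {
    fp <- morganFingerprints(c(ethanol = "CCO", benzene = "c1ccccc1",
        ethanol2 = "CCO"))
    expect_equal(fp@nBits, 2048L)
    bits <- fingerprintBits(fp)
    expect_equal(bits[1L, ], bits[3L, ])            # identical structures
    expect_false(all(bits[1L, ] == bits[2L, ]))     # different structures
    fp64 <- morganFingerprints(c(e = "CCO"), radius = 2, nBits = 64)
    expect_equal(ncol(fingerprintBits(fp64)), 64L)
})

test_that("fingerprint libraries group molecules sharing a bit", {
    m <- matrix(c(1, 1, 1,
                  0, 0, 1), ncol = 2,
        dimnames = list(c("r1", "r2", "r3"), NULL))
    fp <- customFingerprints(m)
    lib <- fingerprintLibrary(fp, minSize = 2)
    expect_equal(nSets(lib), 1L)
    expect_setequal(setMembers(lib, setTerms(lib)), c("r1", "r2", "r3"))
    expect_setequal(drugUniverse(lib), c("r1", "r2", "r3"))
    # minSize 1 keeps both bits; an all-zero matrix gives an empty library
    expect_equal(nSets(fingerprintLibrary(fp, minSize = 1)), 2L)
    zero <- customFingerprints(matrix(0, 3, 2,
        dimnames = list(c("a", "b", "c"), NULL)))
    expect_equal(nSets(fingerprintLibrary(zero, minSize = 1)), 0L)
})

test_that("membership in a bit set mirrors the fingerprint matrix exactly", {
    smi <- drugFixtureSmiles()
    fp <- maccsFingerprints(smi)
    lib <- fingerprintLibrary(fp, minSize = 1)
    bits <- fingerprintBits(fp)
    colnames(bits) <- sprintf("maccs_%d", seq_len(ncol(bits)))
    for (tm in setTerms(lib)) {
        expect_setequal(setMembers(lib, tm),
            rowKeys(fp)[bits[, tm] == 1])
    }
    # and at the default threshold every retained set has >= 5 members
    expect_true(all(setSizes(fingerprintLibrary(fp)) >= 5L))
})

test_that("custom key labels are honored and length-checked", {
    fp <- customFingerprints(matrix(1, 5, 2,
        dimnames = list(letters[1:5], NULL)))
    lib <- fingerprintLibrary(fp, keyLabels = c("ringA", "ringB"),
        minSize = 2)
    expect_setequal(setTerms(lib), c("ringA", "ringB"))
    expect_error(fingerprintLibrary(fp, keyLabels = "onlyone"), "label")
})

test_that("signature libraries keep planted term-drug pairs and drop noise", {
    termSets <- stats::setNames(lapply(1:5, function(i)
        sprintf("G%05d", ((i - 1) * 40 + 1):(i * 40))), paste0("GO_", 1:5))
    ss <- synthSignatures(nDrugs = 30, geneUniverseSize = 1000,
        termSets = termSets,
        planted = data.frame(drug = 1:8, term = "GO_1"), seed = 21)
    lib <- signatureLibrary(ss$signatures, termSets, ss$geneUniverse,
        direction = "up", qThreshold = 0.01, minSize = 5)
    expect_true("GO_1" %in% setTerms(lib))
    planted <- ss$drugs[1:8]
    expect_true(all(planted %in% setMembers(lib, "GO_1")))
    # independent oracle for one planted pair: direct Fisher p then BH
    genes <- signatureGenes(ss$signatures, "up")[[planted[1L]]]
    a <- length(intersect(genes, termSets$GO_1))
    p <- vapply(termSets, function(ts) {
        ov <- length(intersect(genes, ts))
        hyperTailOracle(ov, length(genes) - ov, length(ts) - ov,
            1000 - length(genes) - length(ts) + ov)
    }, numeric(1))
    expect_lte(bhOracle(p)[1L], 0.01)
    expect_gte(a, 0.8 * 40)
})

test_that("drugs with genes disjoint from all terms contribute to no set", {
    termSets <- list(GO_1 = sprintf("G%05d", 1:30))
    sig <- SignatureCollection(up = list(dx = sprintf("G%05d", 500:520)))
    lib <- signatureLibrary(sig, termSets, sprintf("G%05d", 1:1000),
        direction = "up", minSize = 1)
    expect_equal(nSets(lib), 0L)
})

test_that("disabling the threshold admits every overlapping pair", {
    termSets <- list(GO_1 = sprintf("G%05d", 1:30),
                     GO_2 = sprintf("G%05d", 31:60))
    sig <- SignatureCollection(up = list(
        d1 = sprintf("G%05d", c(1:3, 900:910)),
        d2 = sprintf("G%05d", c(31:32, 920:930)),
        d3 = sprintf("G%05d", 940:950)))
    lib <- signatureLibrary(sig, termSets, sprintf("G%05d", 1:1000),
        direction = "up", qThreshold = 1.0, minSize = 1)
    expect_setequal(setMembers(lib, "GO_1"), "d1")
    expect_setequal(setMembers(lib, "GO_2"), "d2")
})

test_that("up and down planted signals give disjoint associations", {
    termSets <- stats::setNames(lapply(1:4, function(i)
        sprintf("G%05d", ((i - 1) * 40 + 1):(i * 40))), paste0("GO_", 1:4))
    ssUp <- synthSignatures(nDrugs = 20, geneUniverseSize = 800,
        termSets = termSets,
        planted = data.frame(drug = 1:6, term = "GO_1"), seed = 31)
    libUp <- signatureLibrary(ssUp$signatures, termSets, ssUp$geneUniverse,
        direction = "up", minSize = 5)
    libDown <- signatureLibrary(ssUp$signatures, termSets, ssUp$geneUniverse,
        direction = "down", minSize = 5)
    if ("GO_1" %in% setTerms(libDown))
        expect_length(intersect(setMembers(libUp, "GO_1"),
            setMembers(libDown, "GO_1")), 0L)
    else
        expect_true(TRUE)
    # a drug with an empty direction set is skipped with a warning
    sigE <- new("SignatureCollection",
        up = list(dz = character()), down = list(dz = "G00001"))
    expect_warning(signatureLibrary(sigE, termSets,
        ssUp$geneUniverse, direction = "up", minSize = 1), "empty")
})
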