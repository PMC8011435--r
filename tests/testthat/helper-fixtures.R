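# Shared helpers: tiny in-code fixtures for the unit tests.

toyLibrary <- function() {
    DrugSetLibrary(
        list(alpha = c("a", "b", "c", "d", "e"),
             beta = c("d", "e", "f", "g", "h"),
             gamma = c("a", "f", "i", "j", "k")),
        descriptions = c("first", "", "third"),
        name = "toy")
}

# Minimal metadata TSV written to a temp file; returns the path.
writeToyMetadata <- function(extraRows = character()) {
    path <- tempfile(fileext = ".tsv")
    rows <- c(
        "name\tinchikey\tsmiles\tsynonyms\tdrugbank\tbrd",
        "Cyclobenzaprine\tJURKNVYFZMSNLP-UHFFFAOYSA-N\tCN(C)CCC=C1c2ccccc2C=Cc2ccccc21\tFlexeril\tDB00924\tBRD-K42348709",
        "Amitriptyline\tKRMDCWKBEZIMAB-UHFFFAOYSA-N\tCN(C)CCC=C1c2ccccc2CCc2ccccc21\tElavil\tDB00321\tBRD-K53737926",
        "Ethanol\tLFQSCWFLJHTTHZ-UHFFFAOYSA-N\tCCO\talcohol\tDB00898\t",
        extraRows)
    writeLines(rows, path)
    path
}

# Independent BH oracle: the direct step-up formula.
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    q <- pmin(1, rev(cummin(rev(ps * m / seq_len(m)))))
    out <- numeric(m)
    out[o] <- q
    out
}

# Independent hypergeometric tail oracle via log-binomials.
hyperTailOracle <- function(a, b, cc, d) {
    N <- a + b + cc + d; K <- a + cc; n <- a + b
    ks <- a:min(K, n)
    sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}
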