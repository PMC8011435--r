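Package: drugsets
Title: Drug Set Libraries, Enrichment Analysis and Drug Attribute Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building, reading and querying drug set libraries
    (tab-delimited DMT/GMT collections of term to drug-set associations),
    resolving heterogeneous small-molecule identifiers (names, InChIKeys,
    SMILES, DrugBank and Broad IDs) against a master metadata table,
    testing drug set enrichment with the one-sided Fisher's exact test and
    Benjamini-Hochberg correction, constructing structure-derived set
    libraries from MACCS and circular fingerprints and signature-derived
    libraries from per-drug up/down gene sets, consensus meta-analysis of
    enrichment across independent screens by cumulative -log10 p ranking,
    and an imbalance-aware machine-learning pipeline that ranks compounds
    for a predicted attribute by mean out-of-fold probability under
    repeated stratified cross-validation. Includes seeded synthetic-data
    generators with known ground truth for every component and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    ChemmineOB,
    ranger,
    e1071,
    glmnet,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
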