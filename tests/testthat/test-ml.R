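smallDataset <- function(seed = 5, n = 300, prevalence = 0.1, shift = 2) {
    synthMlDataset(nCompounds = n, nExpr = 20, nFp = 32,
        prevalence = prevalence, nInformativeExpr = 8, nInformativeBits = 8,
        exprShift = shift, seed = seed)
}

test_that("feature assembly inner-joins blocks and reports drops", {
    e <- matrix(rnorm(8), 4, 2,
        dimnames = list(c("k1", "k2", "k3", "k4"), NULL))
    f <- matrix(rep(0:1, 3), 3, 2, dimnames = list(c("k2", "k3", "k9"), NULL))
    fs <- assembleFeatures(list(expr = e, fp = f))
    expect_equal(rowKeys(fs), c("k2", "k3"))
    expect_equal(fs@dropped$expr, c("k1", "k4"))
    expect_equal(fs@dropped$fp, "k9")
    expect_equal(ncol(featureMatrix(fs)), 4L)
    # single block is an identity join
    fs1 <- assembleFeatures(list(expr = e))
    expect_equal(rowKeys(fs1), rownames(e))
    expect_error(assembleFeatures(list(
        a = matrix(0, 1, 1, dimnames = list("x", NULL)),
        b = matrix(0, 1, 1, dimnames = list("y", NULL)))), "empty")
})

test_that("an expression block plus a fingerprint block give the combined width", {
    e <- matrix(0, 3, 978, dimnames = list(c("k1", "k2", "k3"), NULL))
    f <- matrix(0, 3, 2048, dimnames = list(c("k1", "k2", "k3"), NULL))
    fs <- assembleFeatures(list(expression = e, fingerprints = f))
    expect_equal(ncol(featureMatrix(fs)), 3026L)
})

test_that("a drug set library can serve as a binary incidence block", {
    lib <- toyLibrary()
    fs <- assembleFeatures(list(sets = lib))
    m <- featureMatrix(fs)
    expect_equal(dim(m), c(length(drugUniverse(lib)), nSets(lib)))
    expect_true(all(m %in% c(0, 1)))
    expect_equal(unname(colSums(m)), unname(setSizes(lib)))
})

test_that("TF-IDF weighting follows the frozen formula with row L2 scaling", {
    m <- matrix(c(1, 1, 0,
                  0, 1, 1), ncol = 2)
    w <- tfidfNormalize(m)
    idf <- log((1 + 3) / (1 + 2)) + 1
    raw <- m * idf
    norms <- sqrt(rowSums(raw^2))
    expect_equal(w, raw / norms, tolerance = 1e-12)
    # a ubiquitous column gets the floor weight ln(1)+1 = 1
    mfull <- matrix(1, 4, 1)
    expect_equal(unique(as.vector(tfidfNormalize(mfull))), 1)
    # all-zero rows remain zero
    mz <- rbind(c(1, 0), c(0, 0))
    expect_equal(tfidfNormalize(mz)[2L, ], c(0, 0))
    expect_error(tfidfNormalize(matrix(c(0, 2), 1)), "binary")
})

test_that("labels derive from complete-InChIKey membership with errors on degenerate sets", {
    ds <- smallDataset()
    keys <- rowKeys(ds$features)
    lab <- makeLabels(ds$features, keys[1:5])
    expect_equal(sum(lab), 5L)
    expect_equal(names(lab), keys)
    expect_error(makeLabels(ds$features, keys), "negative")
    expect_error(makeLabels(ds$features, character()), "empty")
    expect_error(makeLabels(ds$features, "NOTAKEY"), "no positive")
    expect_message(makeLabels(ds$features, c(keys[1:5], "NOTAKEY")),
        "not present")
})

test_that("class weights are inverse frequency", {
    expect_equal(classWeights(c(rep(0, 50), rep(1, 50))),
        c("0" = 1, "1" = 1))
    w <- classWeights(c(rep(0, 90), rep(1, 10)))
    expect_equal(unname(w["1"]), 5)
    expect_equal(unname(w["0"]), 100 / 180)
    expect_equal(unname(w["1"] / w["0"]), 9)      # ratio = n_neg / n_pos
    expect_equal(classWeights(c(0, 1)), c("0" = 1, "1" = 1))
    expect_error(classWeights(c(1, 1)), "both classes")
})

test_that("out-of-fold predictions are complete and seed-deterministic", {
    ds <- smallDataset()
    cv <- cvConfig(nFolds = 5, nRepeats = 3, seed = 17)
    for (alg in c("extra_trees", "linear_svm")) {
        spec <- modelSpec(alg, if (alg == "extra_trees")
            list(n_estimators = 100L) else list())
        p1 <- crossValPredict(spec, ds$features, ds$labels, cv)
        # every drug predicted exactly nRepeats times out of fold
        expect_false(anyNA(attr(p1, "probMatrix")))
        expect_equal(dim(attr(p1, "probMatrix")),
            c(length(rowKeys(ds$features)), 3L))
        p2 <- crossValPredict(spec, ds$features, ds$labels, cv)
        expect_identical(p1$mean_probability, p2$mean_probability)
        expect_identical(p1$token, p2$token)
    }
})

test_that("a single repeat reports the single out-of-fold probability", {
    ds <- smallDataset()
    spec <- modelSpec("logistic_regression")
    p <- crossValPredict(spec, ds$features, ds$labels,
        cvConfig(5, 1, seed = 3))
    pm <- attr(p, "probMatrix")
    expect_equal(sort(p$mean_probability), unname(sort(pm[, 1L])))
})

test_that("constant features predict roughly the class prior", {
    n <- 400
    x <- matrix(1, n, 3, dimnames = list(sprintf("k%03d", 1:n), NULL))
    fs <- assembleFeatures(list(const = x))
    lab <- stats::setNames(c(rep(1L, 80), rep(0L, 320)), rowKeys(fs))
    spec <- modelSpec("extra_trees", list(n_estimators = 100L),
        classWeightMode = "none")
    p <- crossValPredict(spec, fs, lab, cvConfig(5, 1, seed = 2))
    expect_true(all(abs(p$mean_probability - 0.2) < 0.05))
})

test_that("stratification fails loudly when a fold would lose a class", {
    ds <- synthMlDataset(nCompounds = 100, nExpr = 10, nFp = 16,
        prevalence = 0.05, nInformativeExpr = 4, nInformativeBits = 4,
        nFolds = 5, seed = 1)                       # 5 positives
    spec <- modelSpec("logistic_regression")
    expect_error(crossValPredict(spec, ds$features, ds$labels,
        cvConfig(nFolds = 10, nRepeats = 1, seed = 1)), "stratification")
})

test_that("model specs validate hyperparameter keys per algorithm", {
    expect_error(modelSpec("logistic_regression", list(cost = 1)), "invalid")
    expect_error(modelSpec("extra_trees", list(criterion = "mse")),
        "criterion")
    expect_silent(modelSpec("extra_trees", list(n_estimators = 10L,
        max_features = "log2", criterion = "entropy")))
})

test_that("the default extra-trees grid contains the reference configuration", {
    g <- defaultGrid("extra_trees")
    expect_true(1250L %in% g$n_estimators)
    expect_true("log2" %in% g$max_features)
    expect_true("entropy" %in% g$criterion)
})

test_that("grid search evaluates exhaustively and selects by AUPRC", {
    ds <- smallDataset(n = 200, prevalence = 0.2)
    gs <- gridSearch(
        list(modelSpec("logistic_regression"), modelSpec("extra_trees")),
        ds$features, ds$labels, cvConfig(5, 1, seed = 4),
        grids = list(list(lambda = c(0.1, 1)),
            list(n_estimators = 50L, max_features = c("sqrt", "log2"))))
    expect_equal(nrow(gs$results), 4L)
    expect_equal(gs$best$mean_auprc, max(gs$results$mean_auprc))
    # a single spec with a single grid point returns that point
    one <- gridSearch(list(modelSpec("linear_svm")), ds$features,
        ds$labels, cvConfig(5, 1, seed = 4), grids = list(list(cost = 2)))
    expect_equal(one$best$spec$hyperparameters$cost, 2)
})

test_that("evaluation metrics behave at the extremes", {
    lab <- c(rep(0, 5), rep(1, 5))
    expect_equal(evaluatePredictions(seq(0.1, 1, 0.1), lab)$auroc, 1)
    expect_equal(evaluatePredictions(seq(1, 0.1, -0.1), lab)$auroc, 0)
    expect_warning(ev <- evaluatePredictions(rep(0.5, 10), lab),
        "degenerate")
    expect_equal(ev$auroc, 0.5)
    perfect <- evaluatePredictions(seq(0.1, 1, 0.1), lab)
    expect_equal(perfect$auprc, 1)
})

test_that("the midrank AUROC agrees with an established implementation", {
    skip_if_not_installed("pROC")
    set.seed(23)
    for (i in 1:5) {
        lab <- rbinom(60, 1, 0.3)
        if (sum(lab) %in% c(0, 60)) next
        sc <- rnorm(60) + lab
        ours <- evaluatePredictions(sc, lab)$auroc
        ref <- as.numeric(suppressMessages(pROC::auc(lab, sc,
            direction = "<")))
        expect_equal(ours, ref, tolerance = 1e-10)
    }
})

test_that("inverse-frequency weighting lifts recall at the prior threshold", {
    # weak-signal 1%-prevalence regime, where the unweighted model scores
    # part of the positive class below the prior
    recallPair <- function(seed) {
        ds <- synthMlDataset(nCompounds = 1500, nExpr = 30, nFp = 64,
            prevalence = 0.01, nInformativeExpr = 6, nInformativeBits = 6,
            exprShift = 0.3, bitRatePos = 0.15, seed = seed)
        cv <- cvConfig(5, 1, seed = seed)
        prior <- mean(ds$labels)
        recall <- function(p) {
            hit <- p$token[p$mean_probability > prior]
            mean(names(ds$labels)[ds$labels == 1L] %in% hit)
        }
        pw <- crossValPredict(modelSpec("logistic_regression",
            classWeightMode = "inverse_frequency"),
            ds$features, ds$labels, cv)
        pu <- crossValPredict(modelSpec("logistic_regression",
            classWeightMode = "none"), ds$features, ds$labels, cv)
        c(weighted = recall(pw), unweighted = recall(pu))
    }
    res <- vapply(41:45, recallPair, numeric(2))
    expect_true(all(res["weighted", ] >= res["unweighted", ]))
    expect_gt(mean(res["weighted", ]), mean(res["unweighted", ]))
})
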