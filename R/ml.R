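# Drug-attribute prediction: feature assembly, TF-IDF weighting, label
# derivation, imbalance-aware classifiers with grid search and repeated
# stratified cross-validation, and mean out-of-fold probability ranking.

.algorithms <- c("logistic_regression", "linear_svm", "random_forest",
    "extra_trees")

#' Assemble row-aligned feature blocks into a FeatureSpace
#'
#' Inner-joins the blocks on their row keys (complete InChIKeys by
#' convention): the result keeps the keys present in every block, in the
#' order of the first block, and records the keys each block lost. A
#' [DrugSetLibrary-class] may be supplied as a block; it is encoded as the
#' binary drug x term incidence matrix over its universe.
#'
#' @param blocks named list of numeric matrices with row names (or
#'   DrugSetLibrary objects).
#' @return a [FeatureSpace-class]. Empty key intersection is an error.
#' @examples
#' e <- matrix(rnorm(6), 3, 2, dimnames = list(c("k1", "k2", "k3"), NULL))
#' f <- matrix(0:5 %% 2, 3, 2, dimnames = list(c("k2", "k3", "k4"), NULL))
#' assembleFeatures(list(expr = e, fp = f))
#' @export
assembleFeatures <- function(blocks) {
    stopifnot(is.list(blocks), length(blocks) >= 1L)
    if (is.null(names(blocks)) || any(!nzchar(names(blocks))))
        stop("blocks must be named")
    mats <- lapply(blocks, function(b) {
        if (is(b, "DrugSetLibrary")) {
            inc <- vapply(b@sets, function(m) b@universe %in% m,
                logical(length(b@universe)))
            if (length(b@universe) == 1L) inc <- matrix(inc, nrow = 1L)
            rownames(inc) <- b@universe
            storage.mode(inc) <- "double"
            return(inc)
        }
        b <- as.matrix(b)
        if (is.null(rownames(b))) stop("every block needs row keys (rownames)")
        if (anyDuplicated(rownames(b))) stop("duplicate row keys in a block")
        b
    })
    common <- rownames(mats[[1L]])
    for (m in mats[-1L]) common <- common[common %in% rownames(m)]
    if (length(common) == 0L)
        stop("empty intersection of row keys across blocks")
    dropped <- lapply(mats, function(m) setdiff(rownames(m), common))
    aligned <- lapply(mats, function(m) {
        m <- m[common, , drop = FALSE]
        rownames(m) <- NULL
        m
    })
    names(aligned) <- names(blocks)
    names(dropped) <- names(blocks)
    new("FeatureSpace", rowKeys = common, blocks = aligned, dropped = dropped)
}

#' TF-IDF weighting of a binary feature block
#'
#' Downweights ubiquitous features (e.g. fingerprint bits set for most
#' compounds) with the smoothed inverse-document-frequency
#' \eqn{idf_j = \ln((1 + N)/(1 + df_j)) + 1}, where \eqn{N} is the number
#' of rows and \eqn{df_j} the number of ones in column \eqn{j}; the
#' weighted entries are \eqn{bit_{ij} \cdot idf_j} and each row is then
#' scaled to unit Euclidean norm (all-zero rows stay zero). A column
#' present in every row gets the floor weight \eqn{\ln 1 + 1 = 1}.
#'
#' @param block binary matrix (entries 0/1).
#' @return weighted numeric matrix of the same shape.
#' @export
tfidfNormalize <- function(block) {
    block <- as.matrix(block)
    if (length(block) && !all(block %in% c(0, 1)))
        stop("domain error: tfidfNormalize expects a binary matrix")
    n <- nrow(block)
    df <- colSums(block)
    idf <- log((1 + n) / (1 + df)) + 1
    w <- sweep(block, 2L, idf, `*`)
    norms <- sqrt(rowSums(w^2))
    nz <- norms > 0
    w[nz, ] <- w[nz, , drop = FALSE] / norms[nz]
    w
}

#' Derive a binary label vector from a positive drug set
#'
#' Label 1 iff a feature-space row key (a complete InChIKey) belongs to the
#' positive set; matching is exact over the complete key. The number of
#' positives that matched no row is reported as an attribute and a
#' message.
#'
#' @param fs a [FeatureSpace-class].
#' @param positives character vector of positive tokens, or a
#'   [DrugSetLibrary-class] set (supply \code{term}).
#' @param term when \code{positives} is a library, the term naming the
#'   positive set.
#' @param positiveSource label recorded for provenance.
#' @return named integer vector (0/1) aligned to \code{rowKeys(fs)}, with
#'   attributes \code{positiveSource} and \code{nUnmatchedPositives}.
#'   Zero matched positives, or zero negatives, is an error.
#' @export
makeLabels <- function(fs, positives, term = NULL,
                       positiveSource = "positives") {
    stopifnot(is(fs, "FeatureSpace"))
    if (is(positives, "DrugSetLibrary")) {
        if (is.null(term)) stop("supply the term naming the positive set")
        positiveSource <- term
        positives <- setMembers(positives, term)
    }
    positives <- unique(as.character(positives))
    if (length(positives) == 0L) stop("empty positive set")
    lab <- as.integer(fs@rowKeys %in% positives)
    nUnmatched <- sum(!positives %in% fs@rowKeys)
    if (sum(lab) == 0L) stop("no positive matched a feature-space row key")
    if (all(lab == 1L)) stop("positives cover every row: no negative class")
    if (nUnmatched > 0L)
        message(sprintf("%d positive token(s) not present in the feature space",
            nUnmatched))
    names(lab) <- fs@rowKeys
    attr(lab, "positiveSource") <- positiveSource
    attr(lab, "nUnmatchedPositives") <- nUnmatched
    lab
}

#' Inverse-frequency class weights
#'
#' \eqn{w_c = N / (2 \, n_c)}, so the positive:negative weight ratio equals
#' the negative:positive count ratio — the "balanced" weighting used to
#' counter class imbalance.
#'
#' @param labels binary vector with both classes present.
#' @return named numeric vector \code{c("0" = w0, "1" = w1)}.
#' @examples
#' classWeights(c(rep(0, 90), rep(1, 10)))
#' @export
classWeights <- function(labels) {
    labels <- as.integer(labels)
    n0 <- sum(labels == 0L); n1 <- sum(labels == 1L)
    if (n0 == 0L || n1 == 0L)
        stop("both classes must be present to compute class weights")
    n <- n0 + n1
    c("0" = n / (2 * n0), "1" = n / (2 * n1))
}

#' Cross-validation configuration
#'
#' @param nFolds number of stratified folds (default 10).
#' @param nRepeats number of repeats (default 3).
#' @param seed integer seed governing every fold assignment and fit.
#' @return validated list of class \code{cv_config}.
#' @export
cvConfig <- function(nFolds = 10L, nRepeats = 3L, seed = 1L) {
    stopifnot(nFolds >= 2L, nRepeats >= 1L)
    structure(list(nFolds = as.integer(nFolds),
        nRepeats = as.integer(nRepeats), seed = as.integer(seed)),
        class = "cv_config")
}

#' Classifier specification
#'
#' @param algorithm one of \code{logistic_regression} (ridge-penalized,
#'   via glmnet), \code{linear_svm} (via e1071), \code{random_forest} and
#'   \code{extra_trees} (via ranger; extra_trees uses totally random
#'   splits). Hyperparameter keys are validated per algorithm:
#'   \code{lambda} for logistic regression, \code{cost} for the SVM, and
#'   \code{n_estimators}, \code{max_features} (\code{"sqrt"},
#'   \code{"log2"} or a count/fraction) and \code{criterion}
#'   (\code{"gini"}/\code{"entropy"}, recorded in the run manifest) for
#'   the forests.
#' @param hyperparameters named list of single values.
#' @param classWeightMode \code{"inverse_frequency"} (default) or
#'   \code{"none"}.
#' @return validated list of class \code{model_spec}.
#' @export
modelSpec <- function(algorithm, hyperparameters = list(),
                      classWeightMode = c("inverse_frequency", "none")) {
    algorithm <- match.arg(algorithm, .algorithms)
    classWeightMode <- match.arg(classWeightMode)
    allowed <- switch(algorithm,
        logistic_regression = "lambda",
        linear_svm = "cost",
        random_forest = c("n_estimators", "max_features", "criterion"),
        extra_trees = c("n_estimators", "max_features", "criterion"))
    bad <- setdiff(names(hyperparameters), allowed)
    if (length(bad))
        stop(sprintf("invalid hyperparameter(s) for %s: %s", algorithm,
            paste(bad, collapse = ", ")))
    if (!is.null(hyperparameters$criterion) &&
        !hyperparameters$criterion %in% c("gini", "entropy"))
        stop("criterion must be 'gini' or 'entropy'")
    structure(list(algorithm = algorithm,
        hyperparameters = hyperparameters,
        classWeightMode = classWeightMode), class = "model_spec")
}

#' Default hyperparameter grid per algorithm
#'
#' The extra-trees default grid includes the configuration
#' \code{n_estimators = 1250, max_features = "log2",
#' criterion = "entropy"}.
#'
#' @param algorithm algorithm name.
#' @return named list of candidate value vectors.
#' @export
defaultGrid <- function(algorithm) {
    algorithm <- match.arg(algorithm, .algorithms)
    switch(algorithm,
        logistic_regression = list(lambda = c(0.01, 0.1, 1)),
        linear_svm = list(cost = c(0.1, 1, 10)),
        random_forest = list(n_estimators = c(250L, 1250L),
            max_features = c("sqrt", "log2"), criterion = c("gini", "entropy")),
        extra_trees = list(n_estimators = c(250L, 1250L),
            max_features = c("sqrt", "log2"), criterion = c("gini", "entropy")))
}

# Stratified fold assignment: within each class, a seeded shuffle then a
# round-robin split, so every fold keeps the class ratio (and >= 1
# positive whenever n_pos >= nFolds).
.stratifiedFolds <- function(labels, nFolds) {
    labels <- as.integer(labels)
    if (min(sum(labels == 0L), sum(labels == 1L)) < nFolds)
        stop("stratification error: a fold would contain no member of one class")
    fold <- integer(length(labels))
    for (cls in c(0L, 1L)) {
        idx <- sample(which(labels == cls))
        fold[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
    fold
}

.mtryValue <- function(maxFeatures, p) {
    if (is.null(maxFeatures)) return(max(1L, floor(sqrt(p))))
    if (is.character(maxFeatures))
        return(switch(maxFeatures,
            sqrt = max(1L, floor(sqrt(p))),
            log2 = max(1L, floor(log2(p))),
            stop("max_features must be 'sqrt', 'log2' or a number")))
    mf <- as.numeric(maxFeatures)
    if (mf <= 1) max(1L, floor(mf * p)) else min(p, as.integer(mf))
}

# Fit one classifier on a training split and return positive-class
# probabilities for the test split. Linear-SVM probabilities are a
# logistic transform of the decision values (monotone, so ranking and
# AUROC/AUPRC are those of the margin itself, and the output is
# deterministic).
.fitPredict <- function(spec, xtr, ytr, xte, seed) {
    if (is.null(colnames(xtr))) {
        colnames(xtr) <- paste0("f", seq_len(ncol(xtr)))
        colnames(xte) <- colnames(xtr)
    }
    hp <- spec$hyperparameters
    cw <- if (spec$classWeightMode == "inverse_frequency") classWeights(ytr)
        else c("0" = 1, "1" = 1)
    p <- ncol(xtr)
    switch(spec$algorithm,
        logistic_regression = {
            lambda <- if (is.null(hp$lambda)) 0.1 else hp$lambda
            fit <- glmnet::glmnet(xtr, factor(ytr, levels = c(0, 1)),
                family = "binomial", alpha = 0, lambda = lambda,
                weights = cw[as.character(ytr)], standardize = TRUE)
            as.numeric(stats::predict(fit, xte, type = "response"))
        },
        linear_svm = {
            cost <- if (is.null(hp$cost)) 1 else hp$cost
            fit <- e1071::svm(xtr, factor(ytr, levels = c(0, 1)),
                kernel = "linear", cost = cost, scale = FALSE,
                class.weights = cw)
            dvm <- attr(stats::predict(fit, xte, decision.values = TRUE),
                "decision.values")
            dv <- dvm[, 1L]
            # positive decision values point at the class named first in
            # the "a/b" column label; flip so larger always means class 1
            if (grepl("^0/", colnames(dvm)[1L])) dv <- -dv
            stats::plogis(dv)
        },
        random_forest = ,
        extra_trees = {
            nTrees <- if (is.null(hp$n_estimators)) 500L else
                as.integer(hp$n_estimators)
            mtry <- .mtryValue(hp$max_features, p)
            extra <- spec$algorithm == "extra_trees"
            fit <- ranger::ranger(x = xtr, y = factor(ytr, levels = c(0, 1)),
                num.trees = nTrees, mtry = mtry, probability = TRUE,
                splitrule = if (extra) "extratrees" else "gini",
                num.random.splits = 1L,
                replace = !extra,
                sample.fraction = if (extra) 1 else 0.632,
                class.weights = unname(cw), seed = seed,
                num.threads = 1L)
            stats::predict(fit, xte, num.threads = 1L)$predictions[, "1"]
        })
}

#' Out-of-fold predictions under repeated stratified cross-validation
#'
#' For each repeat, every drug is predicted exactly once by a model whose
#' training fold excluded it; the reported probability is the mean over
#' repeats. Fold assignment and all fits are seeded, so an identical
#' configuration yields an identical table.
#'
#' @param spec a [modelSpec()].
#' @param fs a [FeatureSpace-class].
#' @param labels binary vector from [makeLabels()].
#' @param cv a [cvConfig()].
#' @param names optional named character vector mapping row keys to
#'   display names.
#' @return data.frame (token, name, known, mean_probability) sorted by
#'   decreasing mean probability, with attributes \code{probMatrix}
#'   (n x nRepeats out-of-fold probabilities) and \code{folds} (n x
#'   nRepeats fold assignments).
#' @export
crossValPredict <- function(spec, fs, labels, cv = cvConfig(), names = NULL) {
    stopifnot(inherits(spec, "model_spec"), is(fs, "FeatureSpace"),
        inherits(cv, "cv_config"))
    x <- featureMatrix(fs)
    y <- as.integer(labels)
    stopifnot(length(y) == nrow(x))
    probs <- matrix(NA_real_, nrow(x), cv$nRepeats)
    folds <- matrix(NA_integer_, nrow(x), cv$nRepeats)
    withr::with_seed(cv$seed, {
        for (r in seq_len(cv$nRepeats)) {
            fold <- .stratifiedFolds(y, cv$nFolds)
            folds[, r] <- fold
            for (f in seq_len(cv$nFolds)) {
                te <- fold == f
                fitSeed <- (cv$seed * 1000L + r * 100L + f) %% .Machine$integer.max
                probs[te, r] <- .fitPredict(spec, x[!te, , drop = FALSE],
                    y[!te], x[te, , drop = FALSE], seed = fitSeed)
            }
        }
    })
    rownames(probs) <- fs@rowKeys
    rownames(folds) <- fs@rowKeys
    meanProb <- rowMeans(probs)
    nm <- if (is.null(names)) fs@rowKeys else
        ifelse(is.na(names[fs@rowKeys]), fs@rowKeys, names[fs@rowKeys])
    out <- data.frame(token = fs@rowKeys, name = nm,
        known = y == 1L, mean_probability = meanProb,
        stringsAsFactors = FALSE)
    out <- out[order(-out$mean_probability, out$token, method = "radix"), ,
        drop = FALSE]
    rownames(out) <- NULL
    attr(out, "probMatrix") <- probs
    attr(out, "folds") <- folds
    attr(out, "spec") <- spec
    out
}

#' Exhaustive grid search with stratified cross-validation
#'
#' Evaluates every hyperparameter combination of every specification with
#' one seeded stratified k-fold split (shared across combinations so the
#' comparison is paired), scoring each fold's held-out predictions by
#' AUROC and AUPRC. The primary model-selection criterion is mean AUPRC —
#' the metric that separates classifiers under heavy class imbalance —
#' with AUROC as tie-breaker and specification/grid order as the final,
#' deterministic tie-break.
#'
#' @param specs list of [modelSpec()] objects (grids may be attached by
#'   passing \code{grid = list(...)} entries in \code{grids}).
#' @param fs a [FeatureSpace-class].
#' @param labels binary vector from [makeLabels()].
#' @param cv a [cvConfig()] (its \code{nFolds}/\code{seed} are used; grid
#'   search uses a single repeat).
#' @param grids optional list, parallel to \code{specs}, of named lists of
#'   candidate value vectors; defaults to [defaultGrid()] per algorithm.
#' @return list with \code{results} (one data.frame row per grid point:
#'   algorithm, hyperparameters, mean/sd AUROC and AUPRC) and \code{best}
#'   (list: algorithm, hyperparameters as a [modelSpec()], metrics).
#' @export
gridSearch <- function(specs, fs, labels, cv = cvConfig(), grids = NULL) {
    stopifnot(is.list(specs), length(specs) >= 1L)
    if (is.null(grids))
        grids <- lapply(specs, function(s) defaultGrid(s$algorithm))
    stopifnot(length(grids) == length(specs))
    x <- featureMatrix(fs)
    y <- as.integer(labels)

    fold <- withr::with_seed(cv$seed, .stratifiedFolds(y, cv$nFolds))
    rows <- list(); candidates <- list()
    for (si in seq_along(specs)) {
        spec <- specs[[si]]
        grid <- grids[[si]]
        if (length(grid) == 0L) stop("empty grid for a specification")
        combos <- expand.grid(lapply(grid, function(v) seq_along(v)),
            KEEP.OUT.ATTRS = FALSE)
        for (gi in seq_len(nrow(combos))) {
            hp <- stats::setNames(lapply(names(grid), function(nm)
                grid[[nm]][[combos[gi, nm]]]), names(grid))
            candidate <- modelSpec(spec$algorithm, hp, spec$classWeightMode)
            perFold <- matrix(NA_real_, cv$nFolds, 2L,
                dimnames = list(NULL, c("auroc", "auprc")))
            for (f in seq_len(cv$nFolds)) {
                te <- fold == f
                fitSeed <- (cv$seed * 1000L + si * 100L + gi * 10L + f) %%
                    .Machine$integer.max
                pr <- .fitPredict(candidate, x[!te, , drop = FALSE], y[!te],
                    x[te, , drop = FALSE], seed = fitSeed)
                perFold[f, "auroc"] <- .auroc(pr, y[te])
                perFold[f, "auprc"] <- .averagePrecision(pr, y[te])
            }
            rows[[length(rows) + 1L]] <- data.frame(
                spec = si, algorithm = spec$algorithm,
                hyperparameters = .hpString(hp),
                mean_auroc = mean(perFold[, "auroc"]),
                sd_auroc = stats::sd(perFold[, "auroc"]),
                mean_auprc = mean(perFold[, "auprc"]),
                sd_auprc = stats::sd(perFold[, "auprc"]),
                stringsAsFactors = FALSE)
            candidates[[length(candidates) + 1L]] <- candidate
        }
    }
    results <- do.call(rbind, rows)
    bestIdx <- order(-results$mean_auprc, -results$mean_auroc,
        seq_len(nrow(results)))[1L]
    list(results = results,
        best = list(algorithm = results$algorithm[bestIdx],
            spec = candidates[[bestIdx]],
            mean_auroc = results$mean_auroc[bestIdx],
            mean_auprc = results$mean_auprc[bestIdx]))
}

.hpString <- function(hp) {
    if (length(hp) == 0L) return("")
    paste(sprintf("%s=%s", names(hp), vapply(hp, as.character, "")),
        collapse = ",")
}

# AUROC as the midrank U-statistic: ties contribute 1/2, so degenerate
# constant scores give exactly 0.5.
.auroc <- function(scores, labels) {
    labels <- as.integer(labels)
    nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
    if (nPos == 0L || nNeg == 0L) return(NA_real_)
    r <- rank(scores)
    (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

# Average precision (step-function area under the precision-recall
# curve): mean over positives of the precision at each positive's rank.
.averagePrecision <- function(scores, labels) {
    labels <- as.integer(labels)
    nPos <- sum(labels == 1L)
    if (nPos == 0L || all(labels == 1L)) return(NA_real_)
    ord <- order(-scores, seq_along(scores), method = "radix")
    y <- labels[ord]
    cumPos <- cumsum(y)
    precisionAt <- cumPos / seq_along(y)
    sum(precisionAt[y == 1L]) / nPos
}

#' Threshold-free evaluation of out-of-fold predictions
#'
#' @param preds a prediction table from [crossValPredict()] or a numeric
#'   probability vector aligned to \code{labels}.
#' @param labels binary vector.
#' @param folds optional fold assignment vector (or matrix, one column per
#'   repeat) for per-fold curve summaries; taken from the prediction
#'   table's attributes when available.
#' @return list with \code{auroc}, \code{auprc}, and when folds are known
#'   \code{per_fold} (fold-level AUROC/AUPRC) plus mean and sd summaries.
#'   Constant probabilities trigger a warning and give AUROC 0.5 by the
#'   midrank convention.
#' @export
evaluatePredictions <- function(preds, labels, folds = NULL) {
    if (is.data.frame(preds)) {
        if (is.null(folds)) folds <- attr(preds, "folds")
        probMat <- attr(preds, "probMatrix")
        if (is.null(names(labels)))
            stop("labels must be named by token (as returned by makeLabels)")
        labByToken <- as.integer(labels)
        names(labByToken) <- names(labels)
        labels <- unname(labByToken[preds$token])
        scores <- preds$mean_probability
    } else {
        scores <- as.numeric(preds)
        probMat <- NULL
        labByToken <- NULL
        labels <- as.integer(labels)
    }
    if (sum(labels == 1L) == 0L || sum(labels == 0L) == 0L)
        stop("both classes must be present")
    if (length(unique(scores)) == 1L)
        warning("degenerate predictions: all probabilities are equal")
    out <- list(auroc = .auroc(scores, labels),
        auprc = .averagePrecision(scores, labels))
    if (!is.null(folds)) {
        folds <- as.matrix(folds)
        foldLabels <- if (!is.null(probMat) && !is.null(labByToken))
            unname(labByToken[rownames(probMat)]) else labels
        rows <- list()
        for (r in seq_len(ncol(folds))) {
            sc <- if (!is.null(probMat)) probMat[, r] else scores
            for (f in sort(unique(folds[, r]))) {
                m <- folds[, r] == f
                rows[[length(rows) + 1L]] <- data.frame(repeat_ = r, fold = f,
                    auroc = .auroc(sc[m], foldLabels[m]),
                    auprc = .averagePrecision(sc[m], foldLabels[m]))
            }
        }
        pf <- do.call(rbind, rows)
        out$per_fold <- pf
        out$mean_auroc <- mean(pf$auroc, na.rm = TRUE)
        out$sd_auroc <- stats::sd(pf$auroc, na.rm = TRUE)
        out$mean_auprc <- mean(pf$auprc, na.rm = TRUE)
        out$sd_auprc <- stats::sd(pf$auprc, na.rm = TRUE)
    }
    out
}
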