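#' Sample-by-feature table for classification
#'
#' Normalized log-scale expression (\code{log2(normalized count + 1)}) with
#' two-class labels; class 0 is \code{"Adeno"}, class 1 \code{"NE"}.
#'
#' @slot x Numeric matrix, samples in rows, features in columns.
#' @slot y Factor of length \code{nrow(x)} with two levels
#'   (class 0 first).
#' @seealso [makeFeatureTable()], [lpocvAuc()]
#' @export
setClass("FeatureTable",
         representation(x = "matrix", y = "factor"))

setValidity("FeatureTable", function(object) {
    msg <- character()
    if (nrow(object@x) != length(object@y))
        msg <- c(msg, "one label per sample required")
    if (anyNA(object@x)) msg <- c(msg, "missing values not allowed")
    if (nlevels(object@y) != 2L || any(table(object@y) == 0L))
        msg <- c(msg, "both classes must be present")
    if (length(msg)) msg else TRUE
})

#' @describeIn FeatureTable-class Compact display.
#' @param object Object to display.
#' @export
setMethod("show", "FeatureTable", function(object) {
    cat("FeatureTable:", nrow(object@x), "samples x", ncol(object@x),
        "features\n")
    print(table(object@y))
})

#' Build a classification feature table from counts
#'
#' Normalizes by median-of-ratios size factors, log-transforms
#' (\code{log2(x + 1)}) and transposes to samples-by-features, restricted
#' to a feature panel.
#'
#' @param se A \linkS4class{MirnaExperiment}.
#' @param features Feature ids to keep (default all).
#' @param sizeFactors Optional precomputed size factors.
#' @param class0,class1 Group labels mapped to class 0 and class 1.
#' @return A \linkS4class{FeatureTable}.
#' @export
makeFeatureTable <- function(se, features = NULL, sizeFactors = NULL,
                             class0 = "Adeno", class1 = "NE") {
    cnt <- assay(se, "counts")
    if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(cnt)
    if (is.null(features)) features <- rownames(cnt)
    miss <- setdiff(features, rownames(cnt))
    if (length(miss))
        stop("unknown features: ", paste(utils::head(miss, 5), collapse = ", "))
    x <- t(log2(sweep(cnt[features, , drop = FALSE], 2L, sizeFactors, `/`) + 1))
    y <- factor(colData(se)$group, levels = c(class0, class1))
    if (anyNA(y)) stop("group labels must be ", class0, " or ", class1)
    new("FeatureTable", x = x, y = y)
}

#' Derive the classifier seed feature set from DE results
#'
#' Filters differential-expression results to the features eligible for
#' classifier construction: significant features above the expression
#' floor, with isomiRs excluded (\code{mature_only}, the default panel),
#' kept (\code{with_isomirs}), or restricted to features significantly
#' altered in both EV and tissue compartments (\code{tissue_concordant}).
#'
#' @param deResults DE table from [nbDiffExp()].
#' @param mode One of \code{"mature_only"}, \code{"with_isomirs"},
#'   \code{"tissue_concordant"}.
#' @param concordance For \code{tissue_concordant}: the table from
#'   [compareCompartments()].
#' @return Character vector of feature ids.
#' @export
seedFeatureSet <- function(deResults,
                           mode = c("mature_only", "with_isomirs",
                                    "tissue_concordant"),
                           concordance = NULL) {
    mode <- match.arg(mode)
    sig <- deResults$feature_id[deResults$significant]
    if (mode == "mature_only") {
        sig <- sig[!grepl("|", sig, fixed = TRUE)]
        if ("feature_kind" %in% colnames(deResults)) {
            kind <- deResults$feature_kind[match(sig, deResults$feature_id)]
            sig <- sig[kind != "isomir"]
        }
    } else if (mode == "tissue_concordant") {
        if (is.null(concordance))
            stop("tissue_concordant mode needs a compartment comparison")
        conc <- concordance$feature_id[concordance$call %in%
                                       c("concordant_up", "concordant_down")]
        sig <- intersect(sig, conc)
    }
    if (length(sig) == 0L)
        stop("empty seed feature set; relax the significance filters ",
             "(alpha, fcMin, expressionFloor) or change mode")
    sig
}

#' Boruta all-relevant feature selection
#'
#' At each iteration every feature is duplicated as a permuted "shadow"
#' copy, a random forest is fitted on real + shadow features, and each
#' real feature scores a hit when its impurity importance exceeds the
#' best shadow importance. After each iteration the hit counts of still
#' undecided features are tested two-sided against Binomial(iterations,
#' 1/2) with Bonferroni correction over the undecided features: features
#' significantly above chance are confirmed, significantly below are
#' rejected, and the rest remain tentative at \code{maxIter}. Iteration
#' stops early once every feature is decided.
#'
#' @param table A \linkS4class{FeatureTable} (at least 2 features and 4
#'   samples; labels must not be constant).
#' @param maxIter Maximum iterations.
#' @param alpha Significance level of the binomial decision test.
#' @param numTrees Trees per forest.
#' @param seed Integer seed.
#' @return A \linkS4class{BorutaResult}.
#' @examples
#' se <- simulateCounts(nClass0 = 10, nClass1 = 10, nFeatures = 20,
#'                      fracDE = 0.2, lfcMagnitude = 3, seed = 2)
#' borutaSelect(makeFeatureTable(se), maxIter = 20, seed = 2)
#' @export
borutaSelect <- function(table, maxIter = 50L, alpha = 0.05,
                         numTrees = 100L, seed = 1L) {
    stopifnot(is(table, "FeatureTable"))
    x <- table@x; y <- droplevels(table@y)
    if (nlevels(y) < 2L) stop("labels are constant")
    if (ncol(x) < 2L) stop("at least 2 features required")
    if (nrow(x) < 4L) stop("at least 4 samples required")
    p <- ncol(x)
    feats <- colnames(x)
    hits <- stats::setNames(integer(p), feats)
    status <- stats::setNames(rep("tentative", p), feats)
    iters <- 0L
    withSeed(seed, {
        for (it in seq_len(maxIter)) {
            undecided <- status == "tentative"
            if (!any(undecided)) break
            shadow <- apply(x, 2L, sample)
            colnames(shadow) <- paste0(".shadow.", feats)
            xa <- cbind(x, shadow)
            fit <- ranger::ranger(x = xa, y = y, num.trees = numTrees,
                                  importance = "impurity",
                                  min.node.size = 1L,
                                  num.threads = 1L, seed = subSeed())
            imp <- fit$variable.importance
            shadowMax <- max(imp[paste0(".shadow.", feats)])
            hits <- hits + as.integer(imp[feats] > shadowMax)
            iters <- it
            # binomial decision test on undecided features
            m <- sum(undecided)
            h <- hits[undecided]
            pTwo <- 2 * pmin(stats::pbinom(h, it, 0.5),
                             stats::pbinom(h - 1L, it, 0.5,
                                           lower.tail = FALSE))
            pTwo <- pmin(1, pTwo)
            decide <- pTwo * m < alpha
            newStatus <- ifelse(h > it / 2, "confirmed", "rejected")
            status[names(h)[decide]] <- newStatus[decide]
        }
    })
    new("BorutaResult", status = status, hits = hits,
        iterations = iters)
}

#' @rdname BorutaResult-class
#' @param x A \linkS4class{BorutaResult}.
#' @return \code{confirmedFeatures}: character vector of confirmed
#'   feature ids; \code{tentativeFeatures}: likewise for tentative.
#' @export
confirmedFeatures <- function(x) names(x@status)[x@status == "confirmed"]

#' @rdname BorutaResult-class
#' @export
tentativeFeatures <- function(x) names(x@status)[x@status == "tentative"]

#' Leave-pair-out cross-validation with nested feature selection
#'
#' Every (class-1, class-0) sample pair is held out once (\eqn{n_1 \times
#' n_0} pairs). When nested selection is on, Boruta runs on the fold's
#' training samples only -- held-out samples never influence feature
#' selection -- and the forest is trained on the confirmed features
#' (falling back to tentative features, then to the full set, so every
#' fold yields a score). Both held-out samples are scored with the
#' class-1 probability; the AUC is the fraction of pairs whose class-1
#' sample outscores its class-0 partner, with half credit for ties.
#'
#' @details
#' The fold schedule is part of the reproducibility contract: pairs are
#' enumerated with the class-0 sample varying fastest (for class-1 samples
#' in order), and fold \eqn{k} derives its RNG seed as
#' \code{(seed + 7919 k) mod 2147483646 + 1}, used for both the fold's
#' Boruta run and its forest. Forests use the default feature subsample
#' (\code{floor(sqrt(p))}) and terminal nodes of minimum size 1.
#'
#' @param table A \linkS4class{FeatureTable} (at least 2 samples per
#'   class).
#' @param nestedSelection Run Boruta inside each fold (default TRUE).
#' @param numTrees Trees per forest.
#' @param borutaMaxIter,borutaAlpha Boruta parameters for nested
#'   selection.
#' @param seed Integer seed; per-fold seeds are derived deterministically.
#' @return An \linkS4class{LpocvResult}.
#' @examples
#' se <- simulateCounts(nClass0 = 5, nClass1 = 4, nFeatures = 15,
#'                      fracDE = 0.4, lfcMagnitude = 3, seed = 5)
#' lpocvAuc(makeFeatureTable(se), nestedSelection = FALSE, seed = 5)
#' @export
lpocvAuc <- function(table, nestedSelection = TRUE, numTrees = 100L,
                     borutaMaxIter = 50L, borutaAlpha = 0.05, seed = 1L) {
    stopifnot(is(table, "FeatureTable"))
    x <- table@x; y <- table@y
    lev <- levels(y)
    idx1 <- which(y == lev[2]); idx0 <- which(y == lev[1])
    if (length(idx1) < 2L || length(idx0) < 2L)
        stop("each class needs at least 2 samples")
    feats <- colnames(x)
    grid <- expand.grid(i0 = idx0, i1 = idx1, KEEP.OUT.ATTRS = FALSE)
    nPair <- nrow(grid)
    selCount <- stats::setNames(numeric(length(feats)), feats)
    impSum <- stats::setNames(numeric(length(feats)), feats)
    score1 <- score0 <- numeric(nPair)
    nSel <- integer(nPair)
    for (k in seq_len(nPair)) {
        i1 <- grid$i1[k]; i0 <- grid$i0[k]
        tr <- setdiff(seq_along(y), c(i1, i0))
        if (length(unique(y[tr])) < 2L)
            stop("degenerate training fold")      # unreachable given pre
        foldSeed <- as.integer((as.numeric(seed) + 7919 * k) %% 2147483646) + 1L
        sel <- feats
        if (nestedSelection && length(feats) >= 2L) {
            sub <- new("FeatureTable", x = x[tr, , drop = FALSE],
                       y = droplevels(y[tr]))
            br <- borutaSelect(sub, maxIter = borutaMaxIter,
                               alpha = borutaAlpha, numTrees = numTrees,
                               seed = foldSeed)
            sel <- confirmedFeatures(br)
            if (length(sel) == 0L) sel <- tentativeFeatures(br)
            if (length(sel) == 0L) sel <- feats
        }
        # min.node.size 1: probability forests otherwise default to 10,
        # which degenerates to root-only trees on folds this small
        fit <- ranger::ranger(x = x[tr, sel, drop = FALSE],
                              y = droplevels(y[tr]),
                              num.trees = numTrees, probability = TRUE,
                              importance = "impurity", num.threads = 1L,
                              min.node.size = 1L, seed = foldSeed)
        pr <- stats::predict(fit, data = x[c(i1, i0), sel, drop = FALSE])
        prob <- pr$predictions[, lev[2]]
        score1[k] <- prob[1]; score0[k] <- prob[2]
        selCount[sel] <- selCount[sel] + 1
        impSum[sel] <- impSum[sel] + fit$variable.importance[sel]
        nSel[k] <- length(sel)
    }
    auc <- (sum(score1 > score0) + 0.5 * sum(score1 == score0)) / nPair
    pairs <- data.frame(pair = seq_len(nPair),
                        id1 = rownames(x)[grid$i1],
                        id0 = rownames(x)[grid$i0],
                        score1 = score1, score0 = score0,
                        n_selected = nSel)
    imp <- ifelse(selCount > 0, impSum / selCount, NA_real_)
    names(imp) <- feats
    new("LpocvResult", pairs = pairs, auc = auc,
        selectionFreq = selCount / nPair, importance = imp,
        nestedSelection = nestedSelection)
}

#' Bootstrap confidence interval for the pairwise AUC
#'
#' Percentile interval from resampling the held-out pairs with
#' replacement and recomputing the pairwise AUC. Reported as a bootstrap
#' interval; pairs sharing samples are resampled as units.
#'
#' @param result An \linkS4class{LpocvResult}.
#' @param level Confidence level.
#' @param nBoot Bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @return Named numeric: \code{auc}, \code{lower}, \code{upper}.
#' @export
aucCI <- function(result, level = 0.95, nBoot = 1000L, seed = 1L) {
    stopifnot(is(result, "LpocvResult"))
    s1 <- result@pairs$score1; s0 <- result@pairs$score0
    n <- length(s1)
    withSeed(seed, {
        boot <- vapply(seq_len(nBoot), function(i) {
            j <- sample.int(n, n, replace = TRUE)
            (sum(s1[j] > s0[j]) + 0.5 * sum(s1[j] == s0[j])) / n
        }, 0)
    })
    q <- stats::quantile(boot, c((1 - level) / 2, 1 - (1 - level) / 2),
                         names = FALSE)
    c(auc = result@auc, lower = q[1], upper = q[2])
}

#' Rank features from a cross-validation run
#'
#' Orders features by selection frequency (descending), then mean
#' impurity importance (descending), then name (ascending), and returns
#' the top \code{k} as the classifier panel.
#'
#' @param result An \linkS4class{LpocvResult}.
#' @param k Panel size; default: every feature selected in at least one
#'   fold. If \code{k} exceeds the available features, all are returned
#'   with a warning.
#' @return Character vector of feature ids in rank order.
#' @export
rankFeatures <- function(result, k = NULL) {
    stopifnot(is(result, "LpocvResult"))
    freq <- result@selectionFreq
    imp <- result@importance
    imp[is.na(imp)] <- -Inf
    ord <- order(-freq, -imp, names(freq))
    ranked <- names(freq)[ord]
    avail <- sum(freq > 0)
    if (is.null(k)) k <- avail
    if (k > length(ranked)) {
        warning("k exceeds available features; returning all")
        k <- length(ranked)
    }
    ranked[seq_len(k)]
}

#' Train the deployable classifier on the full cohort
#'
#' Fits a probability random forest on all samples restricted to the
#' chosen feature panel, and records the resolved configuration with a
#' checksum so a serialized model can be audited.
#'
#' @param table A \linkS4class{FeatureTable}.
#' @param features The panel (must be columns of the table).
#' @param numTrees Trees (default 500 for a final model).
#' @param seed Integer seed; scores are bit-stable given the same seed.
#' @return An \linkS4class{EvClassifier}.
#' @export
buildFinalClassifier <- function(table, features, numTrees = 500L,
                                 seed = 1L) {
    stopifnot(is(table, "FeatureTable"))
    miss <- setdiff(features, colnames(table@x))
    if (length(miss))
        stop("unknown feature id(s): ", paste(miss, collapse = ", "))
    config <- list(features = features, numTrees = numTrees, seed = seed,
                   mtry = floor(sqrt(length(features))),
                   classLevels = levels(table@y))
    fit <- ranger::ranger(x = table@x[, features, drop = FALSE],
                          y = table@y, num.trees = numTrees,
                          probability = TRUE, importance = "impurity",
                          min.node.size = 1L, num.threads = 1L, seed = seed)
    new("EvClassifier", model = fit, features = features,
        classLevels = levels(table@y), config = config,
        configHash = hashObject(config))
}

#' Score samples with a fitted classifier
#'
#' @param classifier An \linkS4class{EvClassifier}.
#' @param x Sample-by-feature matrix (or \linkS4class{FeatureTable})
#'   containing the panel columns.
#' @return Named numeric vector of class-1 probabilities.
#' @export
scoreSamples <- function(classifier, x) {
    if (is(x, "FeatureTable")) x <- x@x
    miss <- setdiff(classifier@features, colnames(x))
    if (length(miss))
        stop("input lacks panel feature(s): ", paste(miss, collapse = ", "))
    pr <- stats::predict(classifier@model,
                         data = x[, classifier@features, drop = FALSE])
    stats::setNames(pr$predictions[, classifier@classLevels[2]], rownames(x))
}
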