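test_that("seed feature sets respect mode and fail when empty", {
    de <- S4Vectors::DataFrame(
        feature_id = c("miR-a", "miR-b|iso_3p_addition|len22", "miR-c"),
        base_mean = 100, log2fc = c(2, 2, 0.1),
        p = c(0.001, 0.001, 0.9), padj = c(0.01, 0.01, 0.9),
        significant = c(TRUE, TRUE, FALSE),
        feature_kind = c("mature", "isomir", "mature"))
    mature <- seedFeatureSet(de, "mature_only")
    expect_false(any(grepl("|", mature, fixed = TRUE)))
    expect_identical(mature, "miR-a")
    expect_setequal(seedFeatureSet(de, "with_isomirs"),
                    c("miR-a", "miR-b|iso_3p_addition|len22"))

    none <- de; none$significant <- FALSE
    expect_error(seedFeatureSet(none, "mature_only"), "relax")
    expect_error(seedFeatureSet(de, "tissue_concordant"), "comparison")
})

test_that("tissue-concordant mode returns exactly the planted pair", {
    mk <- function(sig, lfc) S4Vectors::DataFrame(
        feature_id = paste0("miR-", letters[1:6]), base_mean = 100,
        log2fc = lfc, p = ifelse(sig, 1e-4, 0.5),
        padj = ifelse(sig, 1e-3, 0.8), significant = sig)
    # a, b significant in both with matching signs; c EV-only; d discordant
    deEv <- mk(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
               c(2, -2, 2, 2, 0, 0))
    deTi <- mk(c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
               c(2, -2, 0, -2, 0, 0))
    conc <- compareCompartments(deEv, deTi)
    got <- seedFeatureSet(deEv, "tissue_concordant", concordance = conc)
    expect_setequal(got, c("miR-a", "miR-b"))
})

test_that("Boruta separates informative from noise features", {
    ft <- separableTable(n0 = 12, n1 = 12, nNoise = 10, seed = 3)
    br <- borutaSelect(ft, maxIter = 30, seed = 3)
    expect_true("sep" %in% confirmedFeatures(br))
    expect_true(all(br@hits <= br@iterations))

    # constant feature has zero importance, never a hit
    x <- ft@x; x[, "noise1"] <- 0
    br2 <- borutaSelect(new("FeatureTable", x = x, y = ft@y),
                        maxIter = 30, seed = 3)
    expect_identical(unname(br2@hits["noise1"]), 0L)
    expect_identical(unname(br2@status["noise1"]), "rejected")

    expect_error(borutaSelect(new("FeatureTable", x = ft@x[1:12, ],
                                  y = droplevels(ft@y[1:12]))),
                 "constant|both classes")
})

test_that("LPOCV scores a separable cohort perfectly and counts pairs", {
    # a single perfectly separating feature: every fold ranks the held-out
    # pair correctly
    sep <- separableTable(n0 = 5, n1 = 4, nNoise = 1, seed = 2)
    one <- new("FeatureTable", x = sep@x[, "sep", drop = FALSE], y = sep@y)
    lp1 <- lpocvAuc(one, nestedSelection = FALSE, numTrees = 100, seed = 2)
    expect_equal(lp1@auc, 1.0)
    expect_identical(nrow(lp1@pairs), 5L * 4L)

    # with noise features alongside, the forest still ranks nearly all pairs
    ft <- separableTable(n0 = 8, n1 = 6, nNoise = 5, seed = 2)
    lp <- lpocvAuc(ft, nestedSelection = FALSE, numTrees = 100, seed = 2)
    expect_gte(lp@auc, 0.95)
    lpNest <- lpocvAuc(ft, nestedSelection = TRUE, numTrees = 100,
                       borutaMaxIter = 25, seed = 2)
    expect_gte(lpNest@auc, 0.95)
    expect_gte(lpNest@selectionFreq[["sep"]],
               max(lpNest@selectionFreq[paste0("noise", 1:5)]))
})

test_that("LPOCV equals an independent enumeration of all pairs", {
    se <- simulateCounts(3, 3, 8, fracDE = 0.5, lfcMagnitude = 1.5,
                        baselineMeanLogRange = c(1.5, 3), seed = 13)
    ft <- makeFeatureTable(se)
    lp <- lpocvAuc(ft, nestedSelection = FALSE, numTrees = 100, seed = 13)
    expect_identical(nrow(lp@pairs), 9L)

    # independent script: enumerate pairs per the documented fold contract
    x <- ft@x; y <- ft@y
    idx1 <- which(y == "NE"); idx0 <- which(y == "Adeno")
    k <- 0L; wins <- 0
    s1 <- s0 <- numeric(9)
    for (i1 in idx1) for (i0 in idx0) {
        k <- k + 1L
        foldSeed <- as.integer((13 + 7919 * k) %% 2147483646) + 1L
        tr <- setdiff(seq_along(y), c(i1, i0))
        fit <- ranger::ranger(x = x[tr, , drop = FALSE],
                              y = droplevels(y[tr]), num.trees = 100,
                              probability = TRUE, min.node.size = 1,
                              num.threads = 1, seed = foldSeed)
        pr <- predict(fit, data = x[c(i1, i0), , drop = FALSE])$predictions
        s1[k] <- pr[1, "NE"]; s0[k] <- pr[2, "NE"]
    }
    aucOracle <- (sum(s1 > s0) + 0.5 * sum(s1 == s0)) / 9
    expect_identical(lp@auc, aucOracle)
    expect_identical(lp@pairs$score1, s1)
})

test_that("feature ranking is ordered and deterministic under ties", {
    ft <- separableTable(n0 = 5, n1 = 4, nNoise = 3, seed = 4)
    lp <- lpocvAuc(ft, nestedSelection = TRUE, numTrees = 100,
                   borutaMaxIter = 25, seed = 4)
    ranked <- rankFeatures(lp, 1)
    expect_identical(ranked, "sep")

    lpAll <- lpocvAuc(ft, nestedSelection = FALSE, seed = 4)
    # all features selected in every fold: frequency ties break by
    # importance then name; ranking must be a permutation and stable
    r1 <- rankFeatures(lpAll)
    r2 <- rankFeatures(lpAll)
    expect_identical(r1, r2)
    expect_setequal(r1, colnames(ft@x))
    expect_warning(rankFeatures(lpAll, k = 99), "exceeds")
})

test_that("the final classifier separates, serializes and validates input", {
    ft <- separableTable(n0 = 6, n1 = 5, nNoise = 4, seed = 5)
    clf <- buildFinalClassifier(ft, c("sep", "noise1"), numTrees = 200,
                                seed = 5)
    sc <- scoreSamples(clf, ft)
    expect_gt(min(sc[ft@y == "NE"]), max(sc[ft@y == "Adeno"]))

    f <- tempfile(fileext = ".rds")
    saveRDS(clf, f)
    back <- readRDS(f)
    expect_identical(scoreSamples(back, ft), sc)

    expect_error(buildFinalClassifier(ft, "absent"), "unknown feature")
    expect_error(scoreSamples(clf, ft@x[, "sep", drop = FALSE]), "lacks")
})

test_that("bootstrap AUC intervals bracket the point estimate", {
    ft <- separableTable(n0 = 6, n1 = 5, nNoise = 4, seed = 9)
    lp <- lpocvAuc(ft, nestedSelection = FALSE, numTrees = 100, seed = 9)
    ci <- aucCI(lp, nBoot = 200, seed = 9)
    expect_lte(ci[["lower"]], ci[["auc"]])
    expect_gte(ci[["upper"]], ci[["auc"]])
    expect_identical(ci, aucCI(lp, nBoot = 200, seed = 9))  # seeded
})

test_that("a small concordant panel performs close to the full panel", {
    # two strong concordant features vs a wider panel of moderate ones
    planted <- setNames(c(3, -3, rep(c(1.5, -1.5), 5)),
                        sprintf("mir%04d", 1:12))
    se <- simulateCounts(10, 7, 100, plantedLfc = planted,
                         dispersion = 0.1,
                         baselineMeanLogRange = c(1.5, 3), seed = 17)
    full <- lpocvAuc(makeFeatureTable(se, features = names(planted)),
                     nestedSelection = FALSE, seed = 17)
    pair <- lpocvAuc(makeFeatureTable(se, features = names(planted)[1:2]),
                     nestedSelection = FALSE, seed = 17)
    expect_lte(pair@auc, full@auc + 0.05)
})
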