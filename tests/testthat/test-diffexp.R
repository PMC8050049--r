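test_that("size factors follow the median-of-ratios definition", {
    m <- cbind(s1 = c(10, 20, 30), s2 = c(10, 20, 30))
    expect_equal(unname(computeSizeFactors(m)), c(1, 1))

    # doubled column: hand-computed geometric means and ratio medians
    m2 <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
    expect_equal(unname(computeSizeFactors(m2)),
                 c(1 / sqrt(2), sqrt(2)), tolerance = 1e-6)

    # all-zero rows do not affect the factors
    m3 <- rbind(m2, zero = c(0, 0))
    expect_equal(computeSizeFactors(m3), computeSizeFactors(m2))

    # scaling a column scales its factor proportionally, relative to the
    # others (size factors are defined up to an overall scale)
    se <- simulateCounts(nClass0 = 3, nClass1 = 3, nFeatures = 80, seed = 2)
    cnt <- SummarizedExperiment::assay(se)
    sf1 <- computeSizeFactors(cnt)
    cnt[, 2] <- cnt[, 2] * 3L
    sf2 <- computeSizeFactors(cnt)
    expect_equal((sf2[[2]] / sf2[[1]]) / (sf1[[2]] / sf1[[1]]), 3,
                 tolerance = 1e-9)
    expect_equal(sf2[-2] / sf2[[1]], sf1[-2] / sf1[[1]], tolerance = 1e-9)

    # no feature expressed everywhere: total-count fallback with warning
    m4 <- cbind(s1 = c(5L, 0L), s2 = c(0L, 5L))
    expect_warning(sf <- computeSizeFactors(m4), "total-count")
    expect_equal(unname(sf), c(1, 1))
})

test_that("size factors agree with the DESeq2 reference implementation", {
    se <- simulateCounts(nClass0 = 5, nClass1 = 5, nFeatures = 120, seed = 9)
    cnt <- SummarizedExperiment::assay(se)
    expect_equal(unname(computeSizeFactors(cnt)),
                 unname(DESeq2::estimateSizeFactorsForMatrix(cnt)),
                 tolerance = 1e-8)
})

test_that("BH adjustment matches the step-up definition", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.03), 0.03)

    p <- sort(runif(20))
    expect_true(all(diff(bhAdjust(p)) >= 0))   # monotone on sorted input
    expect_true(all(bhAdjust(p) >= p))

    # NaN propagates and is excluded from the number of tests
    p2 <- c(0.01, NaN, 0.04)
    adj <- bhAdjust(p2)
    expect_true(is.na(adj[2]))
    expect_equal(adj[c(1, 3)], bhAdjust(c(0.01, 0.04)))

    set.seed(11)
    for (i in 1:25) {
        p <- runif(sample(3:40, 1))
        expect_equal(bhAdjust(p), bruteForceBH(p))
    }
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the NB Wald test handles degenerate features and exact nulls", {
    cnt <- matrix(rpois(80, 50), 10, 8,
                  dimnames = list(paste0("f", 1:10), paste0("s", 1:8)))
    cnt[3, ] <- 0L                          # all-zero feature
    cnt[, 5:8] <- cnt[, 1:4]                # class 1 identical to class 0
    grp <- rep(c("Adeno", "NE"), each = 4)
    res <- nbDiffExp(cnt, grp, sizeFactors = rep(1, 8), expressionFloor = 0)
    expect_equal(res$log2fc, rep(0, 10))    # identical classes: exactly 0
    expect_equal(res$p[res$feature_id == "f3"], 1)
    expect_true(all(res$padj >= res$p))
    expect_true(all(res$padj <= 1))

    expect_error(nbDiffExp(cnt, rep("Adeno", 8)), "two classes")
    expect_error(nbDiffExp(cnt, c("Adeno", rep("NE", 7))), "at least 2")
})

test_that("significance filtering applies alpha, fold-change and floor", {
    res <- S4Vectors::DataFrame(
        feature_id = c("kept", "weakFC", "lowExpr"),
        base_mean = c(100, 100, 2),
        log2fc = c(log2(2.5), log2(1.5), 3),
        p = c(0.001, 0.001, 0.001),
        padj = NA_real_, significant = FALSE)
    out <- filterSignificant(res, alpha = 0.05, fcMin = 2,
                             expressionFloor = 10)
    expect_true(out$significant[out$feature_id == "kept"])
    expect_false(out$significant[out$feature_id == "weakFC"])
    expect_false("lowExpr" %in% out$feature_id)    # removed before testing

    # raw-p mode
    res$p <- c(0.04, 0.04, 0.04)
    raw <- filterSignificant(res, useAdjusted = FALSE, expressionFloor = 0)
    expect_true(raw$significant[1])
})

test_that("planted fold changes are recovered with controlled FDR", {
    planted <- setNames(rep(c(3, -3), 10), sprintf("mir%04d", 1:20))
    se <- simulateCounts(10, 10, 200, plantedLfc = planted,
                         dispersion = 0.1,
                         baselineMeanLogRange = c(1.5, 3), seed = 31)
    res <- nbDiffExp(se)
    called <- res$feature_id[res$significant]
    recall <- mean(names(planted) %in% called)
    fdr <- if (length(called)) mean(!called %in% names(planted)) else 0
    expect_gte(recall, 0.9)
    expect_lte(fdr, 0.1)
})
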