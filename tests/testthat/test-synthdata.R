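test_that("count simulation is deterministic and honors its ground truth", {
    a <- simulateCounts(nClass0 = 4, nClass1 = 4, nFeatures = 50, seed = 7)
    b <- simulateCounts(nClass0 = 4, nClass1 = 4, nFeatures = 50, seed = 7)
    expect_identical(SummarizedExperiment::assay(a), SummarizedExperiment::assay(b))
    c <- simulateCounts(nClass0 = 4, nClass1 = 4, nFeatures = 50, seed = 8)
    expect_false(identical(SummarizedExperiment::assay(a),
                           SummarizedExperiment::assay(c)))

    none <- simulateCounts(nClass0 = 3, nClass1 = 3, nFeatures = 30,
                           fracDE = 0, seed = 1)
    expect_length(groundTruth(none)$deFeatures, 0)

    de <- groundTruth(a)$deFeatures
    expect_true(all(names(de) %in% rownames(a)))
    expect_true(all(abs(de) == 2))
    expect_true(any(de > 0) && any(de < 0))   # both directions planted
})

test_that("count simulation rejects invalid configurations", {
    expect_error(simulateCounts(nClass0 = 2.5, nClass1 = 4), "integer")
    expect_error(simulateCounts(nClass0 = 1, nClass1 = 4), "at least 2")
    expect_error(simulateCounts(dispersion = -0.1), "non-negative")
    expect_error(simulateCounts(fracDE = 1.2), "fracDE")
    expect_error(simulateCounts(libSizeRange = c(2, 1)), "libSizeRange")
})

test_that("simulated counts match the stated NB/Poisson moments", {
    # dispersion 0 is Poisson: per-feature variance tracks the mean
    po <- simulateCounts(nClass0 = 5000, nClass1 = 5000, nFeatures = 6,
                         fracDE = 0, dispersion = 0,
                         libSizeRange = c(1e6, 1e6),
                         baselineMeanLogRange = c(1.5, 2.5), seed = 3)
    cnt <- SummarizedExperiment::assay(po)
    m <- rowMeans(cnt); v <- apply(cnt, 1, var)
    expect_true(all(abs(v / m - 1) < 0.05))

    # NB: variance = mu + alpha mu^2 within 5% relative error at n = 10000
    alpha <- 0.2
    nb <- simulateCounts(nClass0 = 5000, nClass1 = 5000, nFeatures = 6,
                         fracDE = 0, dispersion = alpha,
                         libSizeRange = c(1e6, 1e6),
                         baselineMeanLogRange = c(1.5, 2.5), seed = 4)
    cnt <- SummarizedExperiment::assay(nb)
    m <- rowMeans(cnt); v <- apply(cnt, 1, var)
    expect_true(all(abs(v / (m + alpha * m^2) - 1) < 0.05))
})

test_that("read simulation matches its configuration and truth", {
    ref <- syntheticMirnaReference(6, seed = 2)
    expect_error(simulateReads(ref, pCanonical = 0.8, pIso3pAdd = 0.3,
                               pIso3pTrim = 0.1, pIso5p = 0.1),
                 "sum to 1")

    onlyCanon <- simulateReads(ref, readsPerMirna = 10, pCanonical = 1,
                               pIso3pAdd = 0, pIso3pTrim = 0, pIso5p = 0,
                               seed = 1)
    mat <- mirnaSequences(ref)
    expect_true(all(as.character(onlyCanon$reads) ==
                    unname(mat[onlyCanon$truth$parent])))

    sim <- simulateReads(ref, readsPerMirna = 100, seed = 5)
    # truth covers every emitted read exactly once
    expect_identical(sort(names(sim$reads)), sort(sim$truth$read_id))
    expect_false(anyDuplicated(sim$truth$read_id) > 0)
    # read lengths bounded by mature length +/- maxModLen
    lens <- Biostrings::width(sim$reads)
    matLen <- nchar(mat)[sim$truth$parent]
    expect_true(all(abs(lens - matLen) <= 4))

    # empirical class fraction converges (binomial tolerance +/- 0.02)
    big <- simulateReads(syntheticMirnaReference(10, seed = 3),
                         readsPerMirna = 1000, pCanonical = 0.4,
                         pIso3pAdd = 0.3, pIso3pTrim = 0.2, pIso5p = 0.1,
                         seed = 6)
    frac <- mean(big$truth$variant_class == "iso_3p_addition")
    expect_lt(abs(frac - 0.3), 0.02)
})

test_that("reads with no 5' modification always preserve the parent seed", {
    ref <- syntheticMirnaReference(6, seed = 4)
    sim <- simulateReads(ref, readsPerMirna = 50, pCanonical = 0.4,
                         pIso3pAdd = 0.35, pIso3pTrim = 0.25, pIso5p = 0,
                         seed = 7)
    seeds <- mirnaSeeds(ref)
    expect_true(all(substr(as.character(sim$reads), 2, 8) ==
                    unname(seeds[sim$truth$parent])))
})

test_that("FASTQ round trip preserves simulated reads", {
    ref <- syntheticMirnaReference(3, seed = 9)
    sim <- simulateReads(ref, readsPerMirna = 5, seed = 9)
    fq <- tempfile(fileext = ".fastq")
    writeReadsFastq(sim$reads, fq)
    back <- readSmallRnaReads(fq)
    expect_identical(as.character(back), as.character(sim$reads))
})

test_that("ELISA simulation round-trips noiselessly and rejects bad curves", {
    std <- 0.5 * 2^(0:7)
    pan <- simulateElisa(std, sampleConcs = c(2, 7, 20), noiseSD = 0,
                         seed = 1)
    fit <- fitElisaPanel(pan)
    expect_true(all(abs(fit@sampleConc / pan@truthConc - 1) < 1e-3))

    # zero concentration sits exactly on the lower asymptote (noiseless)
    curve <- c(lower = 0.05, upper = 2.5, ec50 = 8, slope = 1.2)
    z <- simulateElisa(std, sampleConcs = 0, curve = curve, noiseSD = 0,
                       seed = 1)
    expect_equal(z@sampleOD, curve[["lower"]])

    expect_error(simulateElisa(std, 1, curve = c(lower = 2, upper = 1,
                                                 ec50 = 8, slope = 1)),
                 "monotone")
    expect_error(simulateElisa(c(0, std), 1), "> 0")
})

test_that("noisy ELISA panels recover mid-curve concentrations within 10%", {
    std <- 0.5 * 2^seq(0, 6, length.out = 8)   # 8 standards, 0.5 - 32 ng/ml
    relErr <- replicate(100, NA_real_)
    for (s in 1:100) {
        pan <- fitElisaPanel(simulateElisa(std, sampleConcs = c(4, 8, 16),
                                           noiseSD = 0.02, seed = s))
        relErr[s] <- max(abs(pan@sampleConc / pan@truthConc - 1))
    }
    expect_gt(mean(relErr < 0.10), 0.9)
})
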