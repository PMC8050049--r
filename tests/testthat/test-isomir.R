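test_that("reference loading normalizes U to T and derives seeds", {
    fa <- writeTempFasta(list("hsa-miR-x" = "UGAGGUAGUAGGUUGUAUAGUU"))
    ref <- loadMirnaReference(fa)
    expect_identical(unname(mirnaSequences(ref)), "TGAGGTAGTAGGTTGTATAGTT")
    expect_identical(unname(mirnaSeeds(ref)), "GAGGTAG")   # positions 2-8

    dup <- writeTempFasta(list(a = "TGAGGTAGTAGGTTGTATAGTT",
                               a = "TAGCTTATCAGACTGATGTTGA"))
    expect_error(loadMirnaReference(dup), "duplicate")

    empty <- tempfile(fileext = ".fa"); file.create(empty)
    expect_error(loadMirnaReference(empty), "empty|read")

    bad <- writeTempFasta(list(x = "TGAGGTAGTAGGTTGTNTAGTT"))
    expect_error(loadMirnaReference(bad), "non-nucleotide")

    dupSeq <- writeTempFasta(list(a = "TGAGGTAGTAGGTTGTATAGTT",
                                  b = "TGAGGTAGTAGGTTGTATAGTT"))
    expect_warning(loadMirnaReference(dupSeq), "duplicate mature")
})

test_that("variant classes and seed integrity follow the matching rules", {
    ref <- handReference()
    m <- mirnaSequences(ref)[["hsa-let-7x"]]

    canon <- classifyRead(m, ref)
    expect_identical(canon$variant_class, "canonical")
    expect_true(canon$seed_intact)

    add <- classifyRead(paste0(m, "TT"), ref)
    expect_identical(add$variant_class, "iso_3p_addition")
    expect_identical(add$parent, "hsa-let-7x")
    expect_true(add$seed_intact)

    trim <- classifyRead(substr(m, 1, nchar(m) - 3), ref)
    expect_identical(trim$variant_class, "iso_3p_trim")
    expect_true(trim$seed_intact)

    # removing the first nucleotide shifts the seed register
    iso5 <- classifyRead(substring(m, 2), ref)
    expect_identical(iso5$variant_class, "iso_5p")
    expect_false(iso5$seed_intact)

    both <- classifyRead(paste0(substring(m, 2), "GG"), ref)
    expect_identical(both$variant_class, "other")

    none <- classifyRead(strrep("AC", 10), ref)
    expect_identical(none$variant_class, "unassigned")
    expect_true(is.na(none$parent))

    expect_error(classifyRead("TGAGGTNGTAGGTTGTATAG", ref), "non-A/C/G/T")
})

test_that("multi-parent matches resolve by class priority", {
    # read is both a 3' addition of 'aaa' and a 3' trim of 'bbb'
    a <- "TGAGGTAGTAGGTTGTATAG"
    read <- paste0(a, "G")
    b <- paste0(read, "CA")
    ref <- mirnaReference(c(aaa = a, bbb = b))
    call <- classifyRead(read, ref)
    expect_identical(call$variant_class, "iso_3p_addition")
    expect_identical(call$parent, "aaa")
})

test_that("classification recovers generator truth exactly", {
    ref <- syntheticMirnaReference(10, seed = 21)
    sim <- simulateReads(ref, readsPerMirna = 100, seed = 22)
    calls <- classifyReads(sim$reads, ref)
    expect_identical(calls$variant_class, sim$truth$variant_class)
    expect_identical(calls$parent, sim$truth$parent)
})

test_that("feature collapse conserves reads and separates variants", {
    ref <- handReference()
    m <- mirnaSequences(ref)[["hsa-let-7x"]]
    reads <- c(r1 = m, r2 = m, r3 = m,
               r4 = paste0(m, "A"), r5 = paste0(m, "C"),
               r6 = strrep("AC", 10))
    calls <- classifyReads(reads, ref)
    feats <- collapseToFeatures(calls)

    canon <- feats[feats$variant_class == "canonical", ]
    expect_identical(nrow(canon), 1L)
    expect_identical(canon$count, 3L)
    expect_identical(canon$feature_id, "hsa-let-7x")   # parent-only name

    adds <- feats[feats$variant_class == "iso_3p_addition", ]
    expect_identical(nrow(adds), 2L)       # distinct sequences, two features
    expect_true(all(grepl("^hsa-let-7x\\|iso_3p_addition\\|len23", adds$feature_id)))
    expect_identical(anyDuplicated(feats$feature_id), 0L)

    expect_identical(sum(feats$count),
                     sum(calls$variant_class != "unassigned"))
    expect_identical(attr(feats, "nUnassigned"), 1L)
})

test_that("isomiR summaries report length histograms and busy loci", {
    calls <- data.frame(read_id = paste0("r", 1:4),
                        parent = "p", variant_class = "canonical",
                        read_length = c(18, 21, 21, 24),
                        seed_intact = TRUE, sequence = "x")
    s <- summarizeIsomirs(calls = calls)
    expect_identical(s$lengthHistogram,
                     c("18" = 1L, "21" = 2L, "24" = 1L))
    expect_identical(s$lengthRange, c(18, 24))

    de <- c(paste0("A|iso_3p_addition|len", 20:22),
            "B|iso_3p_trim|len19",
            paste0("C|iso_3p_addition|len", 18:21),
            "matureOnly")
    s2 <- summarizeIsomirs(deFeatures = de, k = 3)
    expect_identical(s2$perLocus, c(A = 3L, B = 1L, C = 4L))
    expect_identical(s2$lociAtLeastK, c(A = 3L, C = 4L))

    s3 <- summarizeIsomirs(deFeatures = character(0))
    expect_length(s3$lociAtLeastK, 0)
})
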