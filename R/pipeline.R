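#' Default pipeline configuration
#'
#' Returns the fully resolved configuration the pipeline runs with: stage
#' toggles, all stage parameters and the global seed. The defaults run a
#' fully synthetic cohort shaped like a two-class serum-EV study (21
#' adenocarcinoma vs 7 neuroendocrine samples). The list round-trips
#' through YAML losslessly and every run writes its resolved copy next to
#' its artifacts.
#'
#' @return Nested named list.
#' @export
defaultRunConfig <- function() {
    list(
        seed = 1L,
        stages = list(simulate = TRUE, isomir = TRUE, diffexp = TRUE,
                      classifier = TRUE, markers = TRUE, report = TRUE),
        inputs = list(counts = NULL, samples = NULL, reads = NULL,
                      reference = NULL, elisa_plate = NULL),
        simulate = list(n_class0 = 21L, n_class1 = 7L, n_features = 300L,
                        frac_de = 0.1, lfc_magnitude = 2, dispersion = 0.2,
                        frac_isomir = 0.3, tissue_concordance = 0.5,
                        n_ref_mirnas = 15L, reads_per_mirna = 60L,
                        elisa_noise_sd = 0.02),
        de = list(alpha = 0.05, fc_min = 2, expression_floor = 10,
                  use_adjusted = TRUE),
        classifier = list(mode = "mature_only", k = NULL,
                          num_trees = 100L, nested_selection = TRUE,
                          boruta_max_iter = 50L),
        elisa = list(threshold = 7),
        report = list(n_top_features = 500L, clusters = 4L))
}

#' Load a pipeline configuration from YAML
#'
#' Missing keys are filled from [defaultRunConfig()].
#'
#' @param path YAML file path, or NULL for the defaults.
#' @return Resolved configuration list.
#' @export
loadRunConfig <- function(path = NULL) {
    cfg <- defaultRunConfig()
    if (!is.null(path)) {
        user <- yaml::read_yaml(path)
        cfg <- utils::modifyList(cfg, user, keep.null = TRUE)
    }
    cfg
}

#' Generate a synthetic mature-miRNA reference
#'
#' Random mature sequences with first nucleotide T (as most miRNAs start
#' with U) and lengths in the given range, re-drawn until no sequence is
#' a substring of another, so read classification against the reference
#' is unambiguous.
#'
#' @param n Number of miRNAs.
#' @param lengthRange Length bounds in nt.
#' @param seed Integer seed.
#' @return A \linkS4class{MirnaReference} named \code{sim-miR-1}, ...
#' @export
syntheticMirnaReference <- function(n = 15L, lengthRange = c(18L, 23L),
                                    seed = 1L) {
    withSeed(seed, {
        seqs <- character(n)
        for (i in seq_len(n)) {
            repeat {
                len <- sample(seq(lengthRange[1], lengthRange[2]), 1L)
                s <- paste0("T", randNt(len - 1L))
                clash <- any(vapply(seqs[seq_len(i - 1L)], function(o)
                    grepl(s, o, fixed = TRUE) || grepl(o, s, fixed = TRUE),
                    logical(1)))
                if (!clash && !s %in% seqs) break
            }
            seqs[i] <- s
        }
    })
    names(seqs) <- paste0("sim-miR-", seq_len(n))
    mirnaReference(seqs)
}

#' Read a count matrix and sample sheet from TSV
#'
#' @param countsPath TSV whose first column is \code{feature_id} and
#'   remaining columns are sample counts.
#' @param samplesPath TSV with columns \code{sample_id}, \code{group},
#'   and optionally \code{compartment}.
#' @return A \linkS4class{MirnaExperiment}.
#' @export
readCountMatrix <- function(countsPath, samplesPath) {
    cnt <- readTsv(countsPath)
    m <- as.matrix(cnt[, -1, drop = FALSE])
    rownames(m) <- cnt[[1]]
    sheet <- readTsv(samplesPath)
    if (!all(colnames(m) %in% sheet$sample_id))
        stop("sample sheet does not cover all count columns")
    sheet <- sheet[match(colnames(m), sheet$sample_id), ]
    kind <- ifelse(grepl("|", rownames(m), fixed = TRUE), "isomir", "mature")
    MirnaExperiment(m, group = sheet$group,
                    compartment = if ("compartment" %in% names(sheet))
                        sheet$compartment else "EV",
                    featureKind = kind)
}

writeCountMatrix <- function(se, countsPath, samplesPath) {
    cnt <- assay(se, "counts")
    writeTsv(data.frame(feature_id = rownames(cnt), cnt,
                        check.names = FALSE), countsPath)
    writeTsv(data.frame(sample_id = colnames(se),
                        group = colData(se)$group,
                        compartment = colData(se)$compartment),
             samplesPath)
    invisible(NULL)
}

#' Unsupervised exploration of an expression table
#'
#' PCA on centered log-scale expression restricted to the most variable
#' features, and average-linkage hierarchical clustering on the
#' 1 - Pearson correlation distance between samples. Principal-component
#' signs are normalized (the largest-magnitude loading of each component
#' is made positive) so coordinates do not depend on feature order.
#'
#' @param table A \linkS4class{FeatureTable} (at least 3 samples).
#' @param nTopFeatures Number of most-variable features used.
#' @param k Number of clusters to cut (default 4).
#' @return List with \code{coordinates} (data.frame: sample, PC1, PC2,
#'   cluster), \code{varianceExplained}, \code{hclust}.
#' @export
exploreReport <- function(table, nTopFeatures = 500L, k = 4L) {
    stopifnot(is(table, "FeatureTable"))
    x <- table@x
    if (nrow(x) < 3L) stop("at least 3 samples required")
    v <- apply(x, 2L, stats::var)
    if (all(v == 0)) stop("constant expression table")
    top <- order(v, decreasing = TRUE)[seq_len(min(nTopFeatures, sum(v > 0)))]
    # deterministic feature order within the top set
    top <- top[order(colnames(x)[top])]
    xc <- scale(x[, top, drop = FALSE], center = TRUE, scale = FALSE)
    pca <- stats::prcomp(xc, center = FALSE)
    flip <- apply(pca$rotation, 2L, function(r) sign(r[which.max(abs(r))]))
    scores <- sweep(pca$x, 2L, flip, `*`)
    d <- stats::as.dist(1 - stats::cor(t(x[, top, drop = FALSE])))
    hc <- stats::hclust(d, method = "average")
    cl <- stats::cutree(hc, k = min(k, nrow(x)))
    ve <- pca$sdev^2 / sum(pca$sdev^2)
    list(coordinates = data.frame(sample = rownames(x),
                                  PC1 = scores[, 1],
                                  PC2 = if (ncol(scores) >= 2) scores[, 2]
                                        else 0,
                                  cluster = unname(cl)),
         varianceExplained = ve, hclust = hc)
}

stageMsg <- function(stage, ...) {
    message("[", stage, "] ", ...)
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in dependency order -- simulate (or ingest)
#' -> isomir -> diffexp -> classifier -> markers -> report -- writing
#' plain-text artifacts and a manifest (with an md5 checksum of every
#' output and the resolved configuration) to \code{outDir}. A stage
#' failure halts the run with a stage-tagged message; artifacts already
#' written are retained. Reruns with the same configuration and seed are
#' byte-identical.
#'
#' @param config Configuration list (see [defaultRunConfig()]) or a YAML
#'   path.
#' @param outDir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir = tempfile("run")) {
    if (is.character(config)) config <- loadRunConfig(config)
    cfg <- utils::modifyList(defaultRunConfig(), config, keep.null = TRUE)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    addFile <- function(path) files <<- c(files, path)
    ranStages <- character(0)
    runStage <- function(stage, fn) {
        stageMsg(stage, "starting")
        tryCatch(fn(), error = function(e)
            stop("stage '", stage, "' failed: ", conditionMessage(e),
                 call. = FALSE))
        ranStages <<- c(ranStages, stage)
        stageMsg(stage, "done")
    }
    seed <- as.integer(cfg$seed)
    env <- new.env()

    if (isTRUE(cfg$stages$simulate)) runStage("simulate", function() {
        sc <- cfg$simulate
        env$ref <- syntheticMirnaReference(sc$n_ref_mirnas, seed = seed)
        env$se <- simulateCounts(sc$n_class0, sc$n_class1, sc$n_features,
                                 fracDE = sc$frac_de,
                                 lfcMagnitude = sc$lfc_magnitude,
                                 dispersion = sc$dispersion,
                                 fracIsomir = sc$frac_isomir, seed = seed)
        # paired tissue cohort: a configurable fraction of the EV planted
        # fold changes recur in tissue, the rest are tissue-private
        evDe <- groundTruth(env$se)$deFeatures
        nShared <- round(sc$tissue_concordance * length(evDe))
        shared <- evDe[seq_len(nShared)]
        ids <- sub("\\|.*$", "", names(shared))
        names(shared) <- ids
        env$seTissue <- simulateCounts(sc$n_class0, sc$n_class1,
                                       sc$n_features,
                                       plantedLfc = shared,
                                       dispersion = sc$dispersion,
                                       seed = seed + 1L)
        colData(env$seTissue)$compartment <- "tissue"
        sim <- simulateReads(env$ref, readsPerMirna = sc$reads_per_mirna,
                             seed = seed)
        env$reads <- sim$reads; env$readTruth <- sim$truth
        # EV THBS1 ELISA: NE cases release more THBS1
        labels <- colData(env$se)$group
        env$elisaLabels <- labels
        withSeed(seed + 2L, {
            conc <- ifelse(labels == "NE",
                           stats::rlnorm(length(labels), log(12), 0.5),
                           stats::rlnorm(length(labels), log(3), 0.5))
        })
        env$elisa <- simulateElisa(standards = 0.5 * 2^(0:7),
                                   sampleConcs = conc,
                                   noiseSD = sc$elisa_noise_sd,
                                   seed = seed + 3L)
        writeCountMatrix(env$se, file.path(outDir, "counts.tsv"),
                         file.path(outDir, "samples.tsv"))
        writeCountMatrix(env$seTissue, file.path(outDir, "counts_tissue.tsv"),
                         file.path(outDir, "samples_tissue.tsv"))
        writeReadsFastq(env$reads, file.path(outDir, "reads.fastq"))
        writeTsv(env$readTruth, file.path(outDir, "read_truth.tsv"))
        Biostrings::writeXStringSet(env$ref@sequences,
                                    file.path(outDir, "reference.fa"))
        jsonlite::write_json(
            list(de_features = as.list(groundTruth(env$se)$deFeatures)),
            file.path(outDir, "ground_truth.json"), auto_unbox = TRUE,
            digits = NA)
        for (f in c("counts.tsv", "samples.tsv", "counts_tissue.tsv",
                    "samples_tissue.tsv", "reads.fastq", "read_truth.tsv",
                    "reference.fa", "ground_truth.json"))
            addFile(file.path(outDir, f))
    }) else runStage("ingest", function() {
        inp <- cfg$inputs
        if (is.null(inp$counts) || is.null(inp$samples))
            stop("simulate disabled and no input counts/samples given")
        env$se <- readCountMatrix(inp$counts, inp$samples)
        if (!is.null(inp$reference))
            env$ref <- loadMirnaReference(inp$reference)
        if (!is.null(inp$reads))
            env$reads <- readSmallRnaReads(inp$reads)
        if (!is.null(inp$elisa_plate)) {
            env$elisa <- readElisaPlate(inp$elisa_plate)
            # plate samples are assumed to be the cohort samples, in order
            env$elisaLabels <- colData(env$se)$group
        }
    })

    if (isTRUE(cfg$stages$isomir) && !is.null(env$reads) &&
        !is.null(env$ref)) runStage("isomir", function() {
        env$calls <- classifyReads(env$reads, env$ref)
        env$features <- collapseToFeatures(env$calls)
        summ <- summarizeIsomirs(calls = env$calls)
        writeTsv(env$calls[, c("read_id", "parent", "variant_class",
                               "read_length", "seed_intact")],
                 file.path(outDir, "isomir_calls.tsv"))
        writeTsv(env$features, file.path(outDir, "isomir_features.tsv"))
        jsonlite::write_json(
            list(length_histogram = as.list(summ$lengthHistogram),
                 length_range = summ$lengthRange,
                 n_unassigned = attr(env$features, "nUnassigned")),
            file.path(outDir, "isomir_summary.json"), auto_unbox = TRUE,
            digits = NA)
        addFile(file.path(outDir, "isomir_calls.tsv"))
        addFile(file.path(outDir, "isomir_features.tsv"))
        addFile(file.path(outDir, "isomir_summary.json"))
    })

    if (isTRUE(cfg$stages$diffexp)) runStage("diffexp", function() {
        d <- cfg$de
        env$de <- nbDiffExp(env$se, alpha = d$alpha, fcMin = d$fc_min,
                            expressionFloor = d$expression_floor,
                            useAdjusted = d$use_adjusted)
        writeTsv(as.data.frame(env$de), file.path(outDir, "de_results.tsv"))
        addFile(file.path(outDir, "de_results.tsv"))
        if (!is.null(env$seTissue)) {
            env$deTissue <- nbDiffExp(env$seTissue, alpha = d$alpha,
                                      fcMin = d$fc_min,
                                      expressionFloor = d$expression_floor,
                                      useAdjusted = d$use_adjusted)
            writeTsv(as.data.frame(env$deTissue),
                     file.path(outDir, "de_results_tissue.tsv"))
            addFile(file.path(outDir, "de_results_tissue.tsv"))
        }
    })

    if (isTRUE(cfg$stages$classifier)) runStage("classifier", function() {
        cc <- cfg$classifier
        if (cc$mode == "tissue_concordant" && is.null(env$conc) &&
            !is.null(env$deTissue))
            env$conc <- compareCompartments(env$de, env$deTissue)
        panel <- seedFeatureSet(env$de, mode = cc$mode,
                                concordance = env$conc)
        ft <- makeFeatureTable(env$se, features = panel)
        env$lpocv <- lpocvAuc(ft, nestedSelection = cc$nested_selection,
                              numTrees = cc$num_trees,
                              borutaMaxIter = cc$boruta_max_iter,
                              seed = seed)
        ranked <- rankFeatures(env$lpocv, k = cc$k)
        env$final <- buildFinalClassifier(ft, ranked,
                                          numTrees = cc$num_trees,
                                          seed = seed)
        writeTsv(env$lpocv@pairs, file.path(outDir, "lpocv_pairs.tsv"))
        jsonlite::write_json(
            list(panel = ranked,
                 selection_frequency =
                     as.list(env$lpocv@selectionFreq[ranked]),
                 config_hash = env$final@configHash),
            file.path(outDir, "panel.json"), auto_unbox = TRUE, digits = NA)
        jsonlite::write_json(
            list(auc = env$lpocv@auc, n_pairs = nrow(env$lpocv@pairs),
                 mode = cc$mode, n_panel = length(ranked),
                 nested_selection = cc$nested_selection,
                 num_trees = cc$num_trees, seed = seed),
            file.path(outDir, "metrics.json"), auto_unbox = TRUE,
            digits = NA)
        addFile(file.path(outDir, "lpocv_pairs.tsv"))
        addFile(file.path(outDir, "panel.json"))
        addFile(file.path(outDir, "metrics.json"))
    })

    if (isTRUE(cfg$stages$markers)) runStage("markers", function() {
        if (!is.null(env$deTissue)) {
            if (is.null(env$conc))
                env$conc <- compareCompartments(env$de, env$deTissue)
            writeTsv(env$conc, file.path(outDir, "concordance.tsv"))
            ov <- overlapSets(env$de$feature_id[env$de$significant],
                              env$deTissue$feature_id[env$deTissue$significant])
            jsonlite::write_json(ov, file.path(outDir, "overlap.json"),
                                 auto_unbox = FALSE, digits = NA)
            addFile(file.path(outDir, "concordance.tsv"))
            addFile(file.path(outDir, "overlap.json"))
        }
        if (is.null(env$elisa)) return(invisible(NULL))
        pan <- fitElisaPanel(env$elisa)
        res <- classifyByThreshold(pan@sampleConc, env$elisaLabels,
                                   threshold = cfg$elisa$threshold)
        jsonlite::write_json(
            list(threshold_ng_ml = res@threshold,
                 confusion = as.list(confusionCounts(res)),
                 sensitivity_pct = round(sensitivityPct(res)),
                 specificity_pct = round(specificityPct(res)),
                 n_excluded = res@nExcluded,
                 curve = as.list(pan@curve), r2 = pan@r2),
            file.path(outDir, "elisa_results.json"), auto_unbox = TRUE,
            digits = NA)
        addFile(file.path(outDir, "elisa_results.json"))
    })

    if (isTRUE(cfg$stages$report)) runStage("report", function() {
        ft <- makeFeatureTable(env$se)
        rep <- exploreReport(ft, nTopFeatures = cfg$report$n_top_features,
                             k = cfg$report$clusters)
        writeTsv(rep$coordinates, file.path(outDir, "pca_clusters.tsv"))
        # the matrix behind a heat map: top-variable normalized expression
        topf <- names(sort(apply(ft@x, 2L, stats::var),
                           decreasing = TRUE))[seq_len(min(50, ncol(ft@x)))]
        hm <- data.frame(feature_id = topf,
                         t(ft@x[, topf, drop = FALSE]),
                         check.names = FALSE)
        writeTsv(hm, file.path(outDir, "heatmap_matrix.tsv"))
        addFile(file.path(outDir, "pca_clusters.tsv"))
        addFile(file.path(outDir, "heatmap_matrix.tsv"))
    })

    yaml::write_yaml(cfg, file.path(outDir, "config_resolved.yaml"))
    addFile(file.path(outDir, "config_resolved.yaml"))
    manifest <- list(
        package = "exoNED",
        version = as.character(utils::packageVersion("exoNED")),
        seed = seed,
        stages = ranStages,
        files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                        basename(files))))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(manifest)
}
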