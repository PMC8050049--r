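#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData colData<- rowData<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom Biostrings width
NULL

#' Mature miRNA reference
#'
#' Canonical mature miRNA sequences against which small-RNA reads are
#' classified. Sequences are stored T-normalized (U converted to T) as a
#' \linkS4class{DNAStringSet}; the seed of each miRNA is the 7-mer at
#' positions 2--8 (1-based, inclusive), the primary determinant of target
#' recognition.
#'
#' @slot sequences A named \linkS4class{DNAStringSet} of mature sequences.
#'
#' @seealso [loadMirnaReference()], [classifyReads()]
#' @export
setClass("MirnaReference", representation(sequences = "DNAStringSet"))

setValidity("MirnaReference", function(object) {
    s <- object@sequences
    msg <- character()
    if (length(s) == 0L)
        msg <- c(msg, "reference contains no sequences")
    nm <- names(s)
    if (is.null(nm) || anyNA(nm) || any(nm == ""))
        msg <- c(msg, "every sequence must be named")
    else if (anyDuplicated(nm))
        msg <- c(msg, "duplicate miRNA names")
    if (length(s) && any(Biostrings::width(s) < 14L))
        msg <- c(msg, "mature sequences must be at least 14 nt")
    if (length(s)) {
        freq <- Biostrings::alphabetFrequency(s, collapse = TRUE)
        if (sum(freq[c("A", "C", "G", "T")]) != sum(freq))
            msg <- c(msg, "sequences must use the A/C/G/T alphabet")
    }
    if (length(msg)) msg else TRUE
})

#' EV small-RNA count experiment
#'
#' A \linkS4class{SummarizedExperiment} holding an integer feature-by-sample
#' count matrix in the \code{"counts"} assay, with a \code{group} column
#' (\code{"Adeno"}/\code{"NE"}) and optional \code{compartment} column
#' (\code{"EV"}/\code{"tissue"}) in \code{colData}, and a
#' \code{feature_kind} column (\code{"mature"}, \code{"isomir"} or
#' \code{"other"}) in \code{rowData}. Simulated cohorts carry their ground
#' truth in \code{metadata(x)$groundTruth}.
#'
#' @seealso [MirnaExperiment()], [simulateCounts()], [nbDiffExp()]
#' @export
setClass("MirnaExperiment", contains = "SummarizedExperiment")

setValidity("MirnaExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% names(assays(object)))
        return("assay 'counts' is required")
    cnt <- assay(object, "counts")
    if (anyNA(cnt) || any(cnt < 0))
        msg <- c(msg, "counts must be non-negative and complete")
    if (any(cnt != round(cnt)))
        msg <- c(msg, "counts must be integers")
    if (!"group" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain a 'group' column")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "feature ids must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be unique")
    if (length(msg)) msg else TRUE
})

#' Construct a MirnaExperiment
#'
#' @param counts Integer matrix, features in rows, samples in columns; both
#'   dimensions must be named.
#' @param group Character or factor of per-sample class labels, typically
#'   \code{"Adeno"} and \code{"NE"}.
#' @param compartment Optional per-sample compartment tag (\code{"EV"} or
#'   \code{"tissue"}); recycled if length 1.
#' @param featureKind Optional per-feature kind (\code{"mature"},
#'   \code{"isomir"}, \code{"other"}); recycled if length 1.
#'
#' @return A \linkS4class{MirnaExperiment}.
#' @examples
#' m <- matrix(rpois(20, 50), 4, 5,
#'             dimnames = list(paste0("mir", 1:4), paste0("s", 1:5)))
#' MirnaExperiment(m, group = c("Adeno", "Adeno", "Adeno", "NE", "NE"))
#' @export
MirnaExperiment <- function(counts, group,
                            compartment = "EV",
                            featureKind = "mature") {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    if (length(group) != ncol(counts))
        stop("'group' must have one label per sample")
    cd <- DataFrame(group = as.character(group),
                    compartment = rep_len(as.character(compartment),
                                          ncol(counts)),
                    row.names = colnames(counts))
    rd <- DataFrame(feature_kind = rep_len(as.character(featureKind),
                                           nrow(counts)),
                    row.names = rownames(counts))
    new("MirnaExperiment",
        SummarizedExperiment(assays = list(counts = counts),
                             colData = cd, rowData = rd))
}

#' Boruta all-relevant feature selection result
#'
#' Per-feature decisions from shadow-feature selection: at each iteration a
#' permuted copy of every feature is appended, a random forest is fitted,
#' and features whose importance beats the best shadow importance score a
#' "hit"; hit counts are tested against Binomial(iterations, 1/2).
#'
#' @slot status Named character: \code{"confirmed"}, \code{"rejected"} or
#'   \code{"tentative"} per feature.
#' @slot hits Named integer hit counts.
#' @slot iterations Integer, iterations actually run.
#' @seealso [borutaSelect()]
#' @export
setClass("BorutaResult",
         representation(status = "character", hits = "integer",
                        iterations = "integer"))

setValidity("BorutaResult", function(object) {
    msg <- character()
    if (!all(object@status %in% c("confirmed", "rejected", "tentative")))
        msg <- c(msg, "invalid status value")
    if (!identical(names(object@status), names(object@hits)))
        msg <- c(msg, "status and hits must cover the same features")
    if (any(object@hits > object@iterations))
        msg <- c(msg, "hit counts cannot exceed iterations run")
    if (length(msg)) msg else TRUE
})

#' Leave-pair-out cross-validation result
#'
#' Every (class-1, class-0) sample pair is held out once; the model is
#' trained on the remainder (with nested feature selection when requested)
#' and both held-out samples are scored with the class-1 probability. The
#' AUC is the fraction of pairs in which the class-1 sample outscores the
#' class-0 sample, with half credit for ties.
#'
#' @slot pairs data.frame with one row per pair: held-out sample ids,
#'   their scores, and the number of features selected in that fold.
#' @slot auc Numeric pairwise AUC in [0, 1].
#' @slot selectionFreq Named numeric: per-feature fraction of folds in which
#'   the feature entered the model.
#' @slot importance Named numeric: per-feature mean impurity importance over
#'   the folds that selected it.
#' @slot nestedSelection Logical: was Boruta run inside each fold.
#' @seealso [lpocvAuc()], [rankFeatures()]
#' @export
setClass("LpocvResult",
         representation(pairs = "data.frame", auc = "numeric",
                        selectionFreq = "numeric", importance = "numeric",
                        nestedSelection = "logical"))

setValidity("LpocvResult", function(object) {
    msg <- character()
    if (length(object@auc) != 1L || is.na(object@auc) ||
        object@auc < 0 || object@auc > 1)
        msg <- c(msg, "auc must be a single value in [0, 1]")
    need <- c("pair", "id1", "id0", "score1", "score0")
    if (!all(need %in% names(object@pairs)))
        msg <- c(msg, "pairs table is missing required columns")
    if (length(msg)) msg else TRUE
})

#' Fitted EV-miRNA classifier
#'
#' A random forest trained on the full cohort restricted to a feature panel,
#' with the resolved configuration and its hash for provenance.
#'
#' @slot model A fitted \code{ranger} forest (probability mode).
#' @slot features Character vector, the panel in rank order.
#' @slot classLevels Character, the label levels (class 0, class 1).
#' @slot config List of the training parameters.
#' @slot configHash Character checksum of \code{config}.
#' @seealso [buildFinalClassifier()], [scoreSamples()]
#' @export
setClass("EvClassifier",
         representation(model = "ANY", features = "character",
                        classLevels = "character", config = "list",
                        configHash = "character"))

#' ELISA panel with fitted standard curve
#'
#' Standard concentrations and optical densities, the fitted
#' four-parameter-logistic (4PL) curve, and sample ODs with interpolated
#' concentrations (NA where the OD falls outside the asymptote-guarded
#' range).
#'
#' @slot standards data.frame with columns \code{conc} (ng/ml) and \code{od}.
#' @slot curve Named numeric 4PL parameters
#'   \code{lower}, \code{upper}, \code{ec50}, \code{slope}.
#' @slot sampleOD Numeric sample optical densities.
#' @slot sampleConc Numeric interpolated concentrations (ng/ml), NA if
#'   out of range.
#' @slot truthConc Numeric true concentrations for simulated panels
#'   (length 0 otherwise).
#' @slot r2 Numeric, coefficient of determination of the standard-curve fit.
#' @seealso [fitStandardCurve()], [interpolateConcentration()],
#'   [simulateElisa()]
#' @export
setClass("ElisaPanel",
         representation(standards = "data.frame", curve = "numeric",
                        sampleOD = "numeric", sampleConc = "numeric",
                        truthConc = "numeric", r2 = "numeric"))

setValidity("ElisaPanel", function(object) {
    msg <- character()
    if (!all(c("conc", "od") %in% names(object@standards)))
        msg <- c(msg, "standards need 'conc' and 'od' columns")
    if (length(object@curve) &&
        !all(c("lower", "upper", "ec50", "slope") %in% names(object@curve)))
        msg <- c(msg, "curve must have lower/upper/ec50/slope")
    if (length(msg)) msg else TRUE
})

#' Threshold classification of a concentration biomarker
#'
#' Confusion counts and operating characteristics of calling a sample
#' neuroendocrine when its biomarker concentration is at or above a
#' threshold (EV THBS1 is elevated in neuroendocrine cases).
#'
#' @slot threshold Numeric, ng/ml.
#' @slot tp,fn,tn,fp Integer confusion counts (positive class = NE).
#' @slot sensitivity,specificity Numeric percentages.
#' @slot nExcluded Integer, samples dropped for missing concentration.
#' @seealso [classifyByThreshold()]
#' @export
setClass("ThresholdClassification",
         representation(threshold = "numeric", tp = "integer",
                        fn = "integer", tn = "integer", fp = "integer",
                        sensitivity = "numeric", specificity = "numeric",
                        nExcluded = "integer"))

setValidity("ThresholdClassification", function(object) {
    ok1 <- object@tp + object@fn == 0 ||
        isTRUE(all.equal(object@sensitivity,
                         100 * object@tp / (object@tp + object@fn)))
    ok2 <- object@tn + object@fp == 0 ||
        isTRUE(all.equal(object@specificity,
                         100 * object@tn / (object@tn + object@fp)))
    if (ok1 && ok2) TRUE else "sensitivity/specificity inconsistent with counts"
})
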