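#' Classify small-RNA reads against a mature-miRNA reference
#'
#' Assigns each read to a parent miRNA and a variant class by exact
#' substring-anchored matching (no mismatches, no alignment scoring):
#' \describe{
#'   \item{canonical}{read equals the mature sequence}
#'   \item{iso_3p_addition}{read = mature + 1..\code{maxModLen} extra 3' nt}
#'   \item{iso_3p_trim}{read = mature with 1..\code{maxModLen} 3' nt removed}
#'   \item{iso_5p}{read differs from the mature only by a 5' extension or
#'     truncation of up to \code{maxModLen} nt}
#'   \item{other}{read matches a mature with changes at both ends}
#'   \item{unassigned}{no mature matches within tolerance}
#' }
#' When a read matches several parents, class priority is canonical >
#' iso_3p_addition > iso_3p_trim > iso_5p > other, and ties within a class
#' are broken by lexicographic parent name, so output is deterministic.
#' Seed integrity requires the parent seed (mature positions 2--8) to sit
#' at positions 2--8 of the read itself: all pure 3' variants keep it, 5'
#' register shifts break it.
#'
#' @param reads A named \linkS4class{DNAStringSet} or named character
#'   vector of read sequences (T alphabet; U is normalized).
#' @param reference A \linkS4class{MirnaReference}.
#' @param maxModLen Maximum nucleotides of 5'/3' modification considered.
#' @param minLen Reads shorter than this are reported unassigned.
#'
#' @return A data.frame with columns \code{read_id}, \code{parent} (NA when
#'   unassigned), \code{variant_class}, \code{read_length},
#'   \code{seed_intact} (NA when unassigned) and \code{sequence}.
#' @examples
#' ref <- mirnaReference(c(mirA = "TGAGGTAGTAGGTTGTATAGTT"))
#' classifyReads(c(r1 = "TGAGGTAGTAGGTTGTATAGTTTT"), ref)
#' @export
classifyReads <- function(reads, reference, maxModLen = 4L, minLen = 14L) {
    stopifnot(is(reference, "MirnaReference"))
    seqsIn <- toupper(gsub("U", "T", as.character(reads), ignore.case = TRUE))
    ids <- names(seqsIn)
    if (is.null(ids)) ids <- sprintf("read%06d", seq_along(seqsIn))
    if (any(grepl("[^ACGT]", seqsIn)))
        stop("reads contain non-A/C/G/T characters")

    mat <- mirnaSequences(reference)
    mat <- mat[order(names(mat))]          # lexicographic tie-break
    mlen <- nchar(mat)
    seeds <- mirnaSeeds(reference)

    lookupEnv <- function(keys, values) {
        e <- new.env(hash = TRUE, size = length(keys))
        for (i in seq_along(keys)) {
            prev <- e[[keys[i]]]
            # first (lexicographically smallest) parent wins
            if (is.null(prev)) e[[keys[i]]] <- values[i]
        }
        e
    }
    exactTab <- lookupEnv(unname(mat), names(mat))
    t3keys <- character(0); t3par <- character(0)
    t5keys <- character(0); t5par <- character(0)
    for (j in seq_along(mat)) {
        kmax <- min(maxModLen, mlen[j] - minLen)
        if (kmax >= 1L) for (k in seq_len(kmax)) {
            t3keys <- c(t3keys, substr(mat[j], 1L, mlen[j] - k))
            t3par <- c(t3par, names(mat)[j])
            t5keys <- c(t5keys, substring(mat[j], 1L + k))
            t5par <- c(t5par, names(mat)[j])
        }
    }
    trim3Tab <- lookupEnv(t3keys, t3par)
    trim5Tab <- lookupEnv(t5keys, t5par)

    n <- length(seqsIn)
    parent <- rep(NA_character_, n)
    vclass <- rep("unassigned", n)
    for (i in seq_len(n)) {
        r <- seqsIn[i]; L <- nchar(r)
        if (L < minLen) next
        hit <- exactTab[[r]]
        if (!is.null(hit)) { parent[i] <- hit; vclass[i] <- "canonical"; next }
        # 3' addition: strip 1..maxModLen and look up the mature exactly
        found <- FALSE
        for (k in seq_len(min(maxModLen, L - 1L))) {
            hit <- exactTab[[substr(r, 1L, L - k)]]
            if (!is.null(hit)) {
                parent[i] <- hit; vclass[i] <- "iso_3p_addition"
                found <- TRUE; break
            }
        }
        if (found) next
        hit <- trim3Tab[[r]]
        if (!is.null(hit)) { parent[i] <- hit; vclass[i] <- "iso_3p_trim"; next }
        # 5' truncation, then 5' extension
        hit <- trim5Tab[[r]]
        if (!is.null(hit)) { parent[i] <- hit; vclass[i] <- "iso_5p"; next }
        for (k in seq_len(min(maxModLen, L - 1L))) {
            hit <- exactTab[[substring(r, 1L + k)]]
            if (!is.null(hit)) {
                parent[i] <- hit; vclass[i] <- "iso_5p"
                found <- TRUE; break
            }
        }
        if (found) next
        # both-end changes: scan all (parent, 5'-offset) combinations
        for (j in seq_along(mat)) {
            for (d5 in seq.int(-maxModLen, maxModLen)) {
                d3 <- L - mlen[j] - d5
                if (abs(d3) > maxModLen) next
                a1 <- 1L + max(0L, d5); a2 <- L - max(0L, d3)
                b1 <- 1L + max(0L, -d5); b2 <- mlen[j] - max(0L, -d3)
                if (a2 - a1 != b2 - b1 || a2 < a1 || b2 - b1 + 1L < minLen - 2L * maxModLen)
                    next
                if (substr(r, a1, a2) == substr(mat[j], b1, b2)) {
                    parent[i] <- names(mat)[j]; vclass[i] <- "other"
                    found <- TRUE; break
                }
            }
            if (found) break
        }
    }
    lens <- nchar(seqsIn)
    intact <- ifelse(is.na(parent), NA,
                     lens >= 8L & substr(seqsIn, 2L, 8L) == seeds[parent])
    data.frame(read_id = ids, parent = parent, variant_class = vclass,
               read_length = lens, seed_intact = as.logical(intact),
               sequence = unname(seqsIn))
}

#' @rdname classifyReads
#' @param read A single read sequence.
#' @return \code{classifyRead}: a one-row data.frame.
#' @export
classifyRead <- function(read, reference, maxModLen = 4L, minLen = 14L) {
    classifyReads(stats::setNames(read, "read"), reference,
                  maxModLen = maxModLen, minLen = minLen)
}

#' Collapse isomiR calls to count-matrix features
#'
#' Builds one feature per (parent, variant class, exact read sequence).
#' Canonical features are named by the parent alone; isomiR features are
#' named \code{"parent|class|len<k>"}, with a \code{"|v2"}, \code{"|v3"}
#' suffix (sequences ordered lexicographically) when distinct sequences
#' share parent, class and length. Unassigned reads are excluded from
#' features but counted in the \code{"nUnassigned"} attribute.
#'
#' @param calls A data.frame from [classifyReads()].
#'
#' @return data.frame with columns \code{feature_id}, \code{parent},
#'   \code{variant_class}, \code{sequence}, \code{feature_kind} and
#'   \code{count}; total counts equal the number of assigned reads.
#' @export
collapseToFeatures <- function(calls) {
    if (nrow(calls) == 0L) stop("no calls to collapse")
    ok <- calls$variant_class != "unassigned"
    asg <- calls[ok, , drop = FALSE]
    if (nrow(asg) == 0L) {
        out <- data.frame(feature_id = character(0), parent = character(0),
                          variant_class = character(0), sequence = character(0),
                          feature_kind = character(0), count = integer(0))
        attr(out, "nUnassigned") <- sum(!ok)
        return(out)
    }
    key <- paste(asg$parent, asg$variant_class, asg$sequence, sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    out <- data.frame(parent = vapply(parts, `[`, "", 1L),
                      variant_class = vapply(parts, `[`, "", 2L),
                      sequence = vapply(parts, `[`, "", 3L),
                      count = as.integer(tab))
    out <- out[order(out$parent, out$variant_class, out$sequence), ]
    canon <- out$variant_class == "canonical"
    base <- ifelse(canon, out$parent,
                   paste(out$parent, out$variant_class,
                         paste0("len", nchar(out$sequence)), sep = "|"))
    idx <- stats::ave(seq_along(base), base, FUN = seq_along)
    out$feature_id <- ifelse(idx == 1L, base, paste0(base, "|v", idx))
    out$feature_kind <- ifelse(canon, "mature", "isomir")
    rownames(out) <- NULL
    out <- out[, c("feature_id", "parent", "variant_class", "sequence",
                   "feature_kind", "count")]
    attr(out, "nUnassigned") <- sum(!ok)
    out
}

#' Summarize isomiR calls and differentially expressed isomiRs
#'
#' Produces the two standard characterizations of an isomiR cohort: the
#' read-length histogram of classified reads, and the per-locus count of
#' distinct differentially expressed isomiRs, reporting loci producing at
#' least \code{k} of them (default 3).
#'
#' @param calls Optional data.frame from [classifyReads()]; reads with
#'   class \code{unassigned} are excluded from the histogram.
#' @param deFeatures Optional character vector of differentially expressed
#'   feature ids (isomiR ids carry the \code{"|"} delimiter; mature ids do
#'   not count towards locus totals).
#' @param k Locus report threshold.
#'
#' @return A list with \code{lengthHistogram} (named integer, length ->
#'   reads), \code{lengthRange}, \code{perLocus} (named integer, parent ->
#'   distinct DE isomiRs) and \code{lociAtLeastK}.
#' @export
summarizeIsomirs <- function(calls = NULL, deFeatures = NULL, k = 3L) {
    if (is.null(calls) && is.null(deFeatures))
        stop("supply calls and/or deFeatures")
    hist <- NULL; rng <- NULL
    if (!is.null(calls)) {
        asg <- calls[calls$variant_class != "unassigned", , drop = FALSE]
        if (nrow(asg)) {
            tab <- table(asg$read_length)
            hist <- stats::setNames(as.integer(tab), names(tab))
            rng <- range(asg$read_length)
        }
    }
    perLocus <- integer(0)
    if (!is.null(deFeatures) && length(deFeatures)) {
        iso <- unique(deFeatures[grepl("|", deFeatures, fixed = TRUE)])
        if (length(iso)) {
            par <- vapply(strsplit(iso, "|", fixed = TRUE), `[`, "", 1L)
            tab <- table(par)
            perLocus <- stats::setNames(as.integer(tab), names(tab))
        }
    }
    list(lengthHistogram = hist, lengthRange = rng, perLocus = perLocus,
         lociAtLeastK = perLocus[perLocus >= k])
}

#' Assemble a count matrix from per-sample isomiR features
#'
#' @param featureList Named list (one element per sample) of feature
#'   data.frames from [collapseToFeatures()].
#' @param group Per-sample class labels.
#' @param compartment Per-sample compartment tags.
#' @return A \linkS4class{MirnaExperiment} over the union of features
#'   (absent features count 0).
#' @export
buildCountMatrix <- function(featureList, group, compartment = "EV") {
    stopifnot(length(featureList) >= 1L, !is.null(names(featureList)))
    feats <- sort(unique(unlist(lapply(featureList, `[[`, "feature_id"))))
    m <- matrix(0L, length(feats), length(featureList),
                dimnames = list(feats, names(featureList)))
    kind <- rep("mature", length(feats))
    names(kind) <- feats
    for (j in seq_along(featureList)) {
        f <- featureList[[j]]
        m[f$feature_id, j] <- f$count
        kind[f$feature_id] <- f$feature_kind
    }
    MirnaExperiment(m, group = group, compartment = compartment,
                    featureKind = unname(kind))
}
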