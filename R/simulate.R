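#' Simulate an EV small-RNA count cohort
#'
#' Generates an integer feature-by-sample count matrix with the statistical
#' structure the downstream analysis assumes: negative-binomial counts with
#' variance \eqn{\mu + \alpha \mu^2}, per-sample library-size factors drawn
#' log-uniformly, and a planted set of differentially expressed features
#' whose class-1 (NE) means are shifted by \eqn{2^{\pm lfc}} with signs
#' alternating up/down. The default cohort shape mirrors a two-class serum
#' EV study: 21 adenocarcinoma-like vs 7 neuroendocrine-like samples.
#'
#' @param nClass0,nClass1 Samples per class (Adeno = class 0, NE = class 1);
#'   each at least 2.
#' @param nFeatures Number of features.
#' @param fracDE Fraction of features with a planted fold change.
#' @param lfcMagnitude Planted |log2 fold change| for DE features.
#' @param dispersion NB dispersion \eqn{\alpha \ge 0}; 0 means Poisson.
#' @param libSizeRange Length-2 positive vector; library totals are drawn
#'   log-uniformly in this range and applied as multiplicative size factors
#'   (relative to their geometric mean).
#' @param baselineMeanLogRange Length-2 vector of log10 bounds for baseline
#'   mean expression.
#' @param fracIsomir Fraction of features labeled as isomiR-kind (named
#'   with the \code{"|"} delimiter) rather than mature.
#' @param plantedLfc Optional named numeric vector of signed log2 fold
#'   changes, overriding \code{fracDE}/\code{lfcMagnitude}; names must be
#'   drawn from the generated feature ids \code{mir0001}, ...
#' @param seed Integer seed; identical configuration and seed give
#'   bit-identical output.
#'
#' @return A \linkS4class{MirnaExperiment}; \code{groundTruth(x)$deFeatures}
#'   holds the planted signed log2 fold changes.
#' @examples
#' se <- simulateCounts(nClass0 = 4, nClass1 = 4, nFeatures = 50, seed = 1)
#' head(groundTruth(se)$deFeatures)
#' @export
simulateCounts <- function(nClass0 = 21L, nClass1 = 7L, nFeatures = 300L,
                           fracDE = 0.1, lfcMagnitude = 2,
                           dispersion = 0.2,
                           libSizeRange = c(5e5, 2e6),
                           baselineMeanLogRange = c(0.5, 3.5),
                           fracIsomir = 0, plantedLfc = NULL,
                           seed = 1L) {
    if (nClass0 != round(nClass0) || nClass1 != round(nClass1))
        stop("class sizes must be integers")
    if (nClass0 < 2 || nClass1 < 2)
        stop("each class needs at least 2 samples")
    if (dispersion < 0) stop("dispersion must be non-negative")
    if (fracDE < 0 || fracDE > 1) stop("fracDE must be in [0, 1]")
    if (length(libSizeRange) != 2L || any(libSizeRange <= 0) ||
        libSizeRange[1] > libSizeRange[2])
        stop("libSizeRange must be an increasing positive pair")

    n <- nClass0 + nClass1
    featIds <- sprintf("mir%04d", seq_len(nFeatures))
    withSeed(seed, {
        baseMean <- 10^stats::runif(nFeatures, baselineMeanLogRange[1],
                                    baselineMeanLogRange[2])
        if (is.null(plantedLfc)) {
            nDE <- round(fracDE * nFeatures)
            lfc <- numeric(nFeatures)
            if (nDE > 0) {
                signs <- rep_len(c(1, -1), nDE)
                lfc[seq_len(nDE)] <- signs * lfcMagnitude
            }
        } else {
            if (!all(names(plantedLfc) %in% featIds))
                stop("plantedLfc names must be generated feature ids")
            lfc <- numeric(nFeatures)
            lfc[match(names(plantedLfc), featIds)] <- plantedLfc
        }
        libSizes <- 10^stats::runif(n, log10(libSizeRange[1]),
                                    log10(libSizeRange[2]))
        sf <- libSizes / exp(mean(log(libSizes)))
        kind <- rep("mature", nFeatures)
        if (fracIsomir > 0)
            kind[stats::runif(nFeatures) < fracIsomir] <- "isomir"

        mu <- matrix(baseMean, nFeatures, n)
        isNE <- rep(c(FALSE, TRUE), c(nClass0, nClass1))
        mu[, isNE] <- mu[, isNE] * 2^lfc
        mu <- sweep(mu, 2L, sf, `*`)
        counts <- if (dispersion == 0)
            matrix(stats::rpois(nFeatures * n, mu), nFeatures, n)
        else
            matrix(stats::rnbinom(nFeatures * n, mu = mu,
                                  size = 1 / dispersion), nFeatures, n)
    })
    featIds[kind == "isomir"] <- paste0(featIds[kind == "isomir"],
                                        "|iso_3p_addition|len20")
    dimnames(counts) <- list(featIds, sprintf("s%02d", seq_len(n)))
    se <- MirnaExperiment(counts,
                          group = rep(c("Adeno", "NE"), c(nClass0, nClass1)),
                          compartment = "EV", featureKind = kind)
    de <- lfc[lfc != 0]
    names(de) <- featIds[lfc != 0]
    metadata(se)$groundTruth <- list(deFeatures = de, libSizes = libSizes,
                                     seed = seed)
    se
}

#' Simulate small-RNA reads with isomiR structure
#'
#' Emits reads derived from a mature-miRNA reference according to a variant
#' class drawn per read: canonical (the mature sequence itself), 3'
#' non-templated addition of 1..\code{maxModLen} nucleotides, 3' trimming,
#' or 5' modification (trim or extension; these shift the seed register).
#' Defaults emphasize 3' variation, the structure observed in EV cargo,
#' where isoforms differ from the native mature miRNA at the 3' end while
#' preserving the seed.
#'
#' @param reference A \linkS4class{MirnaReference}.
#' @param readsPerMirna Reads emitted per reference miRNA.
#' @param pCanonical,pIso3pAdd,pIso3pTrim,pIso5p Class probabilities; must
#'   sum to 1 (tolerance 1e-9).
#' @param maxModLen Maximum nucleotides added or removed (>= 1).
#' @param seed Integer seed.
#'
#' @return A list with \code{reads} (named \linkS4class{DNAStringSet}) and
#'   \code{truth} (data.frame: read_id, parent, variant_class). Every
#'   emitted read appears exactly once in the truth table.
#' @examples
#' ref <- mirnaReference(c(mirA = "TGAGGTAGTAGGTTGTATAGTT"))
#' sim <- simulateReads(ref, readsPerMirna = 5, seed = 1)
#' sim$truth
#' @export
simulateReads <- function(reference, readsPerMirna = 100L,
                          pCanonical = 0.45, pIso3pAdd = 0.30,
                          pIso3pTrim = 0.15, pIso5p = 0.10,
                          maxModLen = 4L, seed = 1L) {
    stopifnot(is(reference, "MirnaReference"))
    p <- c(canonical = pCanonical, iso_3p_addition = pIso3pAdd,
           iso_3p_trim = pIso3pTrim, iso_5p = pIso5p)
    if (abs(sum(p) - 1) > 1e-9)
        stop("class probabilities must sum to 1 (got ", sum(p), ")")
    if (any(p < 0)) stop("class probabilities must be non-negative")
    if (maxModLen < 1) stop("maxModLen must be >= 1")
    seqs <- mirnaSequences(reference)
    nRead <- readsPerMirna * length(seqs)
    minKeep <- 14L
    withSeed(seed, {
        parent <- rep(names(seqs), each = readsPerMirna)
        cls <- sample(names(p), nRead, replace = TRUE, prob = p)
        reads <- character(nRead)
        for (i in seq_len(nRead)) {
            m <- seqs[[parent[i]]]
            len <- nchar(m)
            kmax <- min(maxModLen, len - minKeep)
            reads[i] <- switch(cls[i],
                canonical = m,
                iso_3p_addition = paste0(m, randNt(sample.int(maxModLen, 1L))),
                iso_3p_trim = {
                    if (kmax < 1L) cls[i] <- "canonical"
                    if (kmax < 1L) m else substr(m, 1L, len - sample.int(kmax, 1L))
                },
                iso_5p = {
                    if (stats::runif(1) < 0.5 && kmax >= 1L)
                        substring(m, 1L + sample.int(kmax, 1L))
                    else
                        paste0(randNt(sample.int(maxModLen, 1L)), m)
                })
        }
    })
    ids <- sprintf("read%06d", seq_len(nRead))
    dss <- Biostrings::DNAStringSet(reads)
    names(dss) <- ids
    list(reads = dss,
         truth = data.frame(read_id = ids, parent = parent,
                            variant_class = cls))
}

randNt <- function(k) paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                            collapse = "")

#' Write simulated reads as FASTQ
#'
#' @param reads A named \linkS4class{DNAStringSet}.
#' @param path Output FASTQ path.
#' @return \code{path}, invisibly. Dummy Phred quality "I" per base.
#' @export
writeReadsFastq <- function(reads, path) {
    qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
    Biostrings::writeXStringSet(reads, path, format = "fastq",
                                qualities = qual)
    invisible(path)
}

#' Read small-RNA reads from FASTA or FASTQ
#'
#' @param path Input path; format detected from the first character
#'   (\code{@} = FASTQ, \code{>} = FASTA).
#' @return A named \linkS4class{DNAStringSet}.
#' @export
readSmallRnaReads <- function(path) {
    first <- substr(readLines(path, n = 1L), 1L, 1L)
    fmt <- if (identical(first, "@")) "fastq" else "fasta"
    out <- Biostrings::readDNAStringSet(path, format = fmt)
    names(out) <- vapply(strsplit(names(out), "\\s+"), `[`, "", 1L)
    out
}

#' Simulate an ELISA plate
#'
#' Generates optical densities from a four-parameter-logistic (4PL)
#' standard curve with additive Gaussian noise, for both the standard
#' series and a set of samples with known concentrations.
#'
#' @param standards Strictly positive standard concentrations (ng/ml).
#' @param sampleConcs Non-negative sample concentrations (ng/ml).
#' @param curve Named 4PL parameters \code{lower}, \code{upper},
#'   \code{ec50}, \code{slope}; must describe a strictly increasing curve
#'   (upper > lower, slope > 0, ec50 > 0).
#' @param noiseSD OD noise standard deviation.
#' @param seed Integer seed.
#'
#' @return An \linkS4class{ElisaPanel} with true sample concentrations
#'   retained in the \code{truthConc} slot (curve not yet fitted).
#' @examples
#' simulateElisa(2^(0:5), c(3, 12), noiseSD = 0, seed = 1)
#' @export
simulateElisa <- function(standards, sampleConcs,
                          curve = c(lower = 0.05, upper = 2.5,
                                    ec50 = 8, slope = 1.2),
                          noiseSD = 0.02, seed = 1L) {
    if (any(standards <= 0)) stop("standard concentrations must be > 0")
    if (any(sampleConcs < 0)) stop("sample concentrations must be >= 0")
    checkFourPL(curve)
    withSeed(seed, {
        odStd <- fourPL(standards, curve) +
            stats::rnorm(length(standards), 0, noiseSD)
        odSmp <- fourPL(sampleConcs, curve) +
            stats::rnorm(length(sampleConcs), 0, noiseSD)
    })
    new("ElisaPanel",
        standards = data.frame(conc = standards, od = odStd),
        curve = numeric(0), sampleOD = odSmp,
        sampleConc = rep(NA_real_, length(sampleConcs)),
        truthConc = as.numeric(sampleConcs), r2 = numeric(0))
}
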