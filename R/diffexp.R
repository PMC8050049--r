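#' Median-of-ratios size factors
#'
#' Per-sample normalization scalars computed the way the DESeq family of
#' tools does: each sample's factor is the median, over features expressed
#' in every sample, of the ratio of its count to the feature's geometric
#' mean. Scaling a column by a constant scales its factor by the same
#' constant; all-zero rows are ignored. If no feature is expressed in all
#' samples, total-count scaling (normalized to geometric mean 1) is used
#' with a warning.
#'
#' @param counts A count matrix (features x samples) or
#'   \linkS4class{MirnaExperiment}.
#' @return Named positive numeric vector, one factor per sample.
#' @examples
#' m <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
#' computeSizeFactors(m)
#' @export
computeSizeFactors <- function(counts) {
    if (is(counts, "SummarizedExperiment")) counts <- assay(counts, "counts")
    counts <- as.matrix(counts)
    logGeo <- rowMeans(log(counts))
    use <- is.finite(logGeo)            # features with nonzero counts everywhere
    if (!any(use)) {
        warning("no feature expressed in all samples; ",
                "falling back to total-count scaling")
        tot <- colSums(counts)
        sf <- tot / exp(mean(log(tot)))
    } else {
        sf <- apply(counts[use, , drop = FALSE], 2L, function(col)
            exp(stats::median(log(col) - logGeo[use])))
    }
    stats::setNames(as.numeric(sf), colnames(counts))
}

#' Negative-binomial Wald test for differential expression
#'
#' Per-feature two-class test on median-of-ratios-normalized counts. The
#' NB dispersion \eqn{\alpha} (variance \eqn{\mu + \alpha\mu^2}) is
#' estimated per feature by method of moments within each class, pooled
#' with degrees-of-freedom weights and floored at 1e-8. The Wald statistic
#' is the log ratio of class means over its delta-method standard error;
#' p-values are two-sided normal. Fold changes are reported with a
#' pseudo-count of 0.5 on each class mean (class 1 over class 0). Features
#' with all-zero counts get p = 1 and log2fc = 0. BH adjustment and the
#' significance filter are applied by [filterSignificant()], which
#' \code{nbDiffExp} calls with its defaults.
#'
#' @param x Count matrix (features x samples) or
#'   \linkS4class{MirnaExperiment}.
#' @param group Per-sample labels; the reference (class 0) level is
#'   \code{"Adeno"} when present, otherwise the first level. Taken from
#'   \code{colData} when \code{x} is a MirnaExperiment.
#' @param sizeFactors Optional precomputed size factors.
#' @param alpha,fcMin,expressionFloor,useAdjusted Passed to
#'   [filterSignificant()].
#'
#' @return A \linkS4class{DataFrame} with columns \code{feature_id},
#'   \code{base_mean}, \code{log2fc}, \code{p}, \code{padj},
#'   \code{significant} and \code{feature_kind}.
#' @examples
#' se <- simulateCounts(nClass0 = 6, nClass1 = 6, nFeatures = 40, seed = 3)
#' res <- nbDiffExp(se)
#' head(res)
#' @export
nbDiffExp <- function(x, group = NULL, sizeFactors = NULL,
                      alpha = 0.05, fcMin = 2, expressionFloor = 10,
                      useAdjusted = TRUE) {
    kind <- NULL
    if (is(x, "SummarizedExperiment")) {
        if (is.null(group)) group <- colData(x)$group
        if ("feature_kind" %in% colnames(rowData(x)))
            kind <- rowData(x)$feature_kind
        x <- assay(x, "counts")
    }
    x <- as.matrix(x)
    if (is.null(kind)) kind <- rep("mature", nrow(x))
    group <- as.character(group)
    lev <- unique(group)
    if (length(lev) != 2L) stop("exactly two classes required")
    if ("Adeno" %in% lev) lev <- c("Adeno", setdiff(lev, "Adeno"))
    is1 <- group == lev[2]
    n0 <- sum(!is1); n1 <- sum(is1)
    if (n0 < 2L || n1 < 2L) stop("each class needs at least 2 samples")
    if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(x)
    norm <- sweep(x, 2L, sizeFactors, `/`)

    m0 <- rowMeans(norm[, !is1, drop = FALSE])
    m1 <- rowMeans(norm[, is1, drop = FALSE])
    v0 <- apply(norm[, !is1, drop = FALSE], 1L, stats::var)
    v1 <- apply(norm[, is1, drop = FALSE], 1L, stats::var)
    # method-of-moments dispersion per class, pooled by df
    a0 <- (v0 - m0) / m0^2
    a1 <- (v1 - m1) / m1^2
    a0[!is.finite(a0)] <- 0                # all-zero class carries no signal
    a1[!is.finite(a1)] <- 0
    disp <- pmax(1e-8, ((n0 - 1) * a0 + (n1 - 1) * a1) / (n0 + n1 - 2))
    mu0 <- m0 + 0.5; mu1 <- m1 + 0.5
    var0 <- mu0 + disp * mu0^2
    var1 <- mu1 + disp * mu1^2
    se <- sqrt(var1 / (n1 * mu1^2) + var0 / (n0 * mu0^2))
    z <- log(mu1 / mu0) / se
    p <- 2 * stats::pnorm(-abs(z))
    log2fc <- log2(mu1 / mu0)
    allZero <- m0 == 0 & m1 == 0
    p[allZero] <- 1
    log2fc[allZero] <- 0
    # identical per-feature values in both classes: exactly no change
    log2fc[m0 == m1] <- 0

    res <- DataFrame(feature_id = rownames(x),
                     base_mean = (n0 * m0 + n1 * m1) / (n0 + n1),
                     log2fc = unname(log2fc), p = unname(p),
                     padj = NA_real_, significant = FALSE,
                     feature_kind = kind)
    filterSignificant(res, alpha = alpha, fcMin = fcMin,
                      expressionFloor = expressionFloor,
                      useAdjusted = useAdjusted)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1. NaN/NA p-values propagate and are excluded from the number
#' of tests.
#'
#' @param p Numeric vector of p-values in [0, 1] (NA/NaN allowed).
#' @return Adjusted p-values, same length and order as \code{p}.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    out <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    out[ok] <- stats::p.adjust(p[ok], method = "BH")
    out
}

#' Apply the significance filters
#'
#' A feature is flagged significant when its (adjusted, by default)
#' p-value is below \code{alpha} and its absolute fold change exceeds
#' \code{fcMin}. Features whose mean normalized expression is below
#' \code{expressionFloor} ("low expressors") are removed before the BH
#' adjustment and flagging.
#'
#' @param results A \linkS4class{DataFrame}/data.frame with columns
#'   \code{feature_id}, \code{base_mean}, \code{log2fc}, \code{p}.
#' @param alpha Significance level on the (adjusted) p-value.
#' @param fcMin Minimum absolute fold change (linear scale; 2 means
#'   |log2fc| > 1).
#' @param expressionFloor Minimum mean normalized count.
#' @param useAdjusted Use BH-adjusted p (TRUE, default) or raw p.
#' @return The filtered table with \code{padj} and \code{significant}
#'   recomputed.
#' @export
filterSignificant <- function(results, alpha = 0.05, fcMin = 2,
                              expressionFloor = 10, useAdjusted = TRUE) {
    keep <- results$base_mean >= expressionFloor
    res <- results[keep, , drop = FALSE]
    res$padj <- bhAdjust(res$p)
    crit <- if (useAdjusted) res$padj else res$p
    res$significant <- !is.na(crit) & crit < alpha &
        abs(res$log2fc) > log2(fcMin)
    res
}
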