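#' Compare differential expression across compartments
#'
#' Cross-tabulates per-feature direction of change in serum EVs against
#' matched tissue. A feature's direction in a compartment is the sign of
#' its log2 fold change when significant there, and \code{ns} otherwise;
#' the concordance call is a pure function of the two directions:
#' \tabular{lll}{
#'   EV \tab tissue \tab call \cr
#'   up \tab up \tab concordant_up \cr
#'   down \tab down \tab concordant_down \cr
#'   up/down \tab down/up \tab discordant \cr
#'   up/down \tab ns \tab ev_only \cr
#'   ns \tab up/down \tab tissue_only \cr
#'   ns \tab ns \tab ns
#' }
#'
#' @param deEv,deTissue DE tables from [nbDiffExp()] on the EV and tissue
#'   cohorts; compared over their shared feature ids.
#' @return data.frame with columns \code{feature_id}, \code{direction_ev},
#'   \code{direction_tissue}, \code{call}.
#' @export
compareCompartments <- function(deEv, deTissue) {
    shared <- intersect(deEv$feature_id, deTissue$feature_id)
    if (length(shared) == 0L)
        stop("no shared features between compartments")
    dirOf <- function(de, ids) {
        i <- match(ids, de$feature_id)
        ifelse(!de$significant[i], "ns",
               ifelse(de$log2fc[i] > 0, "up", "down"))
    }
    dEv <- dirOf(deEv, shared)
    dTi <- dirOf(deTissue, shared)
    call <- ifelse(dEv == "ns" & dTi == "ns", "ns",
            ifelse(dEv == "ns", "tissue_only",
            ifelse(dTi == "ns", "ev_only",
            ifelse(dEv == dTi,
                   ifelse(dEv == "up", "concordant_up", "concordant_down"),
                   "discordant"))))
    data.frame(feature_id = shared, direction_ev = dEv,
               direction_tissue = dTi, call = call)
}

#' Comparative-Ct (delta-delta-Ct) fold change
#'
#' Relative expression of a target gene versus a reference gene, in a
#' sample relative to a calibrator:
#' \eqn{2^{-((Ct_{t}-Ct_{r}) - (Ct_{t,cal}-Ct_{r,cal}))}}.
#'
#' @param ctTarget,ctRef Ct values of target and reference in the sample.
#' @param ctTargetCal,ctRefCal Ct values in the calibrator.
#' @return Fold change (vectorized).
#' @examples
#' deltaDeltaCt(25, 20, 24, 20)   # ddCt = 1 -> fold 0.5
#' @export
deltaDeltaCt <- function(ctTarget, ctRef, ctTargetCal, ctRefCal) {
    stopifnot(all(is.finite(c(ctTarget, ctRef, ctTargetCal, ctRefCal))))
    2^(-((ctTarget - ctRef) - (ctTargetCal - ctRefCal)))
}

#' Overlap of two feature sets
#'
#' @param a,b Character vectors of feature ids (duplicates ignored).
#' @return List with \code{common}, \code{a_only}, \code{b_only} (sorted)
#'   and a \code{counts} vector.
#' @examples
#' overlapSets(c("a", "b", "c"), c("b", "c", "d"))
#' @export
overlapSets <- function(a, b) {
    a <- unique(a); b <- unique(b)
    out <- list(common = sort(intersect(a, b)),
                a_only = sort(setdiff(a, b)),
                b_only = sort(setdiff(b, a)))
    out$counts <- c(common = length(out$common),
                    a_only = length(out$a_only),
                    b_only = length(out$b_only))
    out
}

checkFourPL <- function(curve) {
    need <- c("lower", "upper", "ec50", "slope")
    if (!all(need %in% names(curve)))
        stop("curve needs parameters ", paste(need, collapse = ", "))
    if (curve[["upper"]] <= curve[["lower"]] || curve[["slope"]] <= 0 ||
        curve[["ec50"]] <= 0)
        stop("non-monotone 4PL parameters: require upper > lower, ",
             "slope > 0, ec50 > 0")
    invisible(curve)
}

#' Four-parameter logistic curve
#'
#' \eqn{OD(c) = lower + (upper - lower) / (1 + (ec50/c)^{slope})};
#' strictly increasing in \eqn{c} for slope > 0, with \eqn{OD(0) = lower}.
#'
#' @param conc Non-negative concentrations (ng/ml).
#' @param curve Named parameters \code{lower}, \code{upper}, \code{ec50},
#'   \code{slope}.
#' @return Optical densities.
#' @export
fourPL <- function(conc, curve) {
    checkFourPL(curve)
    if (any(conc < 0)) stop("concentrations must be non-negative")
    od <- curve[["lower"]] + (curve[["upper"]] - curve[["lower"]]) /
        (1 + (curve[["ec50"]] / conc)^curve[["slope"]])
    od[conc == 0] <- curve[["lower"]]
    unname(od)
}

#' Fit a 4PL standard curve
#'
#' Least-squares fit of the four-parameter logistic to an ELISA standard
#' series (Levenberg-Marquardt). The fitted curve is normalized to the
#' increasing orientation (upper > lower, slope > 0); non-convergence is
#' an error carrying the optimizer diagnostics.
#'
#' @param standards At least 5 standard concentrations spanning the assay
#'   range (ng/ml, strictly positive).
#' @param ods Their measured optical densities.
#' @return Named numeric \code{c(lower, upper, ec50, slope)} with
#'   attributes \code{r2} and \code{residuals}.
#' @examples
#' curve <- c(lower = 0.05, upper = 2.5, ec50 = 8, slope = 1.2)
#' fitStandardCurve(2^(0:5), fourPL(2^(0:5), curve))
#' @export
fitStandardCurve <- function(standards, ods) {
    if (length(standards) < 5L)
        stop("at least 5 standards are required")
    if (any(standards <= 0)) stop("standards must be > 0")
    df <- data.frame(conc = standards, od = ods)
    start <- list(lower = min(ods) - 0.01 * diff(range(ods)),
                  upper = max(ods) + 0.01 * diff(range(ods)),
                  ec50 = exp(mean(log(standards))),
                  slope = if (stats::cor(log(standards), ods) >= 0) 1 else -1)
    fit <- tryCatch(
        minpack.lm::nlsLM(
            od ~ lower + (upper - lower) / (1 + (ec50 / conc)^slope),
            data = df, start = start,
            control = minpack.lm::nls.lm.control(maxiter = 500)),
        error = function(e) stop("4PL fit failed to converge: ",
                                 conditionMessage(e)))
    cf <- stats::coef(fit)
    if (cf[["slope"]] < 0) {      # 4PL symmetry: flip to increasing form
        cf[c("lower", "upper")] <- cf[c("upper", "lower")]
        cf[["slope"]] <- -cf[["slope"]]
    }
    res <- stats::resid(fit)
    r2 <- 1 - sum(res^2) / sum((ods - mean(ods))^2)
    out <- cf[c("lower", "upper", "ec50", "slope")]
    attr(out, "r2") <- r2
    attr(out, "residuals") <- as.numeric(res)
    out
}

#' Invert a 4PL curve to concentrations
#'
#' Closed-form inverse of [fourPL()]. ODs at or beyond the asymptotes are
#' out of the quantifiable range and are flagged NA rather than
#' extrapolated.
#'
#' @param od Optical densities.
#' @param curve Fitted 4PL parameters.
#' @return Concentrations (ng/ml), NA where out of range.
#' @export
interpolateConcentration <- function(od, curve) {
    checkFourPL(curve)
    lo <- curve[["lower"]]; up <- curve[["upper"]]
    ok <- od > lo & od < up
    conc <- rep(NA_real_, length(od))
    conc[ok] <- curve[["ec50"]] *
        ((od[ok] - lo) / (up - od[ok]))^(1 / curve[["slope"]])
    conc
}

#' Fit and interpolate an ELISA panel
#'
#' Fits the 4PL standard curve of an \linkS4class{ElisaPanel} and
#' back-calculates sample concentrations from their ODs.
#'
#' @param panel An \linkS4class{ElisaPanel}, e.g. from [simulateElisa()]
#'   or [readElisaPlate()].
#' @return The panel with \code{curve}, \code{r2} and \code{sampleConc}
#'   filled in.
#' @export
fitElisaPanel <- function(panel) {
    stopifnot(is(panel, "ElisaPanel"))
    curve <- fitStandardCurve(panel@standards$conc, panel@standards$od)
    panel@curve <- curve[c("lower", "upper", "ec50", "slope")]
    panel@r2 <- attr(curve, "r2")
    panel@sampleConc <- interpolateConcentration(panel@sampleOD, panel@curve)
    panel
}

#' Read an ELISA plate table
#'
#' Expects a TSV with columns \code{well}, \code{type} (\code{standard}
#' or \code{sample}), \code{conc_ng_ml} (standards only) and \code{od}.
#'
#' @param path TSV path.
#' @return An \linkS4class{ElisaPanel} (curve not yet fitted).
#' @export
readElisaPlate <- function(path) {
    df <- readTsv(path)
    need <- c("well", "type", "od")
    if (!all(need %in% names(df)))
        stop("plate table needs columns: ", paste(need, collapse = ", "))
    std <- df[df$type == "standard", , drop = FALSE]
    smp <- df[df$type == "sample", , drop = FALSE]
    if (nrow(std) == 0L) stop("no standards on plate")
    new("ElisaPanel",
        standards = data.frame(conc = std$conc_ng_ml, od = std$od),
        curve = numeric(0), sampleOD = smp$od,
        sampleConc = rep(NA_real_, nrow(smp)),
        truthConc = numeric(0), r2 = numeric(0))
}

#' Classify samples by a concentration threshold
#'
#' Calls a sample neuroendocrine (the positive class) when its biomarker
#' concentration is at or above the threshold -- EV-associated THBS1 is
#' elevated in neuroendocrine cases, so high concentrations indicate NE.
#' Samples with missing (out-of-range) concentrations are excluded and
#' counted. Sensitivity and specificity are stored exactly and displayed
#' rounded to the nearest integer percent.
#'
#' @param concentrations Numeric (ng/ml), NA allowed.
#' @param labels Per-sample labels, \code{"Adeno"} or \code{"NE"}.
#' @param threshold Decision threshold in ng/ml (default 7).
#' @return A \linkS4class{ThresholdClassification}.
#' @examples
#' classifyByThreshold(c(3, 5, 12, 9, 2), c("Adeno", "Adeno", "NE", "NE", "NE"))
#' @export
classifyByThreshold <- function(concentrations, labels, threshold = 7) {
    labels <- as.character(labels)
    if (!all(labels %in% c("Adeno", "NE")))
        stop("labels must be 'Adeno' or 'NE'")
    if (length(concentrations) != length(labels))
        stop("one concentration per label required")
    ok <- !is.na(concentrations)
    conc <- concentrations[ok]; lab <- labels[ok]
    pos <- conc >= threshold
    tp <- sum(pos & lab == "NE"); fn <- sum(!pos & lab == "NE")
    fp <- sum(pos & lab == "Adeno"); tn <- sum(!pos & lab == "Adeno")
    sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
    new("ThresholdClassification", threshold = threshold,
        tp = as.integer(tp), fn = as.integer(fn), tn = as.integer(tn),
        fp = as.integer(fp), sensitivity = sens, specificity = spec,
        nExcluded = as.integer(sum(!ok)))
}

#' @rdname ThresholdClassification-class
#' @param x A \linkS4class{ThresholdClassification}.
#' @return \code{confusionCounts}: named integer vector (tp, fn, tn, fp);
#'   \code{sensitivityPct}/\code{specificityPct}: exact percentages.
#' @export
confusionCounts <- function(x) c(tp = x@tp, fn = x@fn, tn = x@tn, fp = x@fp)

#' @rdname ThresholdClassification-class
#' @export
sensitivityPct <- function(x) x@sensitivity

#' @rdname ThresholdClassification-class
#' @export
specificityPct <- function(x) x@specificity
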