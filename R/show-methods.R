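#' @describeIn MirnaReference-class Compact display.
#' @param object Object to display.
#' @export
setMethod("show", "MirnaReference", function(object) {
    s <- object@sequences
    cat("MirnaReference with", length(s), "mature miRNAs\n")
    cat("  lengths:", min(Biostrings::width(s)), "-",
        max(Biostrings::width(s)), "nt\n")
    n <- min(3L, length(s))
    for (i in seq_len(n))
        cat("  ", names(s)[i], " ", as.character(s[[i]]),
            " (seed ", mirnaSeeds(object)[i], ")\n", sep = "")
    if (length(s) > n) cat("  ...\n")
})

#' @describeIn BorutaResult-class Compact display.
#' @param object Object to display.
#' @export
setMethod("show", "BorutaResult", function(object) {
    tab <- table(factor(object@status,
                        levels = c("confirmed", "tentative", "rejected")))
    cat("BorutaResult:", length(object@status), "features,",
        object@iterations, "iterations\n")
    cat("  confirmed:", tab[["confirmed"]],
        " tentative:", tab[["tentative"]],
        " rejected:", tab[["rejected"]], "\n")
})

#' @describeIn LpocvResult-class Compact display.
#' @param object Object to display.
#' @export
setMethod("show", "LpocvResult", function(object) {
    cat("LpocvResult:", nrow(object@pairs), "held-out pairs, AUC =",
        format(object@auc, digits = 4), "\n")
    cat("  nested feature selection:",
        if (object@nestedSelection) "on" else "off", "\n")
    top <- utils::head(names(sort(object@selectionFreq, decreasing = TRUE)), 5)
    if (length(top)) cat("  most-selected:", paste(top, collapse = ", "), "\n")
})

#' @describeIn EvClassifier-class Compact display.
#' @param object Object to display.
#' @export
setMethod("show", "EvClassifier", function(object) {
    cat("EvClassifier:", length(object@features), "feature panel",
        paste0("(config ", substr(object@configHash, 1, 8), ")\n"))
    cat("  panel:", paste(utils::head(object@features, 6), collapse = ", "))
    if (length(object@features) > 6) cat(", ...")
    cat("\n")
})

#' @describeIn ElisaPanel-class Compact display.
#' @param object Object to display.
#' @export
setMethod("show", "ElisaPanel", function(object) {
    cat("ElisaPanel:", nrow(object@standards), "standards,",
        length(object@sampleOD), "samples\n")
    if (length(object@curve))
        cat("  4PL: lower=", format(object@curve[["lower"]], digits = 3),
            " upper=", format(object@curve[["upper"]], digits = 3),
            " ec50=", format(object@curve[["ec50"]], digits = 4),
            " slope=", format(object@curve[["slope"]], digits = 3),
            if (length(object@r2)) paste0("  R2=", format(object@r2, digits = 4)),
            "\n", sep = "")
})

#' @describeIn ThresholdClassification-class Compact display.
#' @param object Object to display.
#' @export
setMethod("show", "ThresholdClassification", function(object) {
    cat("ThresholdClassification at", object@threshold, "ng/ml\n")
    cat("  TP:", object@tp, " FN:", object@fn,
        " TN:", object@tn, " FP:", object@fp, "\n")
    cat("  sensitivity:", paste0(round(object@sensitivity), "%"),
        " specificity:", paste0(round(object@specificity), "%\n"))
    if (object@nExcluded > 0)
        cat("  excluded (missing concentration):", object@nExcluded, "\n")
})
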