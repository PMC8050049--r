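#' Load a mature-miRNA reference from FASTA
#'
#' Reads mature miRNA sequences (e.g. a miRBase extract), normalizes U to T,
#' and precomputes nothing beyond the sequence store: seeds are always the
#' 7-mer at positions 2--8 and are derived on access. Duplicate sequences
#' under different names are legal in miRBase and are kept with a warning;
#' duplicate names are an error.
#'
#' @param path Path to a FASTA file (DNA or RNA alphabet).
#'
#' @return A \linkS4class{MirnaReference}.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">hsa-miR-x", "UGAGGUAGUAGGUUGUAUAGUU"), fa)
#' ref <- loadMirnaReference(fa)
#' mirnaSeeds(ref)
#' @export
loadMirnaReference <- function(path) {
    raw <- tryCatch(Biostrings::readBStringSet(path),
                    error = function(e) stop("cannot read FASTA: ",
                                             conditionMessage(e)))
    if (length(raw) == 0L)
        stop("empty FASTA: no sequences in ", path)
    # keep the first whitespace-delimited token of each header
    names(raw) <- vapply(strsplit(names(raw), "\\s+"), `[`, "", 1L)
    if (anyDuplicated(names(raw)))
        stop("duplicate miRNA names in reference: ",
             paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", "))
    seqs <- toupper(gsub("U", "T", as.character(raw), ignore.case = TRUE))
    bad <- grepl("[^ACGT]", seqs)
    if (any(bad))
        stop("non-nucleotide characters in: ",
             paste(names(raw)[bad], collapse = ", "))
    dss <- Biostrings::DNAStringSet(seqs)
    names(dss) <- names(raw)
    if (anyDuplicated(seqs))
        warning("duplicate mature sequences under distinct names")
    new("MirnaReference", sequences = dss)
}

#' Build a reference from in-memory sequences
#'
#' @param sequences Named character vector of mature sequences (U or T
#'   alphabet).
#' @return A \linkS4class{MirnaReference}.
#' @export
mirnaReference <- function(sequences) {
    seqs <- toupper(gsub("U", "T", as.character(sequences),
                         ignore.case = TRUE))
    dss <- Biostrings::DNAStringSet(seqs)
    names(dss) <- names(sequences)
    new("MirnaReference", sequences = dss)
}

#' @rdname MirnaReference-class
#' @param x A \linkS4class{MirnaReference}.
#' @return \code{mirnaNames}: character vector of miRNA names.
#' @export
mirnaNames <- function(x) names(x@sequences)

#' @rdname MirnaReference-class
#' @return \code{mirnaSequences}: named character vector of T-normalized
#'   mature sequences.
#' @export
mirnaSequences <- function(x) {
    out <- as.character(x@sequences)
    names(out) <- names(x@sequences)
    out
}

#' @rdname MirnaReference-class
#' @return \code{mirnaSeeds}: named character vector of 7-mer seeds
#'   (positions 2--8 of each mature sequence).
#' @export
mirnaSeeds <- function(x) {
    out <- substr(as.character(x@sequences), 2L, 8L)
    names(out) <- names(x@sequences)
    out
}

#' @rdname MirnaExperiment
#' @param x A \linkS4class{MirnaExperiment} produced by [simulateCounts()].
#' @return \code{groundTruth}: the simulation ground truth (list with
#'   \code{deFeatures}, a named vector of planted signed log2 fold changes),
#'   or NULL for non-simulated data.
#' @export
groundTruth <- function(x) metadata(x)$groundTruth
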