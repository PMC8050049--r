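# Internal helpers.

# Evaluate expr under a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
        get(".Random.seed", globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    invisible(eval(substitute(expr), envir = parent.frame()))
}

# Fresh sub-seed drawn from the current RNG stream, safe for 32-bit ints.
subSeed <- function() sample.int(.Machine$integer.max, 1L)

# md5 of a serialized R object (base tools only).
hashObject <- function(x) {
    f <- tempfile()
    on.exit(unlink(f))
    saveRDS(x, f, version = 2L, compress = FALSE)
    unname(tools::md5sum(f))
}

writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

readTsv <- function(path) {
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE)
}
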