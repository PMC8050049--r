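# Fixtures shared across test files; everything is generated in code.

# A tiny hand-written reference with known seeds.
handReference <- function() {
    mirnaReference(c(
        "hsa-let-7x"  = "TGAGGTAGTAGGTTGTATAGTT",
        "hsa-miR-21x" = "TAGCTTATCAGACTGATGTTGA",
        "hsa-miR-92x" = "TATTGCACTTGTCCCGGCCTGT"))
}

# Sample-by-feature table with one perfectly separating feature.
separableTable <- function(n0 = 5, n1 = 4, nNoise = 5, seed = 1) {
    set.seed(seed)
    n <- n0 + n1
    x <- cbind(sep = c(rnorm(n0, 0, 0.2), rnorm(n1, 5, 0.2)),
               matrix(rnorm(n * nNoise), n, nNoise,
                      dimnames = list(NULL, paste0("noise", seq_len(nNoise)))))
    rownames(x) <- paste0("s", seq_len(n))
    new("FeatureTable", x = x,
        y = factor(rep(c("Adeno", "NE"), c(n0, n1)),
                   levels = c("Adeno", "NE")))
}

# Brute-force BH step-up from the definition: the adjusted value of p_i is
# the smallest t*m/rank(t) over candidate thresholds t >= p_i, capped at 1.
bruteForceBH <- function(p) {
    m <- length(p)
    vapply(p, function(pi) {
        cand <- p[p >= pi]
        min(1, min(vapply(cand, function(t) t * m / sum(p <= t), 0)))
    }, 0)
}

writeTempFasta <- function(records) {
    fa <- tempfile(fileext = ".fa")
    writeLines(unlist(lapply(names(records), function(n)
        c(paste0(">", n), records[[n]]))), fa)
    fa
}
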