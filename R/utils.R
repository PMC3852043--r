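#' @importFrom stats cor rnorm runif rlnorm sd setNames quantile
NULL

# run expr with a local RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    expr
}

# derived 32-bit seed streams (kept < 2^31)
.deriveSeed <- function(seed, stream) {
    as.integer((as.double(seed) * 48271 + as.double(stream) * 1299709) %%
               2147483647)
}

# djb2 string hash, folded into [0, 2^31)
.hashString <- function(s) {
    h <- 5381
    for (k in utf8ToInt(s)) h <- (h * 33 + k) %% 2147483647
    as.integer(h)
}

.senseCodons <- function() {
    gc <- Biostrings::GENETIC_CODE
    sort(names(gc)[gc != "*"])
}

.aaLetters <- function() {
    gc <- Biostrings::GENETIC_CODE
    sort(unique(gc[gc != "*"]))
}

# genes x 61 sense-codon count matrix (codon-frame trinucleotides)
.codonCounts <- function(orfs) {
    cnt <- Biostrings::trinucleotideFrequency(orfs, step = 3)
    cnt <- cnt[, .senseCodons(), drop = FALSE]
    rownames(cnt) <- names(orfs)
    cnt
}

# genes x 3721 sense codon-pair counts (adjacent codons, codon frame)
.codonPairCounts <- function(orfs) {
    sense <- .senseCodons()
    hex <- Biostrings::oligonucleotideFrequency(orfs, width = 6, step = 3)
    pairs <- as.vector(outer(sense, sense, paste0))
    m <- hex[, pairs, drop = FALSE]
    colnames(m) <- as.vector(outer(sense, sense, paste, sep = "_"))
    rownames(m) <- names(orfs)
    m
}

.rowNormalize <- function(m) {
    s <- rowSums(m)
    out <- m / ifelse(s > 0, s, 1)
    out
}
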