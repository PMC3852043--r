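# shared fixtures (memoised so expensive extractions run once per session)
.fx <- new.env()

tinyTx <- function() {
    if (is.null(.fx$ts)) .fx$ts <- generateTranscriptome(tinyProfile(seed = 7))
    .fx$ts
}

tinyFeatures <- function() {
    if (is.null(.fx$fs)) .fx$fs <- extractFeatures(tinyTx())
    .fx$fs
}

standardRun <- function() {
    if (is.null(.fx$std)) {
        cfg <- standardProfile(seed = 5)
        ts <- generateTranscriptome(cfg)
        fs <- extractFeatures(ts)
        expr <- generateExpression(ts, fs, cfg)
        .fx$std <- list(ts = ts, fs = fs, expr = expr, cfg = cfg)
    }
    .fx$std
}

# exhaustive maximum-weight secondary structure by direct recursion over all
# admissible pairings (independent of the DP implementation)
bruteForceFold <- function(s, minLoop = 3, w = c(GC = 3, AU = 2, GU = 1)) {
    ch <- strsplit(toupper(s), "")[[1]]
    pw <- function(a, b) {
        p <- paste0(sort(c(a, b)), collapse = "")
        if (p == "CG") w[["GC"]] else if (p == "AT") w[["AU"]]
        else if (p == "GT") w[["GU"]] else 0
    }
    rec <- function(i, j) {
        if (j - i <= minLoop) return(0)
        best <- rec(i + 1, j)
        for (k in (i + minLoop + 1):j) {
            wk <- pw(ch[i], ch[k])
            if (wk > 0)
                best <- max(best, wk + rec(i + 1, k - 1) +
                                  (if (k < j) rec(k + 1, j) else 0))
        }
        best
    }
    if (length(ch) < 2) return(0)
    rec(1, length(ch))
}

# exhaustive first-two-feature oracle for the greedy selection (linear)
bruteForcePair <- function(X, y, train) {
    Xtr <- scale(X[train, , drop = FALSE])
    ytr <- y[train]
    corFit <- function(cols) {
        d <- data.frame(y = ytr, Xtr[, cols, drop = FALSE])
        f <- stats::lm(y ~ ., data = d)
        stats::cor(stats::fitted(f), ytr)
    }
    p <- colnames(X)
    r1 <- vapply(p, function(f) corFit(f), 0)
    f1 <- p[which(r1 >= max(r1) - 1e-10)[1]]
    rest <- setdiff(p, f1)
    r2 <- vapply(rest, function(f) corFit(c(f1, f)), 0)
    f2 <- rest[which(r2 >= max(r2) - 1e-10)[1]]
    c(f1, f2)
}

randomOrf <- function(nCodons, seed) {
    set.seed(seed)
    sense <- setdiff(names(Biostrings::GENETIC_CODE)[
        Biostrings::GENETIC_CODE != "*"], character(0))
    paste0("ATG", paste(sample(sense, nCodons - 2, replace = TRUE),
                        collapse = ""), "TAA")
}
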