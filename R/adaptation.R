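#' Default wobble penalty parameters for the tRNA adaptation index
#'
#' Selective constraints s for each codon:anticodon pairing class, named
#' "<anticodon wobble base>.<codon third base>". Watson-Crick pairings carry
#' no penalty; the standard wobble penalties are G:U 0.41, I:C 0.28,
#' I:A 0.9999, U:G 0.68.
#' @return named numeric vector of s parameters
#' @export
taiDefaultS <- function() {
    c(A.T = 0, G.C = 0, T.A = 0, C.G = 0,
      G.T = 0.41, A.C = 0.28, A.A = 0.9999, T.G = 0.68)
}

.revcomp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# wobble pairing classes: for each codon, the perfect anticodon plus the
# single-wobble anticodon and the names of the s parameters involved
.codonPairings <- function() {
    sense <- .senseCodons()
    third <- substr(sense, 3, 3)
    perfect <- .revcomp(sense)
    wobbleBase <- c(T = "G", C = "A", A = "A", G = "T")[third]
    wobble <- paste0(wobbleBase, substr(perfect, 2, 3))
    sPerfect <- paste(substr(perfect, 1, 1), third, sep = ".")
    sWobble <- paste(wobbleBase, third, sep = ".")
    data.frame(codon = sense, perfect = perfect, wobble = wobble,
               sPerfect = sPerfect, sWobble = sWobble,
               stringsAsFactors = FALSE)
}

#' tRNA adaptation index weights from tRNA gene copy numbers
#'
#' For each sense codon, the absolute adaptiveness is
#' W_c = sum over cognate anticodons of (1 - s_pairing) x copies; relative
#' weights w_c = W_c / max(W). Codons with zero W receive the geometric mean
#' of the non-zero weights so that logarithms stay defined.
#'
#' @param trnaCopies data.frame with columns anticodon (5'->3' DNA) and copies
#' @param s wobble penalties, see \code{\link{taiDefaultS}}
#' @return named numeric weight vector over the 61 sense codons with
#'   attributes provenance and s
#' @export
taiWeights <- function(trnaCopies, s = taiDefaultS()) {
    stopifnot(all(c("anticodon", "copies") %in% names(trnaCopies)))
    if (all(trnaCopies$copies == 0)) stop("all tRNA copy numbers are zero")
    cp <- setNames(trnaCopies$copies,
                   chartr("U", "T", toupper(trnaCopies$anticodon)))
    pair <- .codonPairings()
    getCp <- function(a) ifelse(is.na(cp[a]), 0, cp[a])
    W <- (1 - s[pair$sPerfect]) * getCp(pair$perfect) +
         (1 - s[pair$sWobble]) * getCp(pair$wobble)
    w <- as.numeric(W) / max(W)
    names(w) <- pair$codon
    nz <- w > 0
    if (any(!nz)) w[!nz] <- exp(mean(log(w[nz])))
    structure(w, provenance = "tRNA_copy_number", s = s)
}

#' Codon adaptation index weights from a reference gene set
#'
#' w_c = count(c) / count(most frequent synonymous codon of c's amino acid),
#' with counts pooled over the reference ORFs and zero counts imputed with a
#' 0.5 pseudocount.
#' @param referenceOrfs DNAStringSet (or named character) of reference ORFs
#' @return named numeric weight vector over the 61 sense codons
#' @export
caiWeights <- function(referenceOrfs) {
    if (is.character(referenceOrfs))
        referenceOrfs <- Biostrings::DNAStringSet(referenceOrfs)
    if (length(referenceOrfs) < 1) stop("need at least one reference ORF")
    cnt <- colSums(.codonCounts(referenceOrfs))
    cnt[cnt == 0] <- 0.5
    gc <- Biostrings::GENETIC_CODE
    aa <- gc[names(cnt)]
    mx <- tapply(cnt, aa, max)
    w <- as.numeric(cnt / mx[aa])
    names(w) <- names(cnt)
    structure(w, provenance = "reference_set")
}

#' Geometric-mean adaptation index of a gene
#'
#' Geometric mean of the codon weights over the gene's sense codons (start
#' codon included, stop codons excluded); values in (0, 1].
#' @param orfs DNAStringSet (or character) of ORFs, or a precomputed sense
#'   codon count matrix
#' @param weights named weights over the 61 sense codons
#' @return numeric vector, one index per gene
#' @export
geneIndex <- function(orfs, weights) {
    cnt <- if (is.matrix(orfs)) orfs else {
        if (is.character(orfs)) orfs <- Biostrings::DNAStringSet(orfs)
        .codonCounts(orfs)
    }
    w <- weights[colnames(cnt)]
    n <- rowSums(cnt)
    idx <- exp(as.numeric(cnt %*% log(w)) / ifelse(n > 0, n, 1))
    names(idx) <- rownames(cnt)
    idx
}

#' Expression-free reference selection (scheme A)
#'
#' Ranks genes by tAI computed from tRNA copy numbers (a transcript-only
#' proxy for high expression) and returns the top fraction as the reference
#' set used for CAI weights and context-PSSM training. Ties are broken by
#' gene id so the selection is deterministic.
#' @param ts TranscriptSet
#' @param weightsTai tAI weights with tRNA copy-number provenance
#' @param topFraction fraction of genes to keep (default 0.1)
#' @param minGenes smallest admissible reference size (default 10)
#' @return character vector of selected gene ids
#' @export
schemeAReference <- function(ts, weightsTai, topFraction = 0.1,
                             minGenes = 10) {
    idx <- geneIndex(orf(ts), weightsTai)
    k <- max(1, round(topFraction * length(idx)))
    ord <- order(-idx, names(idx))
    sel <- names(idx)[ord][seq_len(k)]
    if (length(sel) < minGenes)
        stop("reference selection yielded fewer than ", minGenes, " genes")
    sel
}

#' Optimize adaptation weights on the train tercile's mRNA levels (scheme B)
#'
#' Deterministic coordinate-ascent hill climbing maximising the Spearman
#' correlation between the gene index and the train-set mRNA levels. For
#' tRNA-provenance weights the wobble s parameters are tuned (clamped to
#' [0, 0.9999]); otherwise the per-codon weights themselves are tuned
#' (clamped to (0, 1]). Stops when no single-parameter step of size delta
#' improves the objective, or after maxSweeps sweeps.
#'
#' @param weights0 starting weights (from \code{taiWeights}/\code{caiWeights})
#' @param trainOrfs DNAStringSet/character/codon-count matrix of the train
#'   tercile genes only
#' @param trainMrna mRNA levels of the same train genes (same order)
#' @param trnaCopies the copy-number table (required for tRNA provenance)
#' @param delta coordinate step size (default 0.05)
#' @param maxSweeps maximum full passes over the parameters (default 200)
#' @return optimized weights; attribute "objective" holds the achieved
#'   Spearman correlation
#' @export
schemeBOptimize <- function(weights0, trainOrfs, trainMrna, trnaCopies = NULL,
                            delta = 0.05, maxSweeps = 200) {
    cnt <- if (is.matrix(trainOrfs)) trainOrfs else {
        if (is.character(trainOrfs)) trainOrfs <- Biostrings::DNAStringSet(trainOrfs)
        .codonCounts(trainOrfs)
    }
    stopifnot(nrow(cnt) == length(trainMrna))
    ok <- is.finite(trainMrna) & trainMrna > 0
    cnt <- cnt[ok, , drop = FALSE]; y <- log(trainMrna[ok])
    obj <- function(w) {
        v <- suppressWarnings(cor(geneIndex(cnt, w), y, method = "spearman"))
        if (!is.finite(v)) stop("non-finite scheme-B objective")
        v
    }
    prov <- attr(weights0, "provenance")
    if (identical(prov, "tRNA_copy_number")) {
        if (is.null(trnaCopies)) stop("trnaCopies required to retune s")
        s <- attr(weights0, "s")
        tune <- c("G.T", "A.C", "A.A", "T.G")
        best <- obj(weights0)
        for (sweep in seq_len(maxSweeps)) {
            improved <- FALSE
            for (p in tune) for (dir in c(1, -1)) {
                s2 <- s
                s2[p] <- min(0.9999, max(0, s2[p] + dir * delta))
                if (s2[p] == s[p]) next
                cand <- obj(taiWeights(trnaCopies, s2))
                if (cand > best) { best <- cand; s <- s2; improved <- TRUE }
            }
            if (!improved) break
        }
        w <- taiWeights(trnaCopies, s)
        attr(w, "provenance") <- "train_optimized"
    } else {
        w <- as.numeric(weights0); names(w) <- names(weights0)
        best <- obj(w)
        for (sweep in seq_len(maxSweeps)) {
            improved <- FALSE
            for (p in names(w)) for (dir in c(1, -1)) {
                w2 <- w
                w2[p] <- min(1, max(delta / 10, w2[p] + dir * delta))
                if (w2[p] == w[p]) next
                cand <- obj(w2)
                if (cand > best) { best <- cand; w <- w2; improved <- TRUE }
            }
            if (!improved) break
        }
        w <- w / max(w)
        w <- structure(w, provenance = "train_optimized")
        best <- obj(w)
    }
    attr(w, "objective") <- best
    w
}

#' Build a start-codon context PSSM
#'
#' Per-position nucleotide frequencies (pseudocount 1) in the window 6 nt
#' upstream / 3 nt downstream of the main START of the training genes,
#' converted to log-odds against the pooled background frequency over all
#' observed context positions.
#' @param ts TranscriptSet
#' @param trainingIds gene ids to train on (e.g. from
#'   \code{\link{schemeAReference}})
#' @param up,down window extent in nt (default 6 and 3)
#' @param pseudocount added per cell (default 1)
#' @return list with elements logodds (positions x ACGT), freq, background,
#'   up, down
#' @export
buildContextPssm <- function(ts, trainingIds = geneIds(ts), up = 6L,
                             down = 3L, pseudocount = 1) {
    sub <- ts[match(trainingIds, geneIds(ts))]
    cw <- .contextWindows(sub, up, down)
    npos <- up + down
    counts <- matrix(pseudocount, npos, 4,
                     dimnames = list(NULL, c("A", "C", "G", "T")))
    for (g in cw) {
        ch <- g$main
        for (p in seq_len(npos))
            if (!is.na(ch[p])) counts[p, ch[p]] <- counts[p, ch[p]] + 1
    }
    freq <- counts / rowSums(counts)
    bgCounts <- colSums(counts) - 4 * (pseudocount - 1)  # pooled, pseudocounted
    background <- bgCounts / sum(bgCounts)
    logodds <- log(sweep(freq, 2, background, "/"))
    list(logodds = logodds, freq = freq, background = background,
         up = up, down = down)
}
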