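#' @importFrom Biostrings vcountPattern letterFrequency subseq
NULL

# overlapping (step-1) ATG count per sequence
.countAtg <- function(seqs) Biostrings::vcountPattern("ATG", seqs)

.compBlock <- function(seqs, prefix, withAtg = TRUE) {
    w <- Biostrings::width(seqs)
    lf <- Biostrings::letterFrequency(seqs, c("A", "C", "G", "T"))
    den <- ifelse(w > 0, w, 1)
    out <- cbind(gc = (lf[, "C"] + lf[, "G"]) / den,
                 freq_A = lf[, "A"] / den, freq_C = lf[, "C"] / den,
                 freq_G = lf[, "G"] / den, freq_T = lf[, "T"] / den)
    if (withAtg) out <- cbind(out, n_atg = .countAtg(seqs))
    colnames(out) <- paste(prefix, colnames(out), sep = ".")
    out
}

.clipSub <- function(seqs, fromStart, len) {
    # fromStart TRUE: first `len` nt, FALSE: last `len` nt; clipped
    w <- Biostrings::width(seqs)
    l <- pmin(w, len)
    if (fromStart) subseq(seqs, start = 1, width = l)
    else subseq(seqs, start = w - l + 1, width = l)
}

#' Length features of a transcript
#'
#' Segment lengths in nt, ORF length in codons, and length ratios
#' (5'UTR/ORF, 3'UTR/ORF, UTRs/transcript).
#' @param ts a TranscriptSet
#' @return numeric matrix, genes x features
#' @export
lengthFeatures <- function(ts) {
    w5 <- Biostrings::width(utr5(ts)); wo <- Biostrings::width(orf(ts))
    w3 <- Biostrings::width(utr3(ts)); wt <- w5 + wo + w3
    m <- cbind(UTR5.length.nt = w5, ORF.length.nt = wo,
               ORF.length.codons = wo / 3, UTR3.length.nt = w3,
               TRANSCRIPT.length.nt = wt,
               TRANSCRIPT.length.ratio_utr5_orf = w5 / wo,
               TRANSCRIPT.length.ratio_utr3_orf = w3 / wo,
               TRANSCRIPT.length.ratio_utrs_tx = (w5 + w3) / wt)
    rownames(m) <- geneIds(ts)
    m
}

#' Composition features
#'
#' GC content, mononucleotide frequencies and overlapping ATG counts per
#' segment and for the whole transcript, plus the same restricted to the
#' "30-codon" windows: first/last 90 nt of the ORF, last 90 nt of the 5'UTR,
#' first 90 nt of the 3'UTR (windows truncated to the segment length).
#' @param ts a TranscriptSet
#' @param window window size in nt for the 30-codon blocks (default 90)
#' @return numeric matrix, genes x features
#' @export
compositionFeatures <- function(ts, window = 90L) {
    tx <- Biostrings::xscat(utr5(ts), orf(ts), utr3(ts))
    m <- cbind(.compBlock(utr5(ts), "UTR5.comp"),
               .compBlock(orf(ts), "ORF.comp"),
               .compBlock(utr3(ts), "UTR3.comp"),
               .compBlock(tx, "TRANSCRIPT.comp"),
               .compBlock(.clipSub(orf(ts), TRUE, window), "ORF.comp30.first",
                          withAtg = FALSE),
               .compBlock(.clipSub(orf(ts), FALSE, window), "ORF.comp30.last",
                          withAtg = FALSE),
               .compBlock(.clipSub(utr5(ts), FALSE, window), "UTR5.comp30.last",
                          withAtg = FALSE),
               .compBlock(.clipSub(utr3(ts), TRUE, window), "UTR3.comp30.first",
                          withAtg = FALSE))
    rownames(m) <- geneIds(ts)
    m
}

#' Codon, amino-acid and pair frequency features of the ORF
#'
#' Relative frequencies of the 61 sense codons, the 20 amino acids, all
#' 61 x 61 ordered adjacent codon pairs and all 20 x 20 ordered amino-acid
#' pairs. Each family sums to 1 per gene; pair families require at least two
#' sense codons (otherwise all-zero defaults). Stop codons (terminal or
#' internal) are excluded from the sense counts.
#' @param ts a TranscriptSet (or a DNAStringSet of ORFs)
#' @return numeric matrix, genes x (61+20+3721+400) features
#' @export
codonPairFeatures <- function(ts) {
    orfs <- if (is(ts, "TranscriptSet")) orf(ts) else ts
    sense <- .senseCodons(); aas <- .aaLetters()
    gc <- Biostrings::GENETIC_CODE
    cod <- .codonCounts(orfs)
    codF <- .rowNormalize(cod)
    colnames(codF) <- paste0("ORF.codon.", sense)
    aaInd <- outer(gc[sense], aas, "==") * 1  # 61 x 20
    aa <- cod %*% aaInd
    aaF <- .rowNormalize(aa)
    colnames(aaF) <- paste0("ORF.aa.", aas)
    cp <- .codonPairCounts(orfs)
    cpF <- .rowNormalize(cp)
    colnames(cpF) <- paste0("ORF.codon_pair.", colnames(cp))
    # amino-acid pairs: collapse codon pairs through the genetic code
    pairAa <- expand.grid(a = gc[sense], b = gc[sense],
                          stringsAsFactors = FALSE)
    grpRow <- match(pairAa$a, aas); grpCol <- match(pairAa$b, aas)
    grp <- (grpCol - 1L) * length(aas) + grpRow
    ap <- matrix(0, nrow(cp), length(aas)^2)
    for (g in seq_len(length(aas)^2)) {
        idx <- which(grp == g)
        if (length(idx)) ap[, g] <- rowSums(cp[, idx, drop = FALSE])
    }
    apF <- .rowNormalize(ap)
    colnames(apF) <- paste0("ORF.aa_pair.",
                            as.vector(outer(aas, aas, paste, sep = "_")))
    m <- cbind(codF, aaF, cpF, apF)
    rownames(m) <- names(orfs)
    m
}

# all overlapping ATG start offsets (0-based) in a character sequence
.atgOffsets <- function(s) {
    if (nchar(s) < 3) return(integer(0))
    g <- gregexpr("(?=ATG)", s, perl = TRUE)[[1]]
    if (g[1] == -1) return(integer(0))
    as.integer(g) - 1L
}

# does an in-frame stop codon start at offset a+3k, fully inside [0, len)?
.hasInframeStop <- function(s, a) {
    len <- nchar(s)
    b <- a + 3L
    while (b + 3L <= len) {
        if (substr(s, b + 1L, b + 3L) %in% STOP_CODONS) return(TRUE)
        b <- b + 3L
    }
    FALSE
}

#' Upstream ORFs in the 5'UTR
#'
#' A uORF is an ATG in the 5'UTR with an in-frame stop codon downstream and
#' entirely within the 5'UTR (set \code{stopInUtr = FALSE} to also accept a
#' stop inside the ORF continuation). The first-ATG distance is the number of
#' nucleotides between the first ATG (uORF-forming or not) and the main
#' START; when the UTR has no ATG it takes the sentinel utr5 length + 1.
#' @param ts TranscriptSet (or named character vector of 5'UTRs)
#' @param orfSeqs ORF sequences, only needed when \code{stopInUtr = FALSE}
#' @param stopInUtr logical; see above
#' @return matrix with columns UTR5.init.n_uorfs, UTR5.init.first_atg_dist
#' @export
findUorfs <- function(ts, orfSeqs = NULL, stopInUtr = TRUE) {
    if (is(ts, "TranscriptSet")) {
        seqs <- setNames(as.character(utr5(ts)), geneIds(ts))
        if (is.null(orfSeqs)) orfSeqs <- as.character(orf(ts))
    } else seqs <- ts
    n <- length(seqs)
    cnt <- integer(n); dist <- numeric(n)
    for (i in seq_len(n)) {
        s <- seqs[[i]]
        len <- nchar(s)
        atg <- .atgOffsets(s)
        scan <- if (stopInUtr) s else paste0(s, orfSeqs[[i]])
        cnt[i] <- sum(vapply(atg, function(a) .hasInframeStop(scan, a),
                             logical(1)))
        dist[i] <- if (length(atg)) len - atg[1] else len + 1
    }
    m <- cbind(UTR5.init.n_uorfs = cnt, UTR5.init.first_atg_dist = dist)
    rownames(m) <- names(seqs)
    m
}

#' Shifted and in-frame alternative ORFs inside the main ORF
#'
#' Scans ATGs at offsets > 0 from the main START; the reading frame is the
#' offset mod 3 (F0 in frame, F1/F2 shifted). A shifted ORF (sORF) is an
#' alternative ATG in frame 1 or 2 followed by an in-frame stop codon within
#' the ORF. Also reports the in-frame (F0) alternative ATG count and the
#' distance (nt) of the first alternative ATG in any frame from the main
#' START (sentinel ORF length + 1 when there is none).
#' @param ts TranscriptSet (or named character vector of ORFs)
#' @return matrix with columns ORF.init.n_sorfs_f1, ORF.init.n_sorfs_f2,
#'   ORF.init.n_alt_atg_f0, ORF.init.first_alt_atg_dist
#' @export
findSorfs <- function(ts) {
    seqs <- if (is(ts, "TranscriptSet"))
        setNames(as.character(orf(ts)), geneIds(ts)) else ts
    n <- length(seqs)
    f1 <- integer(n); f2 <- integer(n); f0 <- integer(n); dist <- numeric(n)
    for (i in seq_len(n)) {
        s <- seqs[[i]]
        atg <- setdiff(.atgOffsets(s), 0L)
        dist[i] <- if (length(atg)) atg[1] else nchar(s) + 1
        fr <- atg %% 3L
        f0[i] <- sum(fr == 0L)
        shifted <- atg[fr != 0L]
        hasStop <- vapply(shifted, function(a) .hasInframeStop(s, a), logical(1))
        f1[i] <- sum(hasStop & shifted %% 3L == 1L)
        f2[i] <- sum(hasStop & shifted %% 3L == 2L)
    }
    m <- cbind(ORF.init.n_sorfs_f1 = f1, ORF.init.n_sorfs_f2 = f2,
               ORF.init.n_alt_atg_f0 = f0, ORF.init.first_alt_atg_dist = dist)
    rownames(m) <- names(seqs)
    m
}

# context window characters around an ATG at 0-based offset `a` of sequence
# `s`: positions a-up .. a-1 and a+3 .. a+2+down; outside -> NA
.contextWindow <- function(s, a, up = 6L, down = 3L) {
    len <- nchar(s)
    pos <- c((a - up):(a - 1L), (a + 3L):(a + 2L + down))
    ch <- rep(NA_character_, length(pos))
    ok <- pos >= 0L & pos < len
    ch[ok] <- vapply(pos[ok] + 1L, function(p) substr(s, p, p), "")
    ch
}

# per-gene context windows: main START plus alternative ATGs per segment,
# computed on the concatenated transcript so windows may cross boundaries
.contextWindows <- function(ts, up = 6L, down = 3L) {
    u5 <- as.character(utr5(ts)); of <- as.character(orf(ts))
    u3 <- as.character(utr3(ts))
    ids <- geneIds(ts)
    out <- vector("list", length(ids)); names(out) <- ids
    for (i in seq_along(ids)) {
        tx <- paste0(u5[i], of[i], u3[i])
        n5 <- nchar(u5[i]); no <- nchar(of[i])
        main <- .contextWindow(tx, n5, up, down)
        alt <- function(offsets) lapply(offsets, .contextWindow, s = tx,
                                        up = up, down = down)
        a5 <- .atgOffsets(u5[i])                       # ATG fully inside UTR5
        ao <- setdiff(.atgOffsets(of[i]), 0L) + n5     # alternative, in ORF
        a3 <- .atgOffsets(u3[i]) + n5 + no
        out[[i]] <- list(main = main, UTR5 = alt(a5), ORF = alt(ao),
                         UTR3 = alt(a3))
    }
    out
}

.scorePssm <- function(chars, pssm) {
    # chars: character vector over the window positions; NA contributes 0
    sc <- 0
    for (p in seq_along(chars)) {
        if (!is.na(chars[p])) sc <- sc + pssm$logodds[p, chars[p]]
    }
    sc
}

#' Start-codon context scores
#'
#' Scores the main START context against a log-odds PSSM over 6 nt upstream
#' and 3 nt downstream of the ATG (positions outside the transcript
#' contribute 0), and for each segment the Best and Mean relative context
#' scores over all alternative ATGs (alternative minus main START; 0 when a
#' segment has no alternative ATG).
#' @param ts TranscriptSet
#' @param pssm a ContextPSSM from \code{\link{buildContextPssm}}
#' @param cache optional precomputed \code{.contextWindows} output
#' @return matrix of context-score features
#' @export
atgContextScores <- function(ts, pssm, cache = NULL) {
    if (is.null(cache)) cache <- .contextWindows(ts, pssm$up, pssm$down)
    n <- length(cache)
    m <- matrix(0, n, 7,
                dimnames = list(names(cache),
                    c("TRANSCRIPT.init.main_context_score",
                      "UTR5.init.best_rel_atg_cs", "UTR5.init.mean_rel_atg_cs",
                      "ORF.init.best_rel_atg_cs", "ORF.init.mean_rel_atg_cs",
                      "UTR3.init.best_rel_atg_cs", "UTR3.init.mean_rel_atg_cs")))
    for (i in seq_len(n)) {
        cw <- cache[[i]]
        main <- .scorePssm(cw$main, pssm)
        m[i, 1] <- main
        col <- 2
        for (seg in c("UTR5", "ORF", "UTR3")) {
            alts <- cw[[seg]]
            if (length(alts)) {
                sc <- vapply(alts, .scorePssm, 0, pssm = pssm) - main
                m[i, col] <- max(sc); m[i, col + 1] <- mean(sc)
            }
            col <- col + 2
        }
    }
    m
}
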