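mkTs <- function(orf, utr5 = NULL, utr3 = NULL)
    suppressMessages(TranscriptSet(orf, utr5 = utr5, utr3 = utr3))

test_that("length features follow the segment arithmetic", {
    ts <- mkTs(c(g = "ATGAAATAA"), utr5 = c(g = "ACGT"))
    m <- lengthFeatures(ts)
    expect_equal(unname(m["g", "TRANSCRIPT.length.ratio_utr5_orf"]), 4 / 9)
    expect_equal(unname(m["g", "ORF.length.codons"]), 3)
    expect_equal(unname(m["g", "UTR3.length.nt"]), 0)
    ts2 <- mkTs(c(g = "ATGAAATAA"))
    expect_equal(unname(lengthFeatures(ts2)["g", "UTR5.length.nt"]), 0)
    expect_equal(unname(lengthFeatures(ts2)["g", "TRANSCRIPT.length.ratio_utr5_orf"]), 0)
})

test_that("composition features: GC, overlapping ATG count, window truncation", {
    ts <- mkTs(c(g = "ATGAAATAA"), utr5 = c(g = "ATGATG"))
    m <- compositionFeatures(ts)
    expect_equal(unname(m["g", "UTR5.comp.gc"]), 2 / 6)
    expect_equal(unname(m["g", "UTR5.comp.n_atg"]), 2)  # step-1 scan
    # ORF shorter than the 90-nt window: first window equals the whole ORF
    expect_equal(unname(m["g", "ORF.comp30.first.gc"]),
                 unname(m["g", "ORF.comp.gc"]))
    # "ATGC" has GC 0.5 wherever it appears
    ts3 <- mkTs(c(g = "ATGAAATAA"), utr3 = c(g = "ATGC"))
    expect_equal(unname(compositionFeatures(ts3)["g", "UTR3.comp.gc"]), 0.5)
})

test_that("codon/aa/pair frequencies normalise and match the two-codon gene", {
    ts <- mkTs(c(g = "ATGAAATAA"))
    m <- codonPairFeatures(ts)
    expect_equal(unname(m["g", "ORF.codon.ATG"]), 0.5)
    expect_equal(unname(m["g", "ORF.codon.AAA"]), 0.5)
    expect_equal(unname(m["g", "ORF.codon_pair.ATG_AAA"]), 1)
    expect_equal(unname(m["g", "ORF.aa.M"]), 0.5)
    expect_equal(unname(m["g", "ORF.aa.K"]), 0.5)
    expect_equal(unname(m["g", "ORF.aa_pair.M_K"]), 1)
})

test_that("frequency families each sum to one on arbitrary valid genes", {
    ts <- mkTs(setNames(vapply(1:6, function(i) randomOrf(30 + i, i), ""),
                        paste0("g", 1:6)))
    m <- codonPairFeatures(ts)
    for (fam in c("ORF\\.codon\\.", "ORF\\.aa\\.", "ORF\\.codon_pair\\.",
                  "ORF\\.aa_pair\\.")) {
        s <- rowSums(m[, grepl(fam, colnames(m)), drop = FALSE])
        expect_equal(unname(s), rep(1, 6), tolerance = 1e-12)
    }
})

test_that("uORF detection requires an in-frame stop inside the 5'UTR", {
    u <- findUorfs(c(a = "ATGTAA", b = "ATGAAA", c = "CCCATGCCCTAACC",
                     d = "CCCCCC"))
    expect_equal(unname(u[, "UTR5.init.n_uorfs"]), c(1, 0, 1, 0))
    # distance = nt between first ATG and the main START; sentinel len+1
    expect_equal(unname(u[, "UTR5.init.first_atg_dist"]), c(6, 6, 11, 7))
    # with the stop allowed inside the ORF, b's downstream stop counts
    u2 <- findUorfs(c(b = "ATGAAA"), orfSeqs = c(b = "TAGATGTAA"),
                    stopInUtr = FALSE)
    expect_equal(unname(u2[, "UTR5.init.n_uorfs"]), 1)
})

test_that("uORF count matches a brute-force ATG/stop scan on random UTRs", {
    set.seed(31)
    stops <- c("TAA", "TAG", "TGA")
    for (k in 1:25) {
        u <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                   collapse = "")
        m <- findUorfs(setNames(u, "g"))
        cnt <- 0
        for (a in seq_len(38)) {
            if (substr(u, a, a + 2) != "ATG") next
            b <- a + 3
            found <- FALSE
            while (b + 2 <= 40) {
                if (substr(u, b, b + 2) %in% stops) { found <- TRUE; break }
                b <- b + 3
            }
            if (found) cnt <- cnt + 1
        }
        expect_equal(unname(m[1, "UTR5.init.n_uorfs"]), cnt)
    }
})

test_that("shifted ORF detection reports frames and first alternative ATG", {
    # alt ATG at offset 4 (frame 1) with in-frame TAA at offset 7
    s <- findSorfs(c(g = "ATGCATGTAACCTAA"))
    expect_equal(unname(s[1, "ORF.init.n_sorfs_f1"]), 1)
    expect_equal(unname(s[1, "ORF.init.n_sorfs_f2"]), 0)
    expect_equal(unname(s[1, "ORF.init.first_alt_atg_dist"]), 4)
    # no alternative ATG: counts zero, sentinel distance len + 1
    s2 <- findSorfs(c(g = "ATGAAATAA"))
    expect_equal(unname(s2[1, "ORF.init.n_sorfs_f1"]), 0)
    expect_equal(unname(s2[1, "ORF.init.first_alt_atg_dist"]), 10)
    # every reported start is an ATG by definition (postcondition, random ORFs)
    for (k in 1:10) {
        o <- randomOrf(25, 100 + k)
        atg <- gregexpr("(?=ATG)", o, perl = TRUE)[[1]]
        alt <- setdiff(as.integer(atg[atg > 0]) - 1L, 0L)
        sk <- findSorfs(setNames(o, "g"))
        if (length(alt))
            expect_equal(unname(sk[1, "ORF.init.first_alt_atg_dist"]), alt[1])
        expect_equal(unname(sk[1, "ORF.init.n_alt_atg_f0"]),
                     sum(alt %% 3 == 0))
    }
})

test_that("context scores: uniform PSSM is zero, singleton best equals mean", {
    ts <- tinyTx()
    uniform <- list(logodds = matrix(0, 9, 4,
                                     dimnames = list(NULL, c("A","C","G","T"))),
                    up = 6L, down = 3L)
    m <- atgContextScores(ts, uniform)
    expect_true(all(m == 0))
    # trained PSSM: a segment with exactly one alternative ATG has best == mean
    pssm <- buildContextPssm(ts, geneIds(ts)[1:20])
    ms <- atgContextScores(ts, pssm)
    one <- compositionFeatures(ts)[, "UTR5.comp.n_atg"] == 1
    if (any(one))
        expect_equal(ms[one, "UTR5.init.best_rel_atg_cs"],
                     ms[one, "UTR5.init.mean_rel_atg_cs"])
})

test_that("a single training gene gives the pseudocounted one-hot PSSM", {
    ts <- mkTs(c(g = "ATGAAATAA"), utr5 = c(g = "CCCCCCAAAAAA"))
    pssm <- buildContextPssm(ts, "g")
    # upstream position -1 observed A: frequency (1+1)/(4+1), others 1/5
    expect_equal(unname(pssm$freq[6, "A"]), 2 / 5)
    expect_equal(unname(pssm$freq[6, "C"]), 1 / 5)
    # log-odds maximal for the observed nucleotide in its column
    expect_equal(which.max(pssm$logodds[6, ]), c(A = 1))
})
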