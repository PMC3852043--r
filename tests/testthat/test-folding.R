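test_that("base-pair maximisation matches simple hand cases", {
    eng <- foldingEngine(weights = c(GC = 1, AU = 1, GU = 1))
    expect_equal(foldScore("AAAAAA", eng)$n_bp, 0)
    expect_equal(foldScore("AAAAAA", eng)$score, 0)
    # GGGAAACCC with min_loop 3 and unit weights: the full 3-pair helix
    r <- foldScore("GGGAAACCC", eng)
    expect_equal(r$n_bp, 3)
    expect_equal(r$score, -3)
    # minimum loop forbids pairing across short hairpins
    expect_equal(foldScore("GAAC", eng)$n_bp, 0)
    expect_equal(foldScore("GAAAC", eng)$n_bp, 1)
})

test_that("DP equals exhaustive enumeration on random and adversarial cases", {
    eng <- foldingEngine()  # GC=3, AU=2, GU=1, min_loop 3
    set.seed(11)
    seqs <- c("GGGGAAAACCCC", "GCGCAAAAGCGC", "GTGTAAAACACA", "ACGTACGTACGT",
              replicate(40, paste(sample(c("A", "C", "G", "T"),
                                         sample(4:12, 1), replace = TRUE),
                                  collapse = "")))
    for (s in seqs) {
        expect_equal(-foldScore(s, eng)$score, bruteForceFold(s),
                     info = s)
    }
})

test_that("windowed folding features clip, default and normalise", {
    ts <- suppressMessages(TranscriptSet(
        c(g = "ATGGGGAAAACCCCTTAA"), utr3 = c(g = "GGGGAAAACCCC")))
    eng <- foldingEngine(weights = c(GC = 1, AU = 1, GU = 1))
    w <- defaultWindows(sliding = FALSE)
    m <- windowedFoldingFeatures(ts, w, eng)
    # empty 5'UTR window emits defaults
    expect_equal(unname(m["g", "UTR5.fold.last40.score"]), 0)
    # window longer than the segment is clipped to it
    expect_equal(unname(m["g", "UTR3.fold.first40.n_bp"]), 4)
    # per-nucleotide score is score / window length
    expect_equal(unname(m["g", "UTR3.fold.first40.score_per_nt"]),
                 unname(m["g", "UTR3.fold.first40.score"]) / 12)
    # whole-ORF window equals the ORF fold
    expect_equal(unname(m["g", "ORF.fold.first90.n_bp"]),
                 foldScore("ATGGGGAAAACCCCTTAA", eng)$n_bp)
})

test_that("PARS features: window statistics and decomposition invariance", {
    orfs <- c(g = "ATGAAATAA", h = "ATGTTTTGA")
    pars <- list(g = rep(0, 9), h = rep(0.5, 9))
    ts <- suppressMessages(TranscriptSet(orfs, pars = pars))
    m <- parsFeatures(ts)
    expect_equal(unname(m["g", "ORF.pars.first90.mean"]), 0)
    expect_equal(unname(m["g", "ORF.pars.first90.mean_exp"]), 1)
    expect_equal(unname(m["h", "ORF.pars.first90.mean"]), 0.5)
    expect_equal(unname(m["h", "ORF.pars.first90.mean_exp"]), exp(0.5))
    # a gene without PARS emits the defaults at unchanged feature count
    ts2 <- suppressMessages(TranscriptSet(orfs))
    m2 <- parsFeatures(ts2)
    expect_equal(dim(m2), dim(m))
    expect_equal(unname(m2["h", "ORF.pars.first90.mean"]), 0)
    expect_equal(unname(m2["h", "ORF.pars.first90.mean_exp"]), 1)
    # mean over a window equals the length-weighted mean of its halves
    p <- rnorm(9)
    ts3 <- suppressMessages(TranscriptSet(c(g = "ATGAAATAA"),
                                          pars = list(g = p)))
    w1 <- data.frame(name = "ORF.first90", segment = "ORF",
                     anchor = "segment_start", offset = 0L, length = 90L)
    wa <- data.frame(name = "ORF.first90", segment = "ORF",
                     anchor = "segment_start", offset = 0L, length = 4L)
    wb <- data.frame(name = "ORF.first90", segment = "ORF",
                     anchor = "segment_start", offset = 4L, length = 5L)
    full <- parsFeatures(ts3, w1)[1, "ORF.pars.first90.mean"]
    ha <- parsFeatures(ts3, wa)[1, "ORF.pars.first90.mean"]
    hb <- parsFeatures(ts3, wb)[1, "ORF.pars.first90.mean"]
    expect_equal(unname(full), unname((4 * ha + 5 * hb) / 9))
})
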