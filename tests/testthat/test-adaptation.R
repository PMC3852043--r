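test_that("tAI weights follow the copy-number formula", {
    # four perfect-match anticodons, wobble switched off (penalties 1)
    tab <- data.frame(anticodon = c("TTT", "GAA", "CAT", "TAC"),
                      copies = c(5, 5, 10, 1))
    sOff <- c(A.T = 0, G.C = 0, T.A = 0, C.G = 0,
              G.T = 1, A.C = 1, A.A = 1, T.G = 1)
    w <- taiWeights(tab, sOff)
    expect_equal(unname(w[c("AAA", "TTC", "ATG", "GTA")]),
                 c(0.5, 0.5, 1, 0.1))
    # scale invariance
    tab2 <- tab; tab2$copies <- tab2$copies * 2
    expect_equal(taiWeights(tab2, sOff), w, ignore_attr = TRUE)
    # single perfect-match family normalises to 1
    w1 <- taiWeights(data.frame(anticodon = "CAT", copies = 5), sOff)
    expect_equal(unname(w1[["ATG"]]), 1)
    expect_error(taiWeights(data.frame(anticodon = "CAT", copies = 0)),
                 "zero")
})

test_that("wobble decoding contributes (1 - s) of the wobble anticodon", {
    # codon TTG (ends G): perfect CAA, wobble TAA with s = 0.68
    tab <- data.frame(anticodon = c("CAA", "TAA"), copies = c(2, 10))
    w <- taiWeights(tab)
    W_TTG <- 2 + (1 - 0.68) * 10
    W_TTA <- 10  # TTA perfect anticodon TAA
    expect_equal(unname(w[["TTG"]] / w[["TTA"]]), W_TTG / W_TTA)
})

test_that("gene index is the geometric mean over sense codons", {
    w <- setNames(rep(1, 61), txpredict:::.senseCodons())
    expect_equal(unname(geneIndex(c(g = "ATGAAATAA"), w)), 1)
    w["AAA"] <- 0.25
    expect_equal(unname(geneIndex(c(g = "ATGAAATAA"), w)), 0.5)
    # permutation invariance of codon order
    w2 <- taiWeights(syntheticTrnaCopies())
    expect_equal(unname(geneIndex(c(g = "ATGAAACCCTGGTAA"), w2)),
                 unname(geneIndex(c(g = "ATGTGGCCCAAATAA"), w2)))
})

test_that("CAI weights are counts over the dominant synonym", {
    # AAA:3, AAG:1 within lysine
    ref <- "ATGAAAAAAAAAAAGTAA"
    w <- caiWeights(ref)
    expect_equal(unname(w[["AAG"]]), 1 / 3)
    expect_equal(unname(w[["AAA"]]), 1)
    expect_equal(unname(w[["ATG"]]), 1)
    # unused codons get the 0.5 pseudocount ratio
    expect_equal(unname(w[["TTT"]]), 0.5 / 0.5)  # whole family unused -> 1
    expect_equal(unname(w[["GGG"]]), 1)
})

test_that("scheme-A reference selection is deterministic and ranked by tAI", {
    ts <- tinyTx()
    w <- taiWeights(syntheticTrnaCopies())
    all50 <- schemeAReference(ts, w, topFraction = 1)
    expect_setequal(all50, geneIds(ts))
    top5 <- schemeAReference(ts, w, topFraction = 0.1, minGenes = 1)
    idx <- sort(geneIndex(orf(ts), w), decreasing = TRUE)
    expect_equal(length(top5), 5)
    expect_setequal(top5, names(idx)[1:5])
    expect_identical(top5, schemeAReference(ts, w, 0.1, minGenes = 1))
    expect_error(schemeAReference(ts, w, 0.1), "fewer than 10")
})

test_that("scheme A refuses expression input at the interface", {
    ts <- tinyTx()
    expr <- data.frame(gene_id = geneIds(ts), mrna = 1, pa = 1, rd = 1)
    expect_error(extractFeatures(ts, scheme = "A", expression = expr),
                 "expression-free")
})

test_that("scheme-B coordinate ascent improves or matches the start", {
    ts <- tinyTx()
    copies <- syntheticTrnaCopies()
    w0 <- taiWeights(copies)
    # truth: different wobble penalties than the scheme-A defaults
    sTrue <- c(A.T = 0, G.C = 0, T.A = 0, C.G = 0,
               G.T = 0.9, A.C = 0.05, A.A = 0.3, T.G = 0.1)
    wTrue <- taiWeights(copies, sTrue)
    mrna <- geneIndex(orf(ts), wTrue)
    wB <- schemeBOptimize(w0, orf(ts), mrna, copies)
    obj0 <- cor(geneIndex(orf(ts), w0), log(mrna), method = "spearman")
    expect_gte(attr(wB, "objective"), obj0)
    # zero sweeps returns the starting weights unchanged
    wZ <- schemeBOptimize(w0, orf(ts), mrna, copies, maxSweeps = 0)
    expect_equal(as.numeric(wZ), as.numeric(w0))
    expect_identical(attr(wB, "provenance"), "train_optimized")
})
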