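test_that("generated transcriptomes validate strictly and are seed-stable", {
    cfg <- tinyProfile(seed = 3)
    ts <- generateTranscriptome(cfg)
    expect_equal(length(ts), 50)
    expect_equal(nrow(attr(ts, "rejected")), 0)   # strict validation passes
    w <- Biostrings::width(orf(ts))
    expect_true(all(w %% 3 == 0) && all(w >= 15))
    expect_true(all(substr(as.character(orf(ts)), 1, 3) == "ATG"))
    ts2 <- generateTranscriptome(cfg)
    expect_identical(as.character(orf(ts)), as.character(orf(ts2)))
    expect_identical(as.character(utr5(ts)), as.character(utr5(ts2)))
})

test_that("uORF injection is controlled: rate zero means no uORFs at all", {
    cfg <- tinyProfile(seed = 9)
    cfg$uorfRate <- 0
    ts <- generateTranscriptome(cfg)
    u <- findUorfs(ts)
    expect_true(all(u[, "UTR5.init.n_uorfs"] == 0))
})

test_that("sampled ORF lengths match the configured mean at large n", {
    cfg <- synthConfig(nGenes = 2000, seed = 21)
    ts <- generateTranscriptome(cfg)
    mo <- mean(Biostrings::width(orf(ts)))
    expect_lt(abs(mo - 1490.8) / 1490.8, 0.05)
    m5 <- mean(Biostrings::width(utr5(ts)))
    expect_lt(abs(m5 - 82.33) / 82.33, 0.1)
})

test_that("planted expression hits the target R-squared and derives PPR/RL", {
    std <- standardRun()
    expr <- std$expr
    lat <- attr(expr, "latent")
    r2 <- cor(lat, log(expr$pa))^2
    expect_gt(r2, 0.44); expect_lt(r2, 0.56)
    expect_equal(expr$ppr, expr$pa / expr$mrna)
    expect_equal(expr$rl, expr$rd * expr$mrna)
    # noiseless generation is a perfect copy of the latent signal
    cfg0 <- tinyProfile(seed = 2); cfg0$plantedR2 <- 0.999999
    ts0 <- generateTranscriptome(cfg0)
    fs0 <- extractFeatures(ts0)
    e0 <- generateExpression(ts0, fs0, cfg0)
    expect_gt(cor(attr(e0, "latent"), log(e0$pa)), 0.999)
})

test_that("a planted constant feature is rejected as uninformative", {
    cfg <- tinyProfile(seed = 4)
    cfg$planted <- c(UTR5.init.n_uorfs = 1)
    cfg$uorfRate <- 0                     # forces the column constant
    ts <- generateTranscriptome(cfg)
    fs <- extractFeatures(ts)
    expect_error(generateExpression(ts, fs, cfg), "constant")
    cfg$planted <- c(not.a.feature = 1)
    expect_error(generateExpression(ts, fs, cfg), "not in catalogue")
})

test_that("the generator spans the catalogue: few constant columns at n=500", {
    cfg <- synthConfig(nGenes = 500, seed = 8)
    ts <- generateTranscriptome(cfg)
    fs <- extractFeatures(ts)
    sds <- apply(featureMatrix(fs), 2, sd)
    expect_gte(mean(sds > 0), 0.95)
})
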