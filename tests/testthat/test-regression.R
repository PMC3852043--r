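test_that("tercile splits partition the gene universe with balanced sizes", {
    ids9 <- paste0("g", 1:9)
    sp <- makeSplits(ids9, 5, seed = 1)
    for (s in sp) {
        expect_equal(lengths(s[c("train", "test", "validation")]),
                     c(train = 3L, test = 3L, validation = 3L))
        expect_setequal(c(s$train, s$test, s$validation), ids9)
    }
    sp10 <- makeSplits(paste0("g", 1:10), 3, seed = 2)
    expect_equal(lengths(sp10[[1]][c("train", "test", "validation")]),
                 c(train = 4L, test = 3L, validation = 3L))
    expect_error(makeSplits(paste0("g", 1:8)), "at least 9")
    # reproducible per (seed, replicate); replicates differ from each other
    expect_identical(makeSplits(ids9, 3, seed = 7)[[2]],
                     makeSplits(ids9, 3, seed = 7)[[2]])
    expect_false(identical(sp[[1]]$train, sp[[2]]$train))
})

test_that("OLS recovers exact coefficients and tolerates duplicate columns", {
    x <- seq(-1, 1, length.out = 50)
    m <- fitLinearModel(cbind(x = x), 2 * x + 1)
    expect_equal(unname(m$coef[["x"]]), 2)
    expect_equal(m$intercept, 1)
    m0 <- fitLinearModel(cbind(x = x), rep(3, 50))
    expect_equal(unname(m0$coef[["x"]]), 0)
    X2 <- cbind(a = x, b = x)
    expect_warning(m2 <- fitLinearModel(X2, 2 * x + 1), "rank-deficient")
    expect_equal(as.numeric(X2 %*% m2$coef + m2$intercept), 2 * x + 1)
    expect_error(fitLinearModel(cbind(x = c(1, NA)), c(1, 2)), "non-finite")
})

test_that("MARS finds a single hinge near the true knot", {
    set.seed(2)
    x <- seq(0, 1, length.out = 200)
    y <- pmax(0, x - 0.5)
    m <- fitMars(cbind(x = x), y, maxTerms = 9, nKnots = 25)
    knots <- unique(unlist(lapply(m$terms, function(t) t$knot)))
    expect_true(any(abs(knots - 0.5) < 0.05))
    pred <- predictModel(list(features = "x", fit = m, center = c(x = 0),
                              scale = c(x = 1)), cbind(x = x))
    expect_gt(cor(pred, y), 0.999)
    # constant response prunes to the intercept-only model
    mc <- fitMars(cbind(x = x), rep(2, 200))
    expect_equal(length(mc$terms), 0)
    expect_error(fitMars(cbind(x = x), y, maxTerms = 0), "maxTerms")
})

test_that("MARS does no harm on linear truth (median over replicates)", {
    # simulated at tercile scale (train ~150 genes), the pipeline's regime
    set.seed(5)
    gaps <- vapply(1:20, function(k) {
        n <- 300
        X <- matrix(rnorm(3 * n), n, 3, dimnames = list(NULL, c("a", "b", "c")))
        y <- X %*% c(1, -0.5, 0.3) + rnorm(n, 0, 0.5)
        tr <- 1:150; va <- 151:300
        lin <- fitLinearModel(X[tr, ], y[tr])
        mars <- fitMars(X[tr, ], y[tr])
        pl <- X[va, ] %*% lin$coef + lin$intercept
        pm <- txpredict:::.marsBasis(X[va, ], mars$terms) %*% mars$coef
        cor(pm, y[va]) - cor(pl, y[va])
    }, 0)
    expect_gte(median(gaps), -0.02)
})

test_that("greedy selection picks an exact predictor first", {
    set.seed(3)
    n <- 60
    X <- matrix(rnorm(5 * n), n, 5,
                dimnames = list(paste0("g", 1:n), paste0("f", 1:5)))
    y <- setNames(X[, "f3"], rownames(X))
    sp <- makeSplits(rownames(X), 1, seed = 1)[[1]]
    p <- greedySelect(X, y, sp, "linear")
    expect_equal(selectedFeatures(p)[1], "f3")
    expect_equal(unname(p@correlations[["train"]]), 1, tolerance = 1e-8)
})

test_that("greedy first two selections match the exhaustive pair oracle", {
    set.seed(17)
    agree <- 0
    for (k in 1:10) {
        n <- 45
        X <- matrix(rnorm(6 * n), n, 6,
                    dimnames = list(paste0("g", 1:n), paste0("f", 1:6)))
        y <- setNames(X %*% rnorm(6) + rnorm(n), rownames(X))
        sp <- makeSplits(rownames(X), 1, seed = k)[[1]]
        p <- greedySelect(X, y, sp, "linear",
                          familyControl(maxFeatures = 2, eps = -Inf))
        oracle <- bruteForcePair(X, y, sp$train)
        if (identical(selectedFeatures(p)[1:2], oracle)) agree <- agree + 1
    }
    expect_equal(agree, 10)
})

test_that("correlation scoring handles degenerate inputs", {
    expect_equal(scoreCorrelation(1:10, 1:10), 1)
    expect_equal(scoreCorrelation(1:10, -(1:10)), -1)
    expect_warning(s <- scoreCorrelation(rep(1, 10), rnorm(10)), "constant")
    expect_true(is.na(s))
    expect_warning(s2 <- scoreCorrelation(c(1, 2, NA, NA), c(1, NA, 2, 3)),
                   "pairs")
    expect_true(is.na(s2))
})

test_that("families are reproducible and bound prevalence by size", {
    std <- standardRun()
    sub <- std$expr[1:120, ]
    fsub <- std$fs
    f1 <- buildFamily(fsub, sub, target = "mrna", nReplicates = 6, seed = 11,
                      control = familyControl(maxFeatures = 5))
    f2 <- buildFamily(fsub, sub, target = "mrna", nReplicates = 6, seed = 11,
                      control = familyControl(maxFeatures = 5))
    expect_identical(f1, f2)
    expect_true(all(prevalence(f1) <= 6))
    expect_true(all(prevalence(f1) >= 1))
    med <- medianPredictor(f1)
    expect_true(med@replicate %in% 1:6)
    expect_lte(length(selectedFeatures(med)), 5)
})

test_that("validation genes never reach scheme-B parameter inference", {
    std <- standardRun()
    expr <- std$expr[1:120, ]
    # spy on the mRNA values the optimizer receives
    seen <- new.env(); seen$ids <- character(0)
    sp <- makeSplits(expr$gene_id, 1, seed = 3)[[1]]
    fsB <- txpredict:::.schemeBReplicate(std$fs, expr, sp$train,
                                         familyControl(schemeBMaxSweeps = 1))
    # recomputed tunable columns exist for all genes, but parameters were
    # inferred from the train tercile only (signature takes train ids only)
    expect_s4_class(fsB, "FeatureSet")
    expect_identical(scheme(fsB), "B")
    expect_false(any(c(sp$test, sp$validation) %in% sp$train))
    # scheme-B family runs end to end on a small problem
    fam <- buildFamily(std$fs, expr, target = "mrna", scheme = "B",
                       nReplicates = 2, seed = 4,
                       control = familyControl(maxFeatures = 3,
                                               schemeBOptimizeCai = FALSE,
                                               schemeBMaxSweeps = 2))
    expect_equal(length(predictors(fam)), 2)
})
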