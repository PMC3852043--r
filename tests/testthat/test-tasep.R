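test_that("single-site chain reproduces the closed-form current", {
    e <- exactTasepSmall(rates = 1, alpha = 1, beta = 1)
    expect_equal(e$current, 0.5)   # alpha beta / (alpha + beta)
    expect_equal(e$density, 0.5)
    e2 <- exactTasepSmall(rates = 1, alpha = 0.3, beta = 0.9)
    expect_equal(e2$current, 0.3 * 0.9 / (0.3 + 0.9))
    s <- simulateTasep(1, tasepConfig(alpha = 1, beta = 1, ell = 1,
                                      burnin = 5e3, sample = 1e5), seed = 2)
    expect_lt(abs(s$current - 0.5), 3 * s$se)
})

test_that("two-site exact solve satisfies balance and symmetry", {
    e <- exactTasepSmall(rates = c(1, 1), alpha = 1, beta = 1)
    # 4-state chain solved by hand from the balance equations: J = 2/5
    expect_equal(e$current, 2 / 5, tolerance = 1e-10)
    # particle-hole symmetry at alpha = beta: rho_i + rho_{n+1-i} = 1
    e5 <- exactTasepSmall(rates = rep(1, 5), alpha = 0.6, beta = 0.6)
    expect_equal(e5$density + rev(e5$density), rep(1, 5), tolerance = 1e-10)
    expect_error(exactTasepSmall(rates = rep(1, 11), 1, 1), "n <= 10")
})

test_that("time rescaling scales the current linearly", {
    e1 <- exactTasepSmall(rates = c(2, 0.5, 1), alpha = 0.4, beta = 1.5)
    ek <- exactTasepSmall(rates = 3 * c(2, 0.5, 1), alpha = 1.2, beta = 4.5)
    expect_equal(ek$current, 3 * e1$current, tolerance = 1e-10)
})

test_that("a near-blocked site throttles the current to zero", {
    s <- simulateTasep(c(1, 1e-9, 1),
                       tasepConfig(alpha = 1, beta = 1, ell = 1,
                                   burnin = 1e3, sample = 1e4), seed = 4) |>
        suppressWarnings()
    expect_lt(s$current, 1e-3)
})

test_that("steric hindrance is monotone: J(ell=2) <= J(ell=1)", {
    c1 <- tasepConfig(alpha = 1, beta = 1, ell = 1, burnin = 2e4, sample = 2e5)
    c2 <- tasepConfig(alpha = 1, beta = 1, ell = 2, burnin = 2e4, sample = 2e5)
    s1 <- simulateTasep(rep(1, 10), c1, seed = 9)
    s2 <- simulateTasep(rep(1, 10), c2, seed = 9)
    expect_lt(s2$current, s1$current)
})

test_that("per-bond current is conserved across the lattice", {
    cfg <- tasepConfig(alpha = 0.8, beta = 1.2, ell = 1,
                       burnin = 5e4, sample = 5e5)
    s <- simulateTasep(rep(1, 4), cfg, seed = 12)
    e <- exactTasepSmall(rep(1, 4), 0.8, 1.2)
    # exact bond currents: alpha (1-rho_1) entering vs beta rho_n leaving
    expect_equal(0.8 * (1 - e$density[1]), 1.2 * e$density[4],
                 tolerance = 1e-10)
    expect_lt(abs(s$current - e$current), 3 * s$se)
})

test_that("the TASEP gene feature is order-sensitive and seed-stable", {
    w <- taiWeights(syntheticTrnaCopies())
    slow <- names(sort(w))[1]; fast <- names(sort(w, decreasing = TRUE))[1]
    mk <- function(cods) paste0("ATG", paste(cods, collapse = ""), "TAA")
    # codon-permuted pair: two slow codons clustered vs spread apart
    cl <- rep(fast, 40); cl[c(20, 21)] <- slow
    sp <- rep(fast, 40); sp[c(10, 30)] <- slow
    orfs <- Biostrings::DNAStringSet(c(a = mk(cl), b = mk(sp)))
    cfg <- tasepConfig(alpha = 10, beta = 10, ell = 3,
                       burnin = 5e4, sample = 5e5)
    j1 <- tasepFeature(orfs, w, cfg, seed = 5)
    j2 <- tasepFeature(orfs, w, cfg, seed = 5)
    expect_identical(j1, j2)                  # reproducible per seed
    # codon order changes the current beyond the Monte-Carlo error bars
    toRates <- function(v) { r <- w[v] / mean(w[v]); as.numeric(r) }
    sa <- simulateTasep(toRates(c("ATG", cl)), cfg, seed = 101)
    sb <- simulateTasep(toRates(c("ATG", sp)), cfg, seed = 102)
    expect_gt(abs(j1[["a"]] - j1[["b"]]), 3 * (sa$se + sb$se))
    # uniform rates: the current ignores codon identities entirely
    wu <- setNames(rep(0.5, 61), names(w))
    ja <- tasepFeature(Biostrings::DNAStringSet(c(x = mk(cl))), wu, cfg, seed = 5)
    jb <- tasepFeature(Biostrings::DNAStringSet(c(x = mk(sp))), wu, cfg, seed = 5)
    expect_identical(ja, jb)
})
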