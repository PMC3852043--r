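#' TASEP configuration
#'
#' @param alpha initiation rate (default 0.1: initiation-limited regime)
#' @param beta termination rate (default 10)
#' @param ell ribosome footprint in codon sites (default 9)
#' @param burnin,sample event horizons for equilibration and sampling
#' @param nBatches batches for the batch-means standard error
#' @return config list
#' @export
tasepConfig <- function(alpha = 0.1, beta = 10, ell = 9L,
                        burnin = 1e5, sample = 1e6, nBatches = 20L) {
    stopifnot(alpha > 0, beta > 0, ell >= 1)
    list(alpha = alpha, beta = beta, ell = as.integer(ell),
         burnin = burnin, sample = sample, nBatches = as.integer(nBatches))
}

#' Fast TASEP profile for feature extraction
#' @export
#' @rdname tasepConfig
tasepFastConfig <- function(alpha = 0.1, beta = 10, ell = 9L)
    tasepConfig(alpha, beta, ell, burnin = 2000, sample = 10000, nBatches = 10L)

#' Simulate a footprint-aware TASEP
#'
#' Continuous-time Markov simulation (Gillespie scheduling, exponential
#' waiting times). A ribosome occupies \code{ell} consecutive codon sites;
#' initiation requires sites 1..ell free, the hop i -> i+1 requires site
#' i+ell free, and the ribosome on the last site exits at rate beta. The
#' steady-state current J is estimated from terminations after burn-in, with
#' a batch-means Monte-Carlo standard error.
#'
#' @param rates per-site hop rates (length = number of sites)
#' @param config see \code{\link{tasepConfig}}
#' @param seed integer seed (self-contained RNG; does not touch R's stream)
#' @param trackDensity accumulate the per-site occupancy profile
#' @return list(current, se, density, n_term, time, low_confidence)
#' @export
simulateTasep <- function(rates, config = tasepConfig(), seed = 1L,
                          trackDensity = TRUE) {
    stopifnot(all(rates > 0))
    r <- .tasep_sim_cpp(as.numeric(rates), config$alpha, config$beta,
                        config$ell, config$burnin, config$sample,
                        as.double(seed), config$nBatches, trackDensity)
    low <- r$n_term < 100
    if (low) warning("fewer than 100 termination events; ",
                     "current estimate is low-confidence")
    list(current = r$current, se = r$se, density = r$density,
         n_term = r$n_term, time = r$time, low_confidence = low)
}

#' Exact stationary solution of a small TASEP (footprint 1)
#'
#' Builds the full 2^n-state generator of the open TASEP with site-wise hop
#' rates, solves for the stationary distribution, and returns the exact
#' current and density profile. Used as the in-repo oracle for the
#' Monte-Carlo simulator.
#' @param rates per-site hop rates, length n <= 10
#' @param alpha,beta entry and exit rates
#' @return list(current, density)
#' @export
exactTasepSmall <- function(rates, alpha, beta) {
    n <- length(rates)
    if (n > 10) stop("exact solver limited to n <= 10 sites")
    ns <- 2L^n
    occ <- matrix(0L, ns, n)
    for (i in seq_len(n)) occ[, i] <- bitwAnd(seq_len(ns) - 1L, 2L^(i - 1L)) > 0
    Q <- matrix(0, ns, ns)
    for (s in seq_len(ns)) {
        o <- occ[s, ]
        if (!o[1]) {
            t <- s + 1L  # set bit 1
            Q[s, t] <- Q[s, t] + alpha
        }
        if (n > 1) for (i in seq_len(n - 1L)) {
            if (o[i] && !o[i + 1]) {
                t <- s - 2L^(i - 1L) + 2L^i
                Q[s, t] <- Q[s, t] + rates[i]
            }
        }
        if (o[n]) {
            t <- s - 2L^(n - 1L)
            Q[s, t] <- Q[s, t] + beta
        }
    }
    diag(Q) <- -rowSums(Q)
    A <- rbind(t(Q), rep(1, ns))
    b <- c(rep(0, ns), 1)
    pi <- qr.solve(A, b)
    pi[pi < 0] <- 0
    pi <- pi / sum(pi)
    list(current = beta * sum(pi * occ[, n]),
         density = as.numeric(t(occ) %*% pi))
}

#' TASEP translation-rate feature
#'
#' One value per gene: the estimated steady-state current with per-codon hop
#' rates proportional to the codon weights along the ORF (terminal stop
#' excluded), rescaled to mean rate 1. Seeding is per gene
#' (hash(gene id) combined with the global seed) so gene order does not
#' affect results.
#' @param ts TranscriptSet (or DNAStringSet of ORFs)
#' @param weights sense-codon weights (tAI scheme A, or scheme-B optimized)
#' @param config see \code{\link{tasepFastConfig}}
#' @param seed global seed
#' @return named numeric vector of currents
#' @export
tasepFeature <- function(ts, weights, config = tasepFastConfig(), seed = 1L) {
    orfs <- if (is(ts, "TranscriptSet")) orf(ts) else ts
    ids <- names(orfs)
    seqs <- as.character(orfs)
    out <- numeric(length(seqs))
    for (g in seq_along(seqs)) {
        s <- seqs[g]
        ncod <- nchar(s) %/% 3
        cods <- substring(s, 3 * seq_len(ncod) - 2, 3 * seq_len(ncod))
        if (cods[ncod] %in% STOP_CODONS) cods <- cods[-ncod]
        w <- weights[cods]
        w[is.na(w)] <- exp(mean(log(weights)))  # internal stop / unknown codon
        r <- as.numeric(w) / mean(w)
        gSeed <- bitwXor(.hashString(ids[g]), as.integer(seed)) %% 2147483647
        sim <- .tasep_sim_cpp(r, config$alpha, config$beta, config$ell,
                              config$burnin, config$sample, as.double(gSeed),
                              config$nBatches, FALSE)
        out[g] <- sim$current
    }
    names(out) <- ids
    out
}
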