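#' Synthetic transcriptome configuration
#'
#' Segment lengths are log-normal with configurable means (defaults: mean
#' 5'UTR 82.33 nt, ORF 1490.8 nt, 3'UTR 133.62 nt, matching a typical yeast
#' transcriptome). ORF codons are drawn from a tAI-weight-biased codon
#' distribution whose per-gene bias temperature varies, creating a tAI/CAI
#' spread; 5'UTRs are scrubbed of spontaneous ATGs and uORFs are injected at
#' a controlled per-gene rate. Expression is generated on the log scale as a
#' planted sparse linear function of true (z-scored) features plus Gaussian
#' noise calibrated to a target R-squared.
#'
#' @param nGenes number of genes
#' @param meanLengths named mean segment lengths (nt)
#' @param sdlog log-normal sdlog per segment
#' @param gcRange per-gene UTR GC-content range (drawn independently for the
#'   5'UTR and the 3'UTR, so segment GC features are not duplicates)
#' @param codonBiasMax maximal per-gene codon bias temperature
#' @param uorfRate expected number of injected uORFs per gene (0, 1 or 2 are
#'   injected); independently, decoy ATGs too close to the ORF to form a
#'   uORF are injected at rate \code{decoyAtgRate} so that the UTR ATG count
#'   and the uORF count remain distinguishable
#' @param decoyAtgRate rate of non-uORF-forming ATGs in the 5'UTR
#' @param utr3AtgRate per-slot rate of injected 3'UTR ATGs (0-3 per gene;
#'   spontaneous ATGs are scrubbed first so the count is a controlled,
#'   length-independent property)
#' @param pars also emit synthetic PARS profiles
#' @param planted named coefficients over catalogue feature names
#' @param plantedR2 planted signal R-squared on the log scale
#' @param targetScales per-target multiplier on the shared latent signal
#' @param seed generator seed
#' @return config list
#' @export
synthConfig <- function(nGenes = 1000L,
                        meanLengths = c(utr5 = 82.33, orf = 1490.8,
                                        utr3 = 133.62),
                        sdlog = c(utr5 = 0.7, orf = 0.65, utr3 = 0.6),
                        gcRange = c(0.3, 0.5), codonBiasMax = 3,
                        uorfRate = 0.3, decoyAtgRate = 0.25,
                        utr3AtgRate = 0.4, pars = FALSE,
                        planted = c(UTR5.length.nt = -0.6,
                                    UTR3.length.nt = 0.6,
                                    UTR5.init.n_uorfs = -0.5,
                                    ORF.fold.w001_40.score = -0.6,
                                    UTR3.comp.n_atg = 0.55),
                        plantedR2 = 0.5,
                        targetScales = c(mrna = 1, pa = 0.8, rd = 0.6),
                        seed = 1L) {
    list(nGenes = as.integer(nGenes), meanLengths = meanLengths,
         sdlog = sdlog, gcRange = gcRange, codonBiasMax = codonBiasMax,
         uorfRate = uorfRate, decoyAtgRate = decoyAtgRate,
         utr3AtgRate = utr3AtgRate, pars = pars,
         planted = planted, plantedR2 = plantedR2,
         targetScales = targetScales, seed = as.integer(seed))
}

#' Fixture profiles
#'
#' "tiny": 50 genes (unit tests); "standard": 1000 genes (recovery tests).
#' @param seed generator seed
#' @return a \code{\link{synthConfig}}
#' @export
tinyProfile <- function(seed = 1L) synthConfig(nGenes = 50L, seed = seed)

#' @rdname tinyProfile
#' @export
standardProfile <- function(seed = 1L) synthConfig(nGenes = 1000L, seed = seed)

.sampleSeg <- function(n, meanLen, sdlog) {
    meanlog <- log(meanLen) - sdlog^2 / 2
    round(rlnorm(n, meanlog, sdlog))
}

.randomNt <- function(len, gc) {
    if (len == 0) return("")
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
          collapse = "")
}

# remove every (overlapping) ATG from a UTR by mutating its G
.scrubAtg <- function(s) {
    repeat {
        i <- regexpr("ATG", s, fixed = TRUE)
        if (i == -1) return(s)
        substr(s, i + 2, i + 2) <- "C"
    }
}

#' Generate a synthetic transcriptome
#'
#' @param cfg a \code{\link{synthConfig}}
#' @return a \code{TranscriptSet} (validates in strict mode by construction)
#' @export
generateTranscriptome <- function(cfg = synthConfig()) {
    .withSeed(cfg$seed, {
        n <- cfg$nGenes
        ids <- sprintf("G%05d", seq_len(n))
        l5 <- .sampleSeg(n, cfg$meanLengths[["utr5"]], cfg$sdlog[["utr5"]])
        l3 <- .sampleSeg(n, cfg$meanLengths[["utr3"]], cfg$sdlog[["utr3"]])
        ncod <- pmax(5L, round(.sampleSeg(n, cfg$meanLengths[["orf"]],
                                          cfg$sdlog[["orf"]]) / 3))
        w <- taiWeights(syntheticTrnaCopies())
        sense <- names(w)
        bias <- runif(n, 0, cfg$codonBiasMax)
        gc5 <- runif(n, cfg$gcRange[1], cfg$gcRange[2])
        gc3 <- runif(n, cfg$gcRange[1], cfg$gcRange[2])
        # per-gene GC preference of the ORF, independent of the codon-bias
        # temperature, so adaptation and composition vary on separate axes
        gcPref <- runif(n, -0.8, 0.8)
        ngc <- vapply(strsplit(names(w), ""),
                      function(ch) sum(ch %in% c("G", "C")), 0)
        utr5 <- character(n); utr3 <- character(n); orfs <- character(n)
        for (i in seq_len(n)) {
            p <- w^bias[i] * exp(gcPref[i] * ngc); p <- p / sum(p)
            body <- sample(sense, ncod[i] - 2L, replace = TRUE, prob = p)
            orfs[i] <- paste0("ATG", paste(body, collapse = ""),
                              sample(STOP_CODONS, 1))
            u5 <- .scrubAtg(.randomNt(l5[i], gc5[i]))
            nU <- stats::rbinom(1, 2, cfg$uorfRate / 2)
            len <- nchar(u5)
            if (nU > 0 && len >= 9 + 6) {
                # disjoint uORFs (ATG + immediate in-frame stop), kept clear
                # of the last 6 nt so the decoy slot stays free
                slots <- seq(1L, len - 6L - 5L, by = 6L)
                for (pos in sort(slots[sample.int(length(slots),
                                                  min(nU, length(slots)))])) {
                    substr(u5, pos, pos + 2) <- "ATG"
                    substr(u5, pos + 3, pos + 5) <- "TAA"
                }
            }
            if (runif(1) < cfg$decoyAtgRate && len >= 6) {
                # ATG with < 3 nt left in the UTR: never forms a uORF
                substr(u5, len - 4L, len - 2L) <- "ATG"
            }
            utr5[i] <- u5
            # 3'UTR ATG content is its own controlled dial: scrub the
            # spontaneous (length-coupled) ATGs, then inject 0-3 of them
            u3 <- .scrubAtg(.randomNt(l3[i], gc3[i]))
            nA <- stats::rbinom(1, 3, cfg$utr3AtgRate)
            len3 <- nchar(u3)
            if (nA > 0 && len3 >= 4) {
                slots <- seq(1L, len3 - 3L, by = 4L)
                for (pos in slots[sample.int(length(slots),
                                             min(nA, length(slots)))])
                    substr(u3, pos, pos + 2) <- "ATG"
            }
            utr3[i] <- u3
        }
        names(orfs) <- names(utr5) <- names(utr3) <- ids
        pars <- NULL
        if (cfg$pars) {
            eng <- foldingEngine()
            wins <- defaultWindows(sliding = FALSE)
            pars <- lapply(seq_len(n), function(i) {
                tot <- l5[i] + 3 * ncod[i] + l3[i]
                base <- rnorm(tot, 0, 0.5)
                segs <- list(UTR5 = utr5[i], ORF = orfs[i], UTR3 = utr3[i])
                starts <- c(UTR5 = 0L, ORF = l5[i], UTR3 = l5[i] + 3L * ncod[i])
                for (wi in seq_len(nrow(wins))) {
                    s <- .windowSeq(segs[[wins$segment[wi]]], wins$anchor[wi],
                                    wins$offset[wi], wins$length[wi])
                    if (nchar(s) < 2) next
                    sc <- -foldScore(s, eng)$score / nchar(s)  # structure >= 0
                    segLen <- nchar(segs[[wins$segment[wi]]])
                    from <- if (wins$anchor[wi] == "segment_start") 1L
                            else max(1L, segLen - nchar(s) + 1L)
                    idx <- starts[wins$segment[wi]] + from - 1L + seq_len(nchar(s))
                    base[idx] <- base[idx] + sc
                }
                stats::filter(base, rep(1 / 3, 3), sides = 2) ->
                    sm
                as.numeric(ifelse(is.na(sm), base, sm))
            })
            names(pars) <- ids
        }
        TranscriptSet(orfs, utr5 = utr5, utr3 = utr3, pars = pars,
                      mode = "strict")
    })
}

#' Generate expression measurements with planted signal
#'
#' The latent signal is the planted linear combination of z-scored feature
#' columns; log mRNA, log PA and log RD are (per-target scaled) copies of
#' the latent plus independent Gaussian noise calibrated so the planted
#' R-squared equals \code{cfg$plantedR2}. PPR and RL are then derived with
#' \code{\link{deriveTargets}}, never planted directly.
#' @param ts TranscriptSet from \code{\link{generateTranscriptome}}
#' @param features FeatureSet extracted from \code{ts} (scheme A)
#' @param cfg the same \code{\link{synthConfig}}
#' @return data.frame gene_id, mrna, pa, rd, ppr, rl; the latent signal is
#'   attached as \code{attr(x, "latent")}
#' @export
generateExpression <- function(ts, features, cfg = synthConfig()) {
    m <- featureMatrix(features)
    miss <- setdiff(names(cfg$planted), colnames(m))
    if (length(miss)) stop("planted feature(s) not in catalogue: ",
                           paste(miss, collapse = ", "))
    P <- m[, names(cfg$planted), drop = FALSE]
    sds <- apply(P, 2, sd)
    if (any(sds == 0)) stop("planted feature constant across genes: ",
                            paste(colnames(P)[sds == 0], collapse = ", "))
    Z <- .applyScale(P, colMeans(P), sds)
    latent <- as.numeric(Z %*% cfg$planted)
    noiseSd <- sd(latent) * sqrt((1 - cfg$plantedR2) / cfg$plantedR2)
    out <- .withSeed(.deriveSeed(cfg$seed, 777L), {
        n <- nrow(m)
        mk <- function(scale) exp(scale * latent +
                                  rnorm(n, 0, abs(scale) * noiseSd))
        data.frame(gene_id = rownames(m),
                   mrna = mk(cfg$targetScales[["mrna"]]),
                   pa = mk(cfg$targetScales[["pa"]]),
                   rd = mk(cfg$targetScales[["rd"]]),
                   stringsAsFactors = FALSE)
    })
    out <- deriveTargets(out)
    attr(out, "latent") <- latent
    out
}
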