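#' Synthetic tRNA gene copy-number table
#'
#' A deterministic, synthetic copy-number table over all anticodons cognate
#' to the 61 sense codons (it does not describe any real genome). Copy
#' numbers are assigned by a fixed hash of the anticodon, giving a stable
#' spread of abundant, rare and absent anticodons so that tAI weights span
#' their range and wobble decoding is exercised.
#' @return data.frame with columns anticodon, copies
#' @export
syntheticTrnaCopies <- function() {
    p <- .codonPairings()
    ac <- sort(unique(c(p$perfect, p$wobble)))
    copies <- vapply(ac, function(a) .hashString(a) %% 13L, integer(1))
    data.frame(anticodon = ac, copies = as.integer(copies),
               stringsAsFactors = FALSE)
}

#' Feature extraction configuration
#'
#' @param window30 width (nt) of the 30-codon composition windows
#' @param foldEngine a \code{\link{foldingEngine}}
#' @param foldWindows,parsWindows window specs (see
#'   \code{\link{defaultWindows}})
#' @param tasep TASEP profile for the translation-rate feature
#' @param topFraction scheme-A reference fraction (tAI-ranked)
#' @param taiS wobble penalties for the scheme-A tAI
#' @param contextUp,contextDown START-context window extent
#' @param includeTasep compute the (Monte-Carlo) TASEP feature
#' @param tasepSeed global seed combined with the per-gene hash
#' @param stopInUtr uORF stops must lie inside the 5'UTR
#' @return config list
#' @export
featureConfig <- function(window30 = 90L, foldEngine = foldingEngine(),
                          foldWindows = defaultWindows(TRUE),
                          parsWindows = defaultWindows(FALSE),
                          tasep = tasepFastConfig(), topFraction = 0.1,
                          taiS = taiDefaultS(), contextUp = 6L,
                          contextDown = 3L, includeTasep = TRUE,
                          tasepSeed = 1L, stopInUtr = TRUE) {
    list(window30 = window30, foldEngine = foldEngine,
         foldWindows = foldWindows, parsWindows = parsWindows,
         tasep = tasep, topFraction = topFraction, taiS = taiS,
         contextUp = contextUp, contextDown = contextDown,
         includeTasep = includeTasep, tasepSeed = tasepSeed,
         stopInUtr = stopInUtr)
}

.famFromName <- function(nm) {
    fam <- vapply(strsplit(nm, ".", fixed = TRUE), `[`, "", 2)
    map <- c(length = "length", comp = "composition", comp30 = "composition",
             codon = "codon", aa = "aa", codon_pair = "codon_pair",
             aa_pair = "aa_pair", init = "init", adaptation = "adaptation",
             fold = "folding", pars = "pars", tasep = "tasep")
    unname(map[fam])
}

#' The feature catalogue
#'
#' One row per feature: stable name "<scope>.<family>.<detail>", segment
#' scope, family, default value for degenerate inputs (NA marks the
#' gene-dependent "segment length + 1" sentinel of the distance features),
#' and whether the feature is retuned from expression data under scheme B.
#' The catalogue size is a derived property of the configured families, not
#' a constant.
#' @param config see \code{\link{featureConfig}}
#' @return data.frame (name, scope, family, default, tunable)
#' @export
featureCatalogue <- function(config = featureConfig()) {
    sense <- .senseCodons(); aas <- .aaLetters()
    compCols <- function(prefix, atg = TRUE)
        paste(prefix, c("gc", "freq_A", "freq_C", "freq_G", "freq_T",
                        if (atg) "n_atg"), sep = ".")
    foldCols <- as.vector(t(outer(config$foldWindows$name,
        c("score", "n_bp", "score_per_nt"),
        function(a, b) sprintf("%s.fold.%s", sub("\\..*$", "", a),
                               paste(sub("^[^.]*\\.", "", a), b, sep = ".")))))
    parsCols <- as.vector(t(outer(config$parsWindows$name,
        c("mean", "max", "mean_exp"),
        function(a, b) sprintf("%s.pars.%s", sub("\\..*$", "", a),
                               paste(sub("^[^.]*\\.", "", a), b, sep = ".")))))
    nm <- c(
        c("UTR5.length.nt", "ORF.length.nt", "ORF.length.codons",
          "UTR3.length.nt", "TRANSCRIPT.length.nt",
          "TRANSCRIPT.length.ratio_utr5_orf",
          "TRANSCRIPT.length.ratio_utr3_orf",
          "TRANSCRIPT.length.ratio_utrs_tx"),
        c(compCols("UTR5.comp"), compCols("ORF.comp"), compCols("UTR3.comp"),
          compCols("TRANSCRIPT.comp"),
          compCols("ORF.comp30.first", FALSE), compCols("ORF.comp30.last", FALSE),
          compCols("UTR5.comp30.last", FALSE), compCols("UTR3.comp30.first", FALSE)),
        paste0("ORF.codon.", sense),
        paste0("ORF.aa.", aas),
        paste0("ORF.codon_pair.", as.vector(outer(sense, sense, paste, sep = "_"))),
        paste0("ORF.aa_pair.", as.vector(outer(aas, aas, paste, sep = "_"))),
        c("UTR5.init.n_uorfs", "UTR5.init.first_atg_dist",
          "ORF.init.n_sorfs_f1", "ORF.init.n_sorfs_f2",
          "ORF.init.n_alt_atg_f0", "ORF.init.first_alt_atg_dist",
          "TRANSCRIPT.init.main_context_score",
          "UTR5.init.best_rel_atg_cs", "UTR5.init.mean_rel_atg_cs",
          "ORF.init.best_rel_atg_cs", "ORF.init.mean_rel_atg_cs",
          "UTR3.init.best_rel_atg_cs", "UTR3.init.mean_rel_atg_cs"),
        c("ORF.adaptation.tai", "ORF.adaptation.cai",
          "ORF.adaptation.tai_first30", "ORF.adaptation.tai_last30",
          "ORF.adaptation.cai_first30", "ORF.adaptation.cai_last30"),
        foldCols,
        parsCols,
        if (config$includeTasep) "ORF.tasep.current")
    default <- rep(0, length(nm))
    default[grepl("_dist$", nm)] <- NA  # gene-dependent sentinel: seglen + 1
    default[grepl("pars.*mean_exp$", nm)] <- 1
    tunable <- grepl("\\.adaptation\\.", nm) | grepl("context_score$", nm) |
               grepl("_cs$", nm) | grepl("\\.tasep\\.", nm)
    data.frame(name = nm,
               scope = vapply(strsplit(nm, ".", fixed = TRUE), `[`, "", 1),
               family = .famFromName(nm),
               default = default, tunable = tunable,
               stringsAsFactors = FALSE)
}

# adaptation + context (+ optional tasep) columns for given weights/pssm
.tunableBlock <- function(cache, taiW, caiW, pssm, tasep = NULL) {
    m <- cbind(
        ORF.adaptation.tai = geneIndex(cache$codonCounts, taiW),
        ORF.adaptation.cai = geneIndex(cache$codonCounts, caiW),
        ORF.adaptation.tai_first30 = geneIndex(cache$codonCountsFirst30, taiW),
        ORF.adaptation.tai_last30 = geneIndex(cache$codonCountsLast30, taiW),
        ORF.adaptation.cai_first30 = geneIndex(cache$codonCountsFirst30, caiW),
        ORF.adaptation.cai_last30 = geneIndex(cache$codonCountsLast30, caiW))
    ctx <- atgContextScores(NULL, pssm, cache = cache$contextCache)
    list(adaptation = m, context = ctx, tasep = tasep)
}

#' Extract the full feature table
#'
#' Scheme A is expression-free: adaptation weights come from tRNA copy
#' numbers and a tAI-ranked reference set, and this function refuses any
#' expression input under scheme A. Scheme B retunes the adaptation weights
#' and START-context PSSM on the supplied train-set genes' mRNA levels.
#'
#' @param ts TranscriptSet
#' @param scheme "A" or "B"
#' @param trnaCopies tRNA copy-number table (default: the synthetic table)
#' @param expression ExpressionTable data.frame; scheme B only
#' @param trainIds train-tercile gene ids; scheme B only
#' @param config see \code{\link{featureConfig}}
#' @return a \code{FeatureSet} (with a cache that allows fast scheme-B
#'   recomputation of the tunable columns)
#' @export
extractFeatures <- function(ts, scheme = c("A", "B"),
                            trnaCopies = syntheticTrnaCopies(),
                            expression = NULL, trainIds = NULL,
                            config = featureConfig()) {
    scheme <- match.arg(scheme)
    if (scheme == "A" && !is.null(expression))
        stop("scheme A is expression-free: remove the expression argument")
    if (scheme == "B" && (is.null(expression) || is.null(trainIds)))
        stop("scheme B needs expression and trainIds")

    cat <- featureCatalogue(config)
    cache <- list(
        codonCounts = .codonCounts(orf(ts)),
        codonCountsFirst30 = .codonCounts(.clipSub(orf(ts), TRUE,
                                                   config$window30)),
        codonCountsLast30 = .codonCounts(.clipSub(orf(ts), FALSE,
                                                  config$window30)),
        contextCache = .contextWindows(ts, config$contextUp,
                                       config$contextDown),
        orfs = orf(ts), trnaCopies = trnaCopies, config = config)

    taiA <- taiWeights(trnaCopies, config$taiS)
    # keep the reference set at >= 10 genes even for small fixtures
    refFrac <- max(config$topFraction, min(1, 10 / length(ts)))
    if (scheme == "A") {
        ref <- schemeAReference(ts, taiA, refFrac)
        taiW <- taiA
        caiW <- caiWeights(orf(ts)[ref])
        pssm <- buildContextPssm(ts, ref, config$contextUp, config$contextDown)
    } else {
        ids <- geneIds(ts)
        stopifnot(all(trainIds %in% ids))
        mrna <- setNames(expression$mrna, expression$gene_id)[trainIds]
        trainCnt <- cache$codonCounts[trainIds, , drop = FALSE]
        taiW <- schemeBOptimize(taiA, trainCnt, mrna, trnaCopies)
        refA <- schemeAReference(ts, taiA, refFrac)
        caiW <- schemeBOptimize(caiWeights(orf(ts)[refA]), trainCnt, mrna)
        top <- trainIds[order(-mrna, trainIds)]
        top <- top[seq_len(max(10, round(config$topFraction * length(top))))]
        pssm <- buildContextPssm(ts, top, config$contextUp, config$contextDown)
    }
    cache$taiA <- taiA
    cache$pssmScheme <- scheme

    tun <- .tunableBlock(cache, taiW, caiW, pssm)
    blocks <- list(
        lengthFeatures(ts),
        compositionFeatures(ts, config$window30),
        codonPairFeatures(ts),
        findUorfs(ts, stopInUtr = config$stopInUtr),
        findSorfs(ts),
        tun$context,
        tun$adaptation,
        windowedFoldingFeatures(ts, config$foldWindows, config$foldEngine),
        parsFeatures(ts, config$parsWindows))
    if (config$includeTasep)
        blocks <- c(blocks, list(
            matrix(tasepFeature(ts, taiW, config$tasep, config$tasepSeed),
                   ncol = 1, dimnames = list(geneIds(ts),
                                             "ORF.tasep.current"))))
    m <- do.call(cbind, blocks)
    m <- m[, cat$name, drop = FALSE]  # canonical catalogue order
    new("FeatureSet", values = m, catalogue = cat, scheme = scheme,
        cache = cache)
}

#' Recompute the expression-tunable columns of a FeatureSet
#'
#' Replaces the adaptation and START-context columns (and optionally the
#' TASEP column) using new weights/PSSM, leaving everything else untouched.
#' Used inside scheme-B jackknife replicates, where the parameters are
#' re-inferred from each replicate's train tercile.
#' @param fs FeatureSet with a cache
#' @param taiW,caiW,pssm replacement parameters
#' @param retuneTasep also re-simulate the TASEP feature with taiW
#' @return FeatureSet with updated columns, scheme set to "B"
#' @export
updateTunableFeatures <- function(fs, taiW, caiW, pssm, retuneTasep = FALSE) {
    cache <- fs@cache
    stopifnot(length(cache) > 0)
    tun <- .tunableBlock(cache, taiW, caiW, pssm)
    m <- fs@values
    m[, colnames(tun$adaptation)] <- tun$adaptation
    m[, colnames(tun$context)] <- tun$context
    if (retuneTasep && "ORF.tasep.current" %in% colnames(m)) {
        cfg <- cache$config
        m[, "ORF.tasep.current"] <- tasepFeature(cache$orfs, taiW, cfg$tasep,
                                                 cfg$tasepSeed)
    }
    new("FeatureSet", values = m, catalogue = fs@catalogue, scheme = "B",
        cache = cache)
}
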