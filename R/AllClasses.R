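#' @import methods
#' @importFrom Biostrings DNAStringSet GENETIC_CODE
NULL

#' TranscriptSet: per-gene transcript segments
#'
#' Holds, for each gene, the three transcript segments (5'UTR, ORF, 3'UTR) as
#' \code{DNAStringSet}s plus an optional per-nucleotide PARS structure profile
#' over the concatenated transcript. UTRs may be empty; the ORF is non-empty,
#' a multiple of 3 nt, and (in strict mode) starts with ATG and ends with a
#' stop codon.
#'
#' @slot utr5,orf,utr3 \code{DNAStringSet}s, parallel and identically named.
#' @slot pars named \code{list}; per gene either \code{NULL} or a numeric
#'   vector with one value per nucleotide of utr5+orf+utr3.
#' @exportClass TranscriptSet
setClass("TranscriptSet",
    representation(utr5 = "DNAStringSet", orf = "DNAStringSet",
                   utr3 = "DNAStringSet", pars = "list"))

setValidity("TranscriptSet", function(object) {
    n <- length(object@orf)
    msgs <- character()
    if (length(object@utr5) != n || length(object@utr3) != n)
        msgs <- c(msgs, "utr5/orf/utr3 must have equal length")
    ids <- names(object@orf)
    if (is.null(ids) || anyDuplicated(ids))
        msgs <- c(msgs, "gene ids must be present and unique")
    else if (!identical(names(object@utr5), ids) ||
             !identical(names(object@utr3), ids))
        msgs <- c(msgs, "segment names must agree across utr5/orf/utr3")
    w <- Biostrings::width(object@orf)
    if (any(w == 0L) || any(w %% 3L != 0L))
        msgs <- c(msgs, "ORF widths must be positive multiples of 3")
    if (length(object@pars)) {
        if (!identical(names(object@pars), ids))
            msgs <- c(msgs, "pars must be named like the gene ids")
        tot <- Biostrings::width(object@utr5) + w + Biostrings::width(object@utr3)
        bad <- vapply(seq_len(n), function(i) {
            p <- object@pars[[i]]
            !is.null(p) && length(p) != tot[i]
        }, logical(1))
        if (any(bad))
            msgs <- c(msgs, paste("pars length mismatch for:",
                                  paste(ids[bad], collapse = ", ")))
    }
    if (length(msgs)) msgs else TRUE
})

#' FeatureSet: genes-by-features matrix plus its catalogue
#'
#' @slot values numeric matrix, genes (rows) by features (columns).
#' @slot catalogue data.frame describing each feature column (name, scope,
#'   family, default value, whether it is retuned under scheme B).
#' @slot scheme "A" (expression-free) or "B" (expression-optimised).
#' @slot cache list of intermediates (codon counts, start-context windows)
#'   that allow cheap per-replicate recomputation of scheme-B columns.
#' @exportClass FeatureSet
setClass("FeatureSet",
    representation(values = "matrix", catalogue = "data.frame",
                   scheme = "character", cache = "list"))

setValidity("FeatureSet", function(object) {
    msgs <- character()
    if (!is.numeric(object@values)) msgs <- c(msgs, "values must be numeric")
    if (anyDuplicated(colnames(object@values)))
        msgs <- c(msgs, "duplicate feature names")
    if (!identical(colnames(object@values), object@catalogue$name))
        msgs <- c(msgs, "columns must match the catalogue (same order)")
    if (!object@scheme %in% c("A", "B"))
        msgs <- c(msgs, "scheme must be 'A' or 'B'")
    if (length(msgs)) msgs else TRUE
})

#' Predictor: one fitted greedy regressor
#'
#' @slot target,scope,scheme,modelKind character scalars.
#' @slot features selected feature names, in selection order.
#' @slot model fitted model (linear: coefficients; mars: basis terms).
#' @slot correlations named numeric: train, test, validation.
#' @slot replicate index of the tercile split this predictor was fitted on.
#' @exportClass Predictor
setClass("Predictor",
    representation(target = "character", scope = "character",
                   scheme = "character", modelKind = "character",
                   features = "character", model = "list",
                   correlations = "numeric", replicate = "integer"))

#' PredictorFamily: the jackknife family of predictors
#'
#' One predictor per random tercile split, the member with the median
#' validation correlation, and per-feature prevalence (how many members
#' selected the feature, 0..n_replicates).
#'
#' @slot predictors list of \code{Predictor}.
#' @slot prevalence named integer vector over selected features.
#' @slot medianIndex index (into predictors) of the median-validation member.
#' @slot seed the root seed the splits were drawn from.
#' @exportClass PredictorFamily
setClass("PredictorFamily",
    representation(predictors = "list", target = "character",
                   scope = "character", scheme = "character",
                   modelKind = "character", prevalence = "integer",
                   medianIndex = "integer", seed = "integer"))

setValidity("PredictorFamily", function(object) {
    n <- length(object@predictors)
    msgs <- character()
    if (any(object@prevalence > n))
        msgs <- c(msgs, "prevalence cannot exceed the family size")
    if (n && (object@medianIndex < 1L || object@medianIndex > n))
        msgs <- c(msgs, "medianIndex out of range")
    if (length(msgs)) msgs else TRUE
})

setMethod("show", "TranscriptSet", function(object) {
    cat("TranscriptSet with", length(object@orf), "genes\n")
    cat("  mean lengths (nt): 5'UTR",
        round(mean(Biostrings::width(object@utr5)), 1), "| ORF",
        round(mean(Biostrings::width(object@orf)), 1), "| 3'UTR",
        round(mean(Biostrings::width(object@utr3)), 1), "\n")
    np <- sum(!vapply(object@pars, is.null, logical(1)))
    if (length(object@pars)) cat("  PARS profiles:", np, "genes\n")
})

setMethod("show", "FeatureSet", function(object) {
    cat("FeatureSet: ", nrow(object@values), " genes x ",
        ncol(object@values), " features (scheme ", object@scheme, ")\n",
        sep = "")
    fam <- table(object@catalogue$family)
    cat("  families:", paste(names(fam), fam, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "Predictor", function(object) {
    cat(sprintf("Predictor [%s | %s | scheme %s | %s] %d features\n",
                object@target, object@scope, object@scheme, object@modelKind,
                length(object@features)))
    cat("  correlations:",
        paste(names(object@correlations),
              round(object@correlations, 3), sep = "=", collapse = ", "), "\n")
})

setMethod("show", "PredictorFamily", function(object) {
    cat(sprintf("PredictorFamily [%s | %s | scheme %s | %s], %d replicates\n",
                object@target, object@scope, object@scheme, object@modelKind,
                length(object@predictors)))
    med <- object@predictors[[object@medianIndex]]
    cat("  median validation correlation:",
        round(med@correlations[["validation"]], 3), "\n")
})
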