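#' Accessors
#'
#' Accessor generics for the core classes.
#' @param x object
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("utr5", function(x) standardGeneric("utr5"))
#' @rdname accessors
#' @export
setGeneric("orf", function(x) standardGeneric("orf"))
#' @rdname accessors
#' @export
setGeneric("utr3", function(x) standardGeneric("utr3"))
#' @rdname accessors
#' @export
setGeneric("parsScores", function(x) standardGeneric("parsScores"))
#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @rdname accessors
#' @export
setGeneric("catalogue", function(x) standardGeneric("catalogue"))
#' @rdname accessors
#' @export
setGeneric("scheme", function(x) standardGeneric("scheme"))
#' @rdname accessors
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))
#' @rdname accessors
#' @export
setGeneric("predictors", function(x) standardGeneric("predictors"))
#' @rdname accessors
#' @export
setGeneric("prevalence", function(x) standardGeneric("prevalence"))
#' @rdname accessors
#' @export
setGeneric("medianPredictor", function(x) standardGeneric("medianPredictor"))

#' @rdname accessors
#' @export
setMethod("geneIds", "TranscriptSet", function(x) names(x@orf))
#' @rdname accessors
#' @export
setMethod("utr5", "TranscriptSet", function(x) x@utr5)
#' @rdname accessors
#' @export
setMethod("orf", "TranscriptSet", function(x) x@orf)
#' @rdname accessors
#' @export
setMethod("utr3", "TranscriptSet", function(x) x@utr3)
#' @rdname accessors
#' @export
setMethod("parsScores", "TranscriptSet", function(x) x@pars)
#' @rdname accessors
#' @export
setMethod("geneIds", "FeatureSet", function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("featureMatrix", "FeatureSet", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("catalogue", "FeatureSet", function(x) x@catalogue)
#' @rdname accessors
#' @export
setMethod("scheme", "FeatureSet", function(x) x@scheme)
#' @rdname accessors
#' @export
setMethod("selectedFeatures", "Predictor", function(x) x@features)
#' @rdname accessors
#' @export
setMethod("predictors", "PredictorFamily", function(x) x@predictors)
#' @rdname accessors
#' @export
setMethod("prevalence", "PredictorFamily", function(x) x@prevalence)
#' @rdname accessors
#' @export
setMethod("medianPredictor", "PredictorFamily",
          function(x) x@predictors[[x@medianIndex]])

#' Number of genes / subsetting
#' @param x a TranscriptSet
#' @export
setMethod("length", "TranscriptSet", function(x) length(x@orf))

#' @param i gene ids or indices
#' @rdname accessors
#' @export
setMethod("[", "TranscriptSet", function(x, i, j, ..., drop = TRUE) {
    new("TranscriptSet", utr5 = x@utr5[i], orf = x@orf[i], utr3 = x@utr3[i],
        pars = if (length(x@pars)) x@pars[i] else list())
})
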