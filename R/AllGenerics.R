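#' @name pgxStrat-accessors
#' @title Accessors for pgxStrat classes
#'
#' @description Accessor generics for the package's S4 classes: `dosages()`
#' (variants x samples dosage matrix), `variantIds()`, `groupLabels()` and
#' `groupLabels<-`, `pcScores()`, `alleleWeights()`, `explainedVariance()`,
#' `foldAccuracy()`, `meanAccuracy()`, `sdAccuracy()`, `confusionMatrix()`,
#' `misclassifiedIds()`, `bestParams()`.
#'
#' @param x an object of the relevant class.
#' @param value replacement value.
#' @return The slot contents (or derived summary) appropriate to the accessor.
NULL

#' @rdname pgxStrat-accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname pgxStrat-accessors
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' @rdname pgxStrat-accessors
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname pgxStrat-accessors
#' @export
setGeneric("groupLabels<-", function(x, value) standardGeneric("groupLabels<-"))

#' @rdname pgxStrat-accessors
#' @export
setGeneric("pcScores", function(x) standardGeneric("pcScores"))

#' @rdname pgxStrat-accessors
#' @export
setGeneric("alleleWeights", function(x) standardGeneric("alleleWeights"))

#' @rdname pgxStrat-accessors
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))

#' @rdname pgxStrat-accessors
#' @export
setGeneric("foldAccuracy", function(x) standardGeneric("foldAccuracy"))

#' @rdname pgxStrat-accessors
#' @export
setGeneric("meanAccuracy", function(x) standardGeneric("meanAccuracy"))

#' @rdname pgxStrat-accessors
#' @export
setGeneric("sdAccuracy", function(x) standardGeneric("sdAccuracy"))

#' @rdname pgxStrat-accessors
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))

#' @rdname pgxStrat-accessors
#' @export
setGeneric("misclassifiedIds", function(x) standardGeneric("misclassifiedIds"))

#' @rdname pgxStrat-accessors
#' @export
setGeneric("bestParams", function(x) standardGeneric("bestParams"))

#' @rdname pgxStrat-accessors
#' @export
setGeneric("groupFrequencies", function(x) standardGeneric("groupFrequencies"))

#' @rdname pgxStrat-accessors
#' @export
setGeneric("divergentVariantIds", function(x) standardGeneric("divergentVariantIds"))

#' @rdname pgxStrat-accessors
#' @export
setGeneric("ancestryProportions", function(x) standardGeneric("ancestryProportions"))
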