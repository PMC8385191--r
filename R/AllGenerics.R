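#' @include AllClasses.R
NULL

#' Extract the expression matrix
#' @param x a PlatformExpression
#' @return numeric matrix, genes x samples
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' Platform tag of an expression object
#' @param x a PlatformExpression
#' @export
setGeneric("platformName", function(x) standardGeneric("platformName"))

#' Scale ("counts" or "log2") of an expression object
#' @param x a PlatformExpression
#' @export
setGeneric("exprScale", function(x) standardGeneric("exprScale"))

#' Gene symbols of a centroid set
#' @param x a CentroidSet
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' Subtype labels of a centroid set or call set
#' @param x a CentroidSet or SubtypeCallSet
#' @export
setGeneric("subtypes", function(x) standardGeneric("subtypes"))

#' Centroid value matrix (genes x subtypes)
#' @param x a CentroidSet
#' @export
setGeneric("centroidValues", function(x) standardGeneric("centroidValues"))

#' Assigned subtype labels, named by sample
#' @param x a SubtypeCallSet
#' @export
setGeneric("callLabels", function(x) standardGeneric("callLabels"))

#' Per-sample centroid correlation matrix
#' @param x a SubtypeCallSet
#' @export
setGeneric("callCorrelations",
           function(x) standardGeneric("callCorrelations"))

#' Classification mode ("SSP5" or "SSP2")
#' @param x a SubtypeCallSet
#' @export
setGeneric("callMode", function(x) standardGeneric("callMode"))

#' Fitted DWD direction (unit vector over genes)
#' @param x a DWDModel
#' @export
setGeneric("dwdDirection", function(x) standardGeneric("dwdDirection"))

## ---------------------------------------------------------------------------
## accessor methods
## ---------------------------------------------------------------------------

#' @rdname exprValues
#' @export
setMethod("exprValues", "PlatformExpression", function(x)
    SummarizedExperiment::assay(x, "exprs"))

#' @rdname platformName
#' @export
setMethod("platformName", "PlatformExpression", function(x) x@platform)

#' @rdname exprScale
#' @export
setMethod("exprScale", "PlatformExpression", function(x) x@scale)

#' @rdname genes
#' @export
setMethod("genes", "CentroidSet", function(x) rownames(x@values))

#' @rdname subtypes
#' @export
setMethod("subtypes", "CentroidSet", function(x) colnames(x@values))

#' @rdname subtypes
#' @export
setMethod("subtypes", "SubtypeCallSet",
          function(x) colnames(x@correlations))

#' @rdname centroidValues
#' @export
setMethod("centroidValues", "CentroidSet", function(x) x@values)

#' @rdname callLabels
#' @export
setMethod("callLabels", "SubtypeCallSet", function(x)
    stats::setNames(x@labels, rownames(x@correlations)))

#' @rdname callCorrelations
#' @export
setMethod("callCorrelations", "SubtypeCallSet",
          function(x) x@correlations)

#' @rdname callMode
#' @export
setMethod("callMode", "SubtypeCallSet", function(x) x@mode)

#' @rdname dwdDirection
#' @export
setMethod("dwdDirection", "DWDModel", function(x) x@direction)

#' @describeIn CentroidSet-class number of genes and subtypes
#' @param x a CentroidSet
#' @export
setMethod("dim", "CentroidSet", function(x) dim(x@values))

#' Subset a CentroidSet by genes (i) and/or subtypes (j)
#' @param x a CentroidSet
#' @param i gene index or names
#' @param j subtype index or names
#' @param ... ignored
#' @param drop ignored (never drops)
#' @export
setMethod("[", "CentroidSet", function(x, i, j, ..., drop = FALSE) {
    v <- x@values
    if (!missing(i)) v <- v[i, , drop = FALSE]
    if (!missing(j)) v <- v[, j, drop = FALSE]
    new("CentroidSet", values = v)
})

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "PlatformExpression", function(object) {
    v <- exprValues(object)
    cat(sprintf("PlatformExpression: %d features x %d samples [%s, %s]\n",
                nrow(v), ncol(v), object@platform, object@scale))
    if (anyNA(v))
        cat(sprintf("  %d missing entries\n", sum(is.na(v))))
})

setMethod("show", "CentroidSet", function(object) {
    v <- object@values
    cat(sprintf("CentroidSet: %d genes x %d subtypes (%s)\n",
                nrow(v), ncol(v), paste(colnames(v), collapse = ", ")))
    if (anyNA(v))
        cat(sprintf("  %d missing entries (impute before classification)\n",
                    sum(is.na(v))))
})

setMethod("show", "SubtypeCallSet", function(object) {
    cat(sprintf("SubtypeCallSet: %d samples, mode %s, threshold %.3g\n",
                length(object@labels), object@mode, object@threshold))
    print(table(factor(object@labels,
                       levels = c(colnames(object@correlations),
                                  UNCLASSIFIED))))
})

setMethod("show", "DWDModel", function(object) {
    cat(sprintf(
        "DWDModel: %d genes, C = %.4g, objective = %.6g\n",
        length(object@direction), object@penaltyC, object@objective))
})

setMethod("show", "ConcordanceResult", function(object) {
    cat(sprintf(
        "ConcordanceResult: %d pairs (%d excluded as UNCLASSIFIED)\n",
        object@nPairsTotal, object@nUnclassifiedExcluded))
    print(object@table)
    if (!is.na(object@agreementCount))
        cat(sprintf("agreement: %d/%d (%.1f%%)\n", object@agreementCount,
                    sum(object@table), 100 * object@agreementProportion))
    if (!is.na(object@kappa))
        cat(sprintf("Cohen's kappa: %.4f\n", object@kappa))
})

setMethod("show", "SyntheticCohort", function(object) {
    cat(sprintf("SyntheticCohort: %d tumors, %d matched normals, %d genes\n",
                length(object@trueLabels), nrow(object@normalPairs),
                nrow(exprValues(object@exprA))))
    print(table(object@trueLabels))
})
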