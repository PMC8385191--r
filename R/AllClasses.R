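#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay
#' @importFrom S4Vectors metadata
#' @importFrom stats cor quantile sd median rnorm runif rexp rbinom rpois
#'   pchisq prcomp setNames
#' @importFrom utils read.delim write.table read.csv head
NULL

#' Canonical PAM50 intrinsic subtype labels
#'
#' The five intrinsic subtypes in canonical order: Basal-like,
#' HER2-enriched, LuminalA, LuminalB, Normal-like.  This order is used
#' for deterministic tie-breaking in classification and as the default
#' column order of centroid tables.
#'
#' @export
PAM50_SUBTYPES <- c("Basal-like", "HER2-enriched", "LuminalA",
                    "LuminalB", "Normal-like")

#' Label assigned to samples whose maximum centroid correlation falls
#' below the unclassified threshold
#'
#' @export
UNCLASSIFIED <- "UNCLASSIFIED"

#' Default housekeeper gene set for digital-count normalization
#'
#' Six stably expressed control genes whose per-sample geometric mean is
#' divided out of every count: ACTB, G6PD, RPLP0, TBP, TFRC, UBB.
#'
#' @export
DEFAULT_HOUSEKEEPERS <- c("ACTB", "G6PD", "RPLP0", "TBP", "TFRC", "UBB")

#' Clinical IHC phenotype labels (hormone receptor x HER2)
#' @export
IHC_PHENOTYPES <- c("HR+/HER2+", "HR+/HER2-", "HR-/HER2+", "HR-/HER2-",
                    "missing")

## ---------------------------------------------------------------------------
## PlatformExpression
## ---------------------------------------------------------------------------

#' PlatformExpression: a gene-by-sample expression matrix with platform
#' and scale metadata
#'
#' Thin extension of \linkS4class{SummarizedExperiment} carrying a
#' platform tag (e.g. \code{"ncounter"}, \code{"microarray"}) and a scale
#' flag: \code{"counts"} for non-negative digital counts, \code{"log2"}
#' for log2 expression values.  Rows are genes (or probes, pre-collapse),
#' columns are samples.
#'
#' @slot platform single character platform tag
#' @slot scale \code{"counts"} or \code{"log2"}
#' @export
setClass("PlatformExpression",
         contains = "SummarizedExperiment",
         representation(platform = "character", scale = "character"))

setValidity("PlatformExpression", function(object) {
    msg <- character()
    if (length(object@platform) != 1L || is.na(object@platform))
        msg <- c(msg, "'platform' must be a single non-NA string")
    if (length(object@scale) != 1L || !object@scale %in% c("counts", "log2"))
        msg <- c(msg, "'scale' must be \"counts\" or \"log2\"")
    v <- SummarizedExperiment::assay(object)
    if (is.null(rownames(v)) || is.null(colnames(v)))
        msg <- c(msg, "expression matrix must have row (gene/probe) and column (sample) names")
    else {
        if (anyDuplicated(rownames(v)))
            msg <- c(msg, "duplicate gene/probe IDs")
        if (anyDuplicated(colnames(v)))
            msg <- c(msg, "duplicate sample IDs")
    }
    if (identical(object@scale, "counts") && any(v < 0, na.rm = TRUE))
        msg <- c(msg, "counts-scale matrix contains negative values")
    if (identical(object@scale, "log2") && any(is.infinite(v)))
        msg <- c(msg, "log2-scale matrix contains infinite values")
    if (length(msg)) msg else TRUE
})

#' Construct a PlatformExpression object
#'
#' @param values numeric matrix, genes/probes in rows, samples in columns,
#'   with dimnames set
#' @param platform platform tag, e.g. \code{"ncounter"} or
#'   \code{"microarray"}
#' @param scale \code{"log2"} or \code{"counts"}
#' @return a \linkS4class{PlatformExpression}
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("ESR1", "ERBB2"), paste0("S", 1:3)))
#' PlatformExpression(m, platform = "microarray", scale = "log2")
#' @export
PlatformExpression <- function(values, platform = "generic",
                               scale = c("log2", "counts")) {
    scale <- match.arg(scale)
    values <- as.matrix(values)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values))
    new("PlatformExpression", se, platform = platform, scale = scale)
}

## ---------------------------------------------------------------------------
## CentroidSet
## ---------------------------------------------------------------------------

#' CentroidSet: subtype prototype expression vectors
#'
#' A genes x subtypes matrix of prototype (centroid) log2 expression
#' values against which samples are correlated.  Gene symbols are stored
#' uppercase and must be unique; missing entries (\code{NA}) are allowed
#' before imputation.
#'
#' @slot values numeric matrix with gene symbols as rownames and subtype
#'   labels as colnames
#' @export
setClass("CentroidSet", representation(values = "matrix"))

setValidity("CentroidSet", function(object) {
    v <- object@values
    msg <- character()
    if (!is.numeric(v)) msg <- c(msg, "centroid values must be numeric")
    if (is.null(rownames(v)) || is.null(colnames(v)))
        msg <- c(msg, "centroid matrix must have gene rownames and subtype colnames")
    else {
        dup <- rownames(v)[duplicated(rownames(v))]
        if (length(dup))
            msg <- c(msg, paste0("duplicate gene symbol(s): ",
                                 paste(unique(dup), collapse = ", ")))
        if (any(rownames(v) != toupper(rownames(v))))
            msg <- c(msg, "gene symbols must be uppercase")
        if (anyDuplicated(colnames(v)))
            msg <- c(msg, "duplicate subtype labels")
    }
    if (any(is.infinite(v)))
        msg <- c(msg, "centroid values must be finite or NA")
    if (length(msg)) msg else TRUE
})

#' Construct a CentroidSet
#'
#' @param values numeric matrix, genes in rows (symbols, will be
#'   uppercased), subtypes in columns
#' @return a \linkS4class{CentroidSet}
#' @export
CentroidSet <- function(values) {
    values <- as.matrix(values)
    rownames(values) <- toupper(rownames(values))
    new("CentroidSet", values = values)
}

## ---------------------------------------------------------------------------
## SubtypeCallSet
## ---------------------------------------------------------------------------

#' SubtypeCallSet: per-sample nearest-centroid subtype calls
#'
#' Holds, for each sample, the Spearman correlation to every centroid of
#' the mode, the assigned label (a subtype or \code{UNCLASSIFIED}), the
#' number of genes used, the mode (\code{"SSP5"} with the Normal-like
#' centroid, \code{"SSP2"} without it) and the unclassified threshold
#' applied.
#'
#' @slot correlations samples x subtypes matrix of Spearman rho (NA where
#'   undefined)
#' @slot labels character vector of assigned labels, parallel to rows
#' @slot nGenesUsed integer vector of overlapping gene counts
#' @slot mode \code{"SSP5"} or \code{"SSP2"}
#' @slot threshold unclassified threshold applied to the maximum rho
#' @export
setClass("SubtypeCallSet",
         representation(correlations = "matrix", labels = "character",
                        nGenesUsed = "integer", mode = "character",
                        threshold = "numeric"))

setValidity("SubtypeCallSet", function(object) {
    msg <- character()
    n <- nrow(object@correlations)
    if (length(object@labels) != n || length(object@nGenesUsed) != n)
        msg <- c(msg, "labels/nGenesUsed length must match correlation rows")
    if (!object@mode %in% c("SSP5", "SSP2"))
        msg <- c(msg, "mode must be SSP5 or SSP2")
    ok <- c(colnames(object@correlations), UNCLASSIFIED)
    if (!all(object@labels %in% ok))
        msg <- c(msg, "labels must be a correlation column or UNCLASSIFIED")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## DWDModel
## ---------------------------------------------------------------------------

#' DWDModel: a fitted distance-weighted discrimination direction
#'
#' @slot direction unit vector over genes (named)
#' @slot intercept scalar intercept of the separating hyperplane
#' @slot penaltyC positive penalty used
#' @slot scaleFactors per-gene standard deviations used for
#'   standardization ("Standardized DWD"); zero-variance genes carry
#'   factor NA and direction weight 0
#' @slot refMeanProjection projection of the reference batch mean on the
#'   direction
#' @slot objective achieved objective value of the DWD program
#' @export
setClass("DWDModel",
         representation(direction = "numeric", intercept = "numeric",
                        penaltyC = "numeric", scaleFactors = "numeric",
                        refMeanProjection = "numeric",
                        objective = "numeric"))

setValidity("DWDModel", function(object) {
    msg <- character()
    nrm <- sqrt(sum(object@direction^2))
    if (abs(nrm - 1) > 1e-8)
        msg <- c(msg, sprintf("direction norm %.10f != 1", nrm))
    if (!(length(object@penaltyC) == 1L && object@penaltyC > 0))
        msg <- c(msg, "penaltyC must be a positive scalar")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## ConcordanceResult
## ---------------------------------------------------------------------------

#' ConcordanceResult: paired-call agreement bookkeeping
#'
#' Confusion matrix of paired subtype calls (reference subtypes in
#' columns, test subtypes in rows), with pairs involving an
#' \code{UNCLASSIFIED} label excluded from the body but counted, plus the
#' derived per-class accuracies, overall agreement and Cohen's kappa
#' (filled in by \code{\link{perClassAccuracy}},
#' \code{\link{overallAgreement}} and \code{\link{cohensKappa}}).
#'
#' @slot table integer matrix of counts, test x reference
#' @slot nPairsTotal total paired samples
#' @slot nUnclassifiedExcluded pairs dropped because either label was
#'   UNCLASSIFIED
#' @slot perClassAccuracy data.frame (subtype, numerator, denominator,
#'   proportion) or empty before computation
#' @slot agreementCount diagonal sum (NA before computation)
#' @slot agreementProportion diagonal sum / body sum (NA before)
#' @slot kappa unweighted Cohen's kappa (NA before computation or when
#'   degenerate)
#' @export
setClass("ConcordanceResult",
         representation(table = "matrix", nPairsTotal = "integer",
                        nUnclassifiedExcluded = "integer",
                        perClassAccuracy = "data.frame",
                        agreementCount = "numeric",
                        agreementProportion = "numeric",
                        kappa = "numeric"))

setValidity("ConcordanceResult", function(object) {
    msg <- character()
    if (sum(object@table) + object@nUnclassifiedExcluded !=
        object@nPairsTotal)
        msg <- c(msg, "body sum + unclassified-excluded != total pairs")
    if (!identical(rownames(object@table), colnames(object@table)))
        msg <- c(msg, "confusion matrix must be square with matching labels")
    if (!is.na(object@kappa) &&
        (object@kappa < -1 - 1e-12 || object@kappa > 1 + 1e-12))
        msg <- c(msg, "kappa outside [-1, 1]")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Synthetic cohort spec / cohort
## ---------------------------------------------------------------------------

#' SyntheticCohortSpec: every knob of the synthetic cohort generator
#'
#' Defaults emulate the study design this package targets: a tumor cohort
#' with subtype composition (Basal-like 23, HER2-enriched 28, LuminalA 55,
#' LuminalB 37), 24 matched normal breast samples, 50 classifier genes,
#' per-gene Gaussian log2 noise, per-gene affine platform distortion for
#' platform B, exponential subtype-specific survival with uniform
#' censoring over an 11.6-year follow-up horizon.
#'
#' @slot nPerSubtype named counts of tumor samples per subtype
#' @slot nGenes number of classifier genes
#' @slot noiseSd per-gene Gaussian noise SD on the log2 scale
#' @slot platformShiftSd SD of the per-gene additive shift applied on
#'   platform B
#' @slot platformScaleRange length-2 range of the per-gene multiplicative
#'   distortion on platform B
#' @slot missingRate fraction of entries masked missing in [0, 1)
#' @slot probesPerGene probes emitted per gene for the probe-level matrix
#' @slot nNormalPairs number of matched normal samples
#' @slot hazard named per-subtype exponential event rates (per year)
#' @slot censorTimeMax upper bound of the uniform censoring time (years)
#' @slot separation SD of centroid entries (log2 units)
#' @slot ihcProbs subtype x phenotype probability matrix (rows sum to 1)
#' @slot seed integer RNG seed; identical seed gives a bit-identical
#'   cohort
#' @export
setClass("SyntheticCohortSpec",
         representation(nPerSubtype = "numeric", nGenes = "numeric",
                        noiseSd = "numeric", platformShiftSd = "numeric",
                        platformScaleRange = "numeric",
                        missingRate = "numeric", probesPerGene = "numeric",
                        nNormalPairs = "numeric", hazard = "numeric",
                        censorTimeMax = "numeric", separation = "numeric",
                        ihcProbs = "matrix", seed = "numeric"))

setValidity("SyntheticCohortSpec", function(object) {
    msg <- character()
    if (any(object@nPerSubtype < 0)) msg <- c(msg, "negative subtype count")
    if (is.null(names(object@nPerSubtype)))
        msg <- c(msg, "nPerSubtype must be named by subtype")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (object@missingRate < 0 || object@missingRate >= 1)
        msg <- c(msg, "missingRate must be in [0, 1)")
    if (object@probesPerGene < 1) msg <- c(msg, "probesPerGene must be >= 1")
    if (length(object@platformScaleRange) != 2L ||
        diff(object@platformScaleRange) < 0)
        msg <- c(msg, "platformScaleRange must be an increasing length-2 range")
    if (any(object@hazard < 0)) msg <- c(msg, "hazards must be >= 0")
    if (abs(sum(object@ihcProbs) - nrow(object@ihcProbs)) > 1e-8)
        msg <- c(msg, "each ihcProbs row must sum to 1")
    if (length(msg)) msg else TRUE
})

#' SyntheticCohort: a generated paired two-platform cohort with ground
#' truth
#'
#' @slot exprA platform-A log2 expression (\linkS4class{PlatformExpression})
#' @slot exprB platform-B log2 expression, same samples, affine-distorted
#' @slot trueLabels named true subtype per sample
#' @slot clinical data.frame of clinical records (sample_id, hr_status,
#'   her2_status, followup_time, event_death, event_bc)
#' @slot centroids the \linkS4class{CentroidSet} the cohort was drawn from
#' @slot normalExpr matrix of matched normal samples (or NULL)
#' @slot normalPairs data.frame linking normal sample IDs to tumor IDs
#' @export
setClass("SyntheticCohort",
         representation(exprA = "PlatformExpression",
                        exprB = "PlatformExpression",
                        trueLabels = "character",
                        clinical = "data.frame",
                        centroids = "CentroidSet",
                        normalExpr = "ANY",
                        normalPairs = "data.frame"))
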