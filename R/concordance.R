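## Cross-platform / cross-assay agreement statistics: confusion matrix
## with unclassified bookkeeping, per-class accuracy, overall agreement,
## unweighted Cohen's kappa, IHC crosstabs and matched-normal summaries.

.labelsOf <- function(x) {
    if (is(x, "SubtypeCallSet")) callLabels(x)
    else if (is.character(x)) {
        if (is.null(names(x))) stop("label vectors must be named by sample")
        x
    } else stop("expected a SubtypeCallSet or a named character vector")
}

#' Paired confusion matrix of two call sets
#'
#' Counts paired calls (reference subtypes in columns, test subtypes in
#' rows).  Pairs where either label is \code{UNCLASSIFIED} are excluded
#' from the matrix body but counted in \code{nUnclassifiedExcluded}.
#'
#' @param callsRef reference calls (\linkS4class{SubtypeCallSet} or
#'   named character vector), e.g. the gold-standard platform
#' @param callsTest test calls, paired by sample ID
#' @param classes class labels of the matrix (default: subtypes seen in
#'   either call set, in canonical PAM50 order first)
#' @return a \linkS4class{ConcordanceResult} with counts only; chain
#'   \code{\link{perClassAccuracy}}, \code{\link{overallAgreement}} and
#'   \code{\link{cohensKappa}} (or call \code{\link{concordance}})
#' @export
confusionMatrix <- function(callsRef, callsTest, classes = NULL) {
    ref <- .labelsOf(callsRef); test <- .labelsOf(callsTest)
    if (is(callsRef, "SubtypeCallSet") && is(callsTest, "SubtypeCallSet") &&
        callMode(callsRef) != callMode(callsTest))
        stop("call sets have different modes: ", callMode(callsRef),
             " vs ", callMode(callsTest))
    unpaired <- c(setdiff(names(ref), names(test)),
                  setdiff(names(test), names(ref)))
    if (length(unpaired))
        stop("unpaired sample(s): ",
             paste(unique(unpaired), collapse = ", "))
    test <- test[names(ref)]
    if (is.null(classes)) {
        seen <- setdiff(unique(c(ref, test)), UNCLASSIFIED)
        classes <- c(intersect(PAM50_SUBTYPES, seen),
                     setdiff(seen, PAM50_SUBTYPES))
    }
    drop <- ref == UNCLASSIFIED | test == UNCLASSIFIED
    tab <- table(factor(test[!drop], levels = classes),
                 factor(ref[!drop], levels = classes))
    body <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                   dimnames = list(classes, classes))
    new("ConcordanceResult", table = body,
        nPairsTotal = length(ref),
        nUnclassifiedExcluded = sum(drop),
        perClassAccuracy = data.frame(),
        agreementCount = NA_real_, agreementProportion = NA_real_,
        kappa = NA_real_)
}

#' Build a ConcordanceResult from a pre-tabulated confusion matrix
#'
#' For agreement tables that are given as counts (e.g. transcribed from
#' a publication) rather than as per-sample calls.
#'
#' @param tab square count matrix, test subtypes in rows, reference
#'   subtypes in columns
#' @param nUnclassifiedExcluded pairs that were dropped from the body
#'   because one platform left them unclassified
#' @return a \linkS4class{ConcordanceResult} with counts only
#' @export
concordanceFromTable <- function(tab, nUnclassifiedExcluded = 0L) {
    tab <- as.matrix(tab)
    storage.mode(tab) <- "integer"
    if (nrow(tab) != ncol(tab) ||
        !identical(rownames(tab), colnames(tab)))
        stop("need a square matrix with identical row and column labels")
    new("ConcordanceResult", table = tab,
        nPairsTotal = as.integer(sum(tab) + nUnclassifiedExcluded),
        nUnclassifiedExcluded = as.integer(nUnclassifiedExcluded),
        perClassAccuracy = data.frame(),
        agreementCount = NA_real_, agreementProportion = NA_real_,
        kappa = NA_real_)
}

#' Per-class prediction accuracy against the reference platform
#'
#' For each reference subtype: diagonal cell over reference column total
#' (classified pairs only).  Classes with an empty reference column are
#' reported as NA.
#'
#' @param result a \linkS4class{ConcordanceResult}
#' @return the result with \code{perClassAccuracy} filled in
#' @export
perClassAccuracy <- function(result) {
    tab <- result@table
    num <- diag(tab)
    den <- colSums(tab)
    result@perClassAccuracy <- data.frame(
        subtype = colnames(tab), numerator = as.integer(num),
        denominator = as.integer(den),
        proportion = ifelse(den > 0, num / den, NA_real_),
        row.names = NULL)
    result
}

#' Overall agreement (diagonal proportion) of a confusion matrix
#'
#' @param result a \linkS4class{ConcordanceResult}
#' @return the result with \code{agreementCount} and
#'   \code{agreementProportion} (over classified pairs) filled in
#' @export
overallAgreement <- function(result) {
    tab <- result@table
    if (sum(tab) == 0L) stop("empty confusion-matrix body")
    result@agreementCount <- as.numeric(sum(diag(tab)))
    result@agreementProportion <- sum(diag(tab)) / sum(tab)
    result
}

.kappa <- function(tab) {
    n <- sum(tab)
    po <- sum(diag(tab)) / n
    pe <- sum(rowSums(tab) * colSums(tab)) / n^2
    if (abs(1 - pe) < 1e-15) return(NA_real_)
    (po - pe) / (1 - pe)
}

#' Unweighted Cohen's kappa of a confusion matrix
#'
#' kappa = (p_o - p_e) / (1 - p_e) with p_o the diagonal proportion and
#' p_e = sum_i (row_i * col_i) / N^2, computed on the classified-pairs
#' body.  Degenerate marginals (p_e = 1) give NA.
#'
#' @param result a \linkS4class{ConcordanceResult}
#' @return the result with \code{kappa} filled in
#' @export
cohensKappa <- function(result) {
    tab <- result@table
    nz <- sum(rowSums(tab) > 0 | colSums(tab) > 0)
    if (nz < 2L) stop("kappa needs >= 2 classes with nonzero marginals")
    result@kappa <- .kappa(tab)
    result
}

#' Full concordance analysis of two paired call sets
#'
#' Convenience wrapper chaining \code{\link{confusionMatrix}},
#' \code{\link{perClassAccuracy}}, \code{\link{overallAgreement}} and
#' \code{\link{cohensKappa}}.
#'
#' @inheritParams confusionMatrix
#' @return a fully populated \linkS4class{ConcordanceResult}
#' @export
concordance <- function(callsRef, callsTest, classes = NULL) {
    cohensKappa(overallAgreement(perClassAccuracy(
        confusionMatrix(callsRef, callsTest, classes = classes))))
}

## ---------------------------------------------------------------------------
## IHC crosstabs
## ---------------------------------------------------------------------------

#' Derive the HR/HER2 phenotype of each clinical record
#'
#' @param clinical data.frame with columns \code{hr_status} and
#'   \code{her2_status} (values "positive", "negative" or "missing")
#' @return character vector of \code{IHC_PHENOTYPES}
#' @export
ihcPhenotype <- function(clinical) {
    hr <- clinical$hr_status; her2 <- clinical$her2_status
    out <- rep("missing", nrow(clinical))
    known <- hr != "missing" & her2 != "missing"
    out[known] <- paste0("HR", ifelse(hr[known] == "positive", "+", "-"),
                         "/HER2",
                         ifelse(her2[known] == "positive", "+", "-"))
    out
}

#' Crosstab of subtype calls against clinical IHC phenotypes
#'
#' @param calls \linkS4class{SubtypeCallSet} or named label vector
#' @param clinical clinical data.frame with \code{sample_id},
#'   \code{hr_status}, \code{her2_status}
#' @return list with \code{counts} (phenotype x subtype matrix, one
#'   explicit "missing" row) and \code{fractions} (per-subtype phenotype
#'   fractions over non-missing IHC only)
#' @export
ihcCrosstab <- function(calls, clinical) {
    labels <- .labelsOf(calls)
    unmatched <- c(setdiff(names(labels), clinical$sample_id),
                   setdiff(clinical$sample_id, names(labels)))
    if (length(unmatched))
        stop("sample(s) without both a call and a clinical record: ",
             paste(unique(unmatched), collapse = ", "))
    clinical <- clinical[match(names(labels), clinical$sample_id), ]
    ph <- factor(ihcPhenotype(clinical), levels = IHC_PHENOTYPES)
    seen <- unique(labels)
    lv <- c(intersect(c(PAM50_SUBTYPES, UNCLASSIFIED), seen),
            setdiff(seen, c(PAM50_SUBTYPES, UNCLASSIFIED)))
    counts <- table(ph, factor(labels, levels = lv))
    counts <- matrix(as.integer(counts), nrow(counts), ncol(counts),
                     dimnames = list(IHC_PHENOTYPES, lv))
    list(counts = counts, fractions = ihcFractions(counts))
}

#' Per-subtype phenotype fractions from an IHC crosstab
#'
#' Fractions are computed over non-missing IHC only (the "missing" row
#' is excluded from the denominator); subtypes with no non-missing
#' record get NA.
#'
#' @param counts phenotype x subtype count matrix whose last/named
#'   "missing" row holds records without IHC
#' @return phenotype x subtype matrix of fractions
#' @export
ihcFractions <- function(counts) {
    if (!"missing" %in% rownames(counts))
        stop("crosstab needs an explicit 'missing' phenotype row")
    body <- counts[setdiff(rownames(counts), "missing"), , drop = FALSE]
    den <- colSums(body)
    sweep(body, 2L, ifelse(den > 0, den, NA_real_), `/`)
}

## ---------------------------------------------------------------------------
## Matched-normal summary
## ---------------------------------------------------------------------------

#' Summarize subtype calls of matched normal tissues
#'
#' Reports (a) how many normal samples are called Normal-like (SSP5),
#' and (b) among normals not called Normal-like, how many share the
#' subtype of their matched tumor.
#'
#' @param callsNormal SSP5 calls for the normal samples
#'   (\linkS4class{SubtypeCallSet} or named label vector)
#' @param callsTumor calls (or true labels) for the matched tumors
#' @param pairs data.frame with columns \code{normal_id} and
#'   \code{tumor_id} linking each normal to its tumor
#' @return list: nNormals, nNormalLike, fracNormalLike,
#'   nNotNormalLike, nMatchingTumor, fracMatchingTumor (NA when no
#'   non-Normal-like normals exist)
#' @export
normalPairSummary <- function(callsNormal, callsTumor, pairs) {
    nl <- .labelsOf(callsNormal); tl <- .labelsOf(callsTumor)
    if (!all(c("normal_id", "tumor_id") %in% colnames(pairs)))
        stop("pairs needs columns 'normal_id' and 'tumor_id'")
    bad <- c(setdiff(pairs$normal_id, names(nl)),
             setdiff(pairs$tumor_id, names(tl)))
    if (length(bad))
        stop("unpaired sample(s): ", paste(unique(bad), collapse = ", "))
    normLab <- nl[pairs$normal_id]
    tumLab <- tl[pairs$tumor_id]
    isNL <- normLab == "Normal-like"
    notNL <- !isNL
    nMatch <- sum(normLab[notNL] == tumLab[notNL])
    list(nNormals = nrow(pairs),
         nNormalLike = sum(isNL),
         fracNormalLike = sum(isNL) / nrow(pairs),
         nNotNormalLike = sum(notNL),
         nMatchingTumor = nMatch,
         fracMatchingTumor = if (sum(notNL) > 0) nMatch / sum(notNL)
                             else NA_real_)
}

#' Expand a tumor-subtype x normal-call count table into paired labels
#'
#' Utility for tables that tabulate matched normal calls against the
#' matched tumor's subtype: returns per-pair label vectors suitable for
#' \code{\link{normalPairSummary}}.
#'
#' @param tab count matrix, matched tumor subtype in rows, normal-tissue
#'   call in columns
#' @return list with named vectors \code{normal}, \code{tumor} and the
#'   \code{pairs} data.frame
#' @export
expandPairTable <- function(tab) {
    tab <- as.matrix(tab)
    normal <- character(); tumor <- character()
    for (i in seq_len(nrow(tab)))
        for (j in seq_len(ncol(tab))) {
            k <- tab[i, j]
            if (k > 0) {
                tumor <- c(tumor, rep(rownames(tab)[i], k))
                normal <- c(normal, rep(colnames(tab)[j], k))
            }
        }
    ids <- sprintf("P%03d", seq_along(normal))
    list(normal = stats::setNames(normal, paste0(ids, "_N")),
         tumor = stats::setNames(tumor, paste0(ids, "_T")),
         pairs = data.frame(normal_id = paste0(ids, "_N"),
                            tumor_id = paste0(ids, "_T")))
}
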