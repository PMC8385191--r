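## Single-sample prediction (SSP): nearest-centroid subtyping by
## Spearman rank correlation, with the unclassified rule.

#' Spearman rank correlation with an explicit undefined-value contract
#'
#' Pearson correlation of average-tie ranks.  When either vector has
#' zero rank variance (all values tied) the correlation is undefined and
#' \code{NA} is returned; callers ranking centroids treat \code{NA} as
#' minus infinity so an undefined correlation can never win the argmax.
#'
#' @param x,y numeric vectors of equal length >= 2
#' @return Spearman rho in [-1, 1], or NA when undefined
#' @export
spearmanRho <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    if (length(x) < 2L) stop("need at least 2 observations")
    suppressWarnings(stats::cor(x, y, method = "spearman"))
}

.sspCentroids <- function(centroids, mode) {
    v <- centroidValues(centroids)
    if (anyNA(v))
        stop("centroid table has missing entries; run imputeMissingKnn first")
    if (mode == "SSP2") {
        if (!"Normal-like" %in% colnames(v))
            stop("SSP2 requested but no Normal-like column to drop")
        v <- v[, setdiff(colnames(v), "Normal-like"), drop = FALSE]
    }
    v
}

#' Classify one sample against subtype centroids
#'
#' Spearman rho of the sample against every centroid over the
#' overlapping gene set (in centroid gene order); the label is the
#' argmax subtype, or \code{UNCLASSIFIED} when the maximum rho is
#' (strictly) below the threshold.  Exact rho ties are broken by
#' centroid column order (canonical subtype order) with a warning.
#'
#' @param values named numeric vector of one sample's (gene-centered)
#'   log2 expression; names are gene symbols
#' @param centroids a complete \linkS4class{CentroidSet}
#' @param mode \code{"SSP5"} (all centroids) or \code{"SSP2"} (drop
#'   Normal-like)
#' @param threshold unclassified threshold on the maximum rho
#'   (default 0.1)
#' @param minGenes minimum overlapping genes required (default 40)
#' @return list with elements \code{label}, \code{correlations} (named
#'   rho vector, NA where undefined), \code{nGenesUsed}
#' @export
classifySample <- function(values, centroids, mode = c("SSP5", "SSP2"),
                           threshold = 0.1, minGenes = 40) {
    mode <- match.arg(mode)
    if (!(threshold > 0 && threshold < 1))
        stop("threshold must be in (0, 1)")
    if (minGenes < 2) stop("minGenes must be >= 2")
    cv <- .sspCentroids(centroids, mode)
    if (is.null(names(values))) stop("sample vector must be gene-named")
    names(values) <- toupper(names(values))
    values <- values[!is.na(values)]
    ov <- rownames(cv)[rownames(cv) %in% names(values)]
    if (length(ov) < minGenes)
        stop(sprintf(
            "only %d of %d centroid genes present (min %d); missing: %s",
            length(ov), nrow(cv), minGenes,
            paste(utils::head(setdiff(rownames(cv), names(values)), 10),
                  collapse = ", ")))
    x <- values[ov]
    rho <- vapply(colnames(cv),
                  function(s) spearmanRho(x, cv[ov, s]), numeric(1))
    key <- ifelse(is.na(rho), -Inf, rho)
    best <- max(key)
    if (!is.finite(best) || best < threshold) {
        label <- UNCLASSIFIED
    } else {
        hits <- which(key == best)
        if (length(hits) > 1L)
            warning("rho tie broken by canonical subtype order: ",
                    paste(colnames(cv)[hits], collapse = " = "))
        label <- colnames(cv)[hits[1L]]
    }
    list(label = label, correlations = rho,
         nGenesUsed = length(ov))
}

#' Classify every sample of a cohort by nearest centroid
#'
#' Applies \code{\link{classifySample}} column-wise.  Samples failing
#' the gene-overlap precondition are skipped with a warning rather than
#' aborting the cohort.  A warning is also emitted when the input does
#' not look gene-centered (some row mean exceeds 0.05 in absolute
#' value).
#'
#' @param expr gene x sample matrix or \linkS4class{PlatformExpression}
#'   of gene-centered log2 values
#' @param centroids complete \linkS4class{CentroidSet}
#' @param mode \code{"SSP5"} or \code{"SSP2"}
#' @param threshold unclassified threshold (default 0.1)
#' @param minGenes minimum overlapping genes (default 40)
#' @param checkCentering warn when row means exceed 0.05 (default TRUE)
#' @return a \linkS4class{SubtypeCallSet}
#' @examples
#' cen <- makeCentroids(nGenes = 50, seed = 1)
#' coh <- generateCohort(cohortSpec(seed = 1, noiseSd = 0), cen)
#' calls <- classifyCohort(exprValues(coh@exprA), cen, mode = "SSP5",
#'                         checkCentering = FALSE)
#' table(callLabels(calls) == coh@trueLabels)
#' @export
classifyCohort <- function(expr, centroids, mode = c("SSP5", "SSP2"),
                           threshold = 0.1, minGenes = 40,
                           checkCentering = TRUE) {
    mode <- match.arg(mode)
    m <- .asExprMatrix(expr)
    if (checkCentering) {
        rm <- abs(rowMeans(m, na.rm = TRUE))
        if (any(rm > 0.05, na.rm = TRUE))
            warning(sum(rm > 0.05, na.rm = TRUE),
                    " gene row(s) have |mean| > 0.05; input may not be gene-centered")
    }
    cv <- .sspCentroids(centroids, mode)
    n <- ncol(m)
    corr <- matrix(NA_real_, n, ncol(cv),
                   dimnames = list(colnames(m), colnames(cv)))
    labels <- rep(NA_character_, n)
    used <- rep(NA_integer_, n)
    for (j in seq_len(n)) {
        res <- tryCatch(
            classifySample(m[, j], centroids, mode = mode,
                           threshold = threshold, minGenes = minGenes),
            error = function(e) e)
        if (inherits(res, "error")) {
            warning(sprintf("sample '%s' skipped: %s", colnames(m)[j],
                            conditionMessage(res)))
            next
        }
        corr[j, ] <- res$correlations
        labels[j] <- res$label
        used[j] <- res$nGenesUsed
    }
    ok <- !is.na(labels)
    out <- new("SubtypeCallSet",
               correlations = corr[ok, , drop = FALSE],
               labels = labels[ok], nGenesUsed = used[ok],
               mode = mode, threshold = threshold)
    counts <- table(factor(out@labels,
                           levels = c(colnames(cv), UNCLASSIFIED)))
    message("subtype calls: ",
            paste(names(counts), counts, sep = "=", collapse = ", "))
    out
}

#' Turn a SubtypeCallSet into a plain data.frame
#'
#' @param x a \linkS4class{SubtypeCallSet}
#' @param row.names,optional,... ignored (S3 compatibility)
#' @return data.frame with sample_id, label, one rho_<subtype> column per
#'   centroid, n_genes_used and mode
#' @export
as.data.frame.SubtypeCallSet <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
    corr <- x@correlations
    colnames(corr) <- paste0("rho_", colnames(corr))
    data.frame(sample_id = rownames(x@correlations), label = x@labels,
               corr, n_genes_used = x@nGenesUsed, mode = x@mode,
               row.names = NULL, check.names = FALSE)
}
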