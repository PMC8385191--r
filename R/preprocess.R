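## Platform-specific preprocessing: negative-control background
## subtraction and housekeeping normalization for digital counts,
## probe-to-gene collapse for microarray data, gene centering for both.

#' Subtract negative-control background from digital counts
#'
#' Per sample, the mean (optionally mean + 2 SD) of that sample's
#' negative-control rows is subtracted from every non-control row and
#' the result clamped at \code{countFloor}.  Control rows are dropped
#' from the output.
#'
#' @param counts a counts-scale \linkS4class{PlatformExpression}
#' @param negativeControls row IDs of the negative-control probes
#' @param countFloor lower clamp applied after subtraction (default 1)
#' @param method \code{"mean"} (default) or \code{"mean2sd"} (mean of the
#'   negatives plus twice their SD)
#' @return counts-scale \linkS4class{PlatformExpression} without the
#'   control rows
#' @export
backgroundSubtract <- function(counts, negativeControls, countFloor = 1,
                               method = c("mean", "mean2sd")) {
    method <- match.arg(method)
    stopifnot(is(counts, "PlatformExpression"))
    if (exprScale(counts) != "counts")
        stop("backgroundSubtract expects a counts-scale matrix")
    v <- exprValues(counts)
    missing <- setdiff(negativeControls, rownames(v))
    if (length(missing))
        stop("negative-control row(s) absent: ",
             paste(missing, collapse = ", "))
    ctl <- v[negativeControls, , drop = FALSE]
    bg <- colMeans(ctl)
    if (method == "mean2sd")
        bg <- bg + 2 * apply(ctl, 2L, stats::sd)
    keep <- setdiff(rownames(v), negativeControls)
    if (!length(keep))
        stop("background subtraction would leave an empty matrix")
    out <- sweep(v[keep, , drop = FALSE], 2L, bg, `-`)
    out[out < countFloor] <- countFloor
    PlatformExpression(out, platform = platformName(counts),
                       scale = "counts")
}

#' Housekeeping (content) normalization of digital counts
#'
#' Per sample, every count is divided by the geometric mean of that
#' sample's housekeeper counts and the ratio log2-transformed.
#' Housekeeper rows are retained (they become roughly constant rows).
#'
#' @param counts background-subtracted counts
#'   (\linkS4class{PlatformExpression}, scale \code{"counts"})
#' @param housekeepers housekeeper gene symbols (default the six-gene
#'   panel \code{DEFAULT_HOUSEKEEPERS})
#' @return log2-scale \linkS4class{PlatformExpression}
#' @export
housekeepingNormalize <- function(counts,
                                  housekeepers = DEFAULT_HOUSEKEEPERS) {
    stopifnot(is(counts, "PlatformExpression"))
    if (exprScale(counts) != "counts")
        stop("housekeepingNormalize expects a counts-scale matrix")
    if (!length(housekeepers)) stop("empty housekeeper list")
    v <- exprValues(counts)
    missing <- setdiff(housekeepers, rownames(v))
    if (length(missing))
        stop("housekeeper row(s) absent: ", paste(missing, collapse = ", "))
    hk <- v[housekeepers, , drop = FALSE]
    if (any(hk <= 0))
        stop("housekeeper count <= 0; apply backgroundSubtract with a positive floor first")
    geo <- exp(colMeans(log(hk)))
    out <- log2(sweep(v, 2L, geo, `/`))
    PlatformExpression(out, platform = platformName(counts),
                       scale = "log2")
}

#' Collapse probe-level rows to one row per gene by maximal IQR
#'
#' When several probes map to the same gene, the probe with the largest
#' interquartile range across samples (the most variable one) is kept;
#' the surviving row is re-labelled with the gene symbol.  Unmapped
#' probes are dropped with a message.
#'
#' @param expr log2 probe-indexed \linkS4class{PlatformExpression}
#' @param annotation data.frame with columns \code{probe_id} and
#'   \code{gene} (many probes may map to one gene; each probe to exactly
#'   one gene)
#' @return gene-indexed log2 \linkS4class{PlatformExpression}
#' @details Quartiles use the default linear-interpolation convention
#'   (\code{stats::quantile} type 7).  IQR ties are broken by probe row
#'   order.
#' @export
collapseProbes <- function(expr, annotation) {
    stopifnot(is(expr, "PlatformExpression"))
    if (!nrow(annotation))
        stop("empty probe annotation")
    if (!all(c("probe_id", "gene") %in% colnames(annotation)))
        stop("annotation needs columns 'probe_id' and 'gene'")
    if (anyDuplicated(annotation$probe_id))
        stop("a probe maps to more than one gene in the annotation")
    v <- exprValues(expr)
    ann <- annotation[annotation$probe_id %in% rownames(v), , drop = FALSE]
    nUnmapped <- sum(!rownames(v) %in% ann$probe_id)
    if (nUnmapped)
        message(nUnmapped, " unmapped probe(s) dropped")
    if (!nrow(ann))
        stop("no probe in the matrix is covered by the annotation")
    iqr <- apply(v, 1L, function(r) unname(diff(
        stats::quantile(r, c(0.25, 0.75), na.rm = TRUE))))
    genesU <- unique(toupper(ann$gene))
    pick <- character(length(genesU))
    for (i in seq_along(genesU)) {
        probes <- ann$probe_id[toupper(ann$gene) == genesU[i]]
        ## preserve matrix row order so IQR ties resolve deterministically
        probes <- rownames(v)[rownames(v) %in% probes]
        pick[i] <- probes[which.max(iqr[probes])]
    }
    out <- v[pick, , drop = FALSE]
    rownames(out) <- genesU
    PlatformExpression(out, platform = platformName(expr), scale = "log2")
}

#' Center each gene row at its within-matrix mean or median
#'
#' Subtracting each gene's cohort mean (or median) puts expression on the
#' relative scale the centroids are defined on.  Centering is done
#' independently per matrix (per platform).
#'
#' @param expr log2 \linkS4class{PlatformExpression}
#' @param method \code{"mean"} (default) or \code{"median"}
#' @return centered log2 \linkS4class{PlatformExpression}
#' @export
centerGenes <- function(expr, method = c("mean", "median")) {
    method <- match.arg(method)
    stopifnot(is(expr, "PlatformExpression"))
    if (exprScale(expr) != "log2")
        stop("centerGenes expects a log2-scale matrix")
    v <- exprValues(expr)
    ctr <- if (method == "mean") rowMeans(v, na.rm = TRUE)
           else apply(v, 1L, stats::median, na.rm = TRUE)
    PlatformExpression(v - ctr, platform = platformName(expr),
                       scale = "log2")
}
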