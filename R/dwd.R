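## Distance-weighted discrimination (DWD) batch adjustment.
##
## DWD finds the direction w (with intercept b) minimizing
##     sum_i 1/r_i + C * sum_i xi_i,   r_i = y_i (w.x_i + b) + xi_i > 0,
## over ||w||_2 <= 1, xi_i >= 0, with y = +1 for the reference batch and
## -1 for the new batch.  Eliminating the slacks gives the equivalent
## smooth convex loss
##     V(u) = 1/u            for u >= 1/sqrt(C)
##     V(u) = 2*sqrt(C) - Cu otherwise,
## minimized here over the unit ball by accelerated projected gradient.
## Systematic batch bias is then removed by shifting every new-batch
## sample along w until the two batch means project identically
## ("center at the first mean").

.asExprMatrix <- function(x) {
    if (is(x, "PlatformExpression")) exprValues(x) else as.matrix(x)
}

## DWD loss and its gradient on standardized data
.dwdObjective <- function(w, b, A, C) {
    u <- drop(crossprod(A, c(w, b)))        # y_i (w.z_i + b)
    thr <- 1 / sqrt(C)
    lo <- u < thr
    sum(1 / u[!lo]) + sum(2 * sqrt(C) - C * u[lo])
}

.dwdGradient <- function(w, b, A, C) {
    u <- drop(crossprod(A, c(w, b)))
    thr <- 1 / sqrt(C)
    vp <- ifelse(u >= thr, -1 / u^2, -C)
    drop(A %*% vp)
}

#' Fit a distance-weighted discrimination direction between two batches
#'
#' Variables are standardized to unit pooled variance before solving
#' (standardized DWD); the fitted direction is then mapped back to the
#' original scale (a unit step along the standardized-space direction
#' corresponds to a step along the per-gene scales times that direction)
#' and renormalized.  Zero-variance genes are excluded from the fit and
#' receive direction weight 0.
#'
#' @param xRef gene x sample matrix (or \linkS4class{PlatformExpression})
#'   of the reference batch (label +1)
#' @param xNew same-gene matrix of the batch to be adjusted (label -1)
#' @param penaltyC positive penalty, or \code{NULL} for the auto rule
#'   C = 100 / (median pairwise inter-batch distance)^2 on the
#'   standardized data
#' @param maxIter iteration cap for the accelerated projected-gradient
#'   solver
#' @param tol relative objective tolerance declaring convergence
#' @return a \linkS4class{DWDModel}
#' @export
fitDWD <- function(xRef, xNew, penaltyC = NULL, maxIter = 50000L,
                   tol = 1e-12) {
    xRef <- .asExprMatrix(xRef); xNew <- .asExprMatrix(xNew)
    if (!identical(rownames(xRef), rownames(xNew)))
        stop("the two batches must share an identical gene index")
    if (ncol(xRef) < 2L || ncol(xNew) < 2L)
        stop("each batch needs at least 2 samples")
    pooled <- cbind(xRef, xNew)
    s <- apply(pooled, 1L, stats::sd)
    keep <- which(s > 0)
    if (length(keep) < 1L) stop("all genes have zero pooled variance")
    zRef <- xRef[keep, , drop = FALSE] / s[keep]
    zNew <- xNew[keep, , drop = FALSE] / s[keep]
    if (is.null(penaltyC)) {
        d2 <- outer(colSums(zRef^2), colSums(zNew^2), `+`) -
            2 * crossprod(zRef, zNew)
        penaltyC <- 100 / stats::median(d2[d2 > 0])
    }
    if (penaltyC <= 0) stop("penaltyC must be positive")
    Z <- cbind(zRef, zNew)
    y <- rep(c(1, -1), c(ncol(zRef), ncol(zNew)))
    A <- rbind(Z, 1) * rep(y, each = nrow(Z) + 1L)   # columns y_i [z_i; 1]
    ## Lipschitz bound: V'' <= 2 C^(3/2), times the top squared singular
    ## value of A
    L <- 2 * penaltyC^1.5 * (svd(A, nu = 0, nv = 0)$d[1L])^2
    step <- 1 / L
    d <- nrow(Z)
    w <- rep(0, d); b <- 0
    vw <- w; vb <- b
    tPrev <- 1
    fPrev <- .dwdObjective(w, b, A, penaltyC)
    converged <- FALSE
    for (it in seq_len(maxIter)) {
        g <- .dwdGradient(vw, vb, A, penaltyC)
        wNew <- vw - step * g[seq_len(d)]
        nrm <- sqrt(sum(wNew^2))
        if (nrm > 1) wNew <- wNew / nrm
        bNew <- vb - step * g[d + 1L]
        tNew <- (1 + sqrt(1 + 4 * tPrev^2)) / 2
        vw <- wNew + ((tPrev - 1) / tNew) * (wNew - w)
        vb <- bNew + ((tPrev - 1) / tNew) * (bNew - b)
        w <- wNew; b <- bNew; tPrev <- tNew
        if (it %% 50L == 0L) {
            f <- .dwdObjective(w, b, A, penaltyC)
            if (abs(fPrev - f) <= tol * max(1, abs(f))) {
                converged <- TRUE
                fPrev <- f
                break
            }
            if (f > fPrev) { vw <- w; vb <- b; tPrev <- 1 }  # restart
            fPrev <- f
        }
    }
    if (!converged) {
        f1 <- .dwdObjective(w, b, A, penaltyC)
        g <- .dwdGradient(w, b, A, penaltyC)
        if (sqrt(sum(g^2)) * step > 1e-4)
            stop(sprintf(
                "DWD solver did not converge: objective %.8g, gradient-step norm %.3g",
                f1, sqrt(sum(g^2)) * step))
        fPrev <- f1
    }
    ## map back to the original gene scale: the adjustment happens in
    ## the standardized space, so a unit step along w there is a step
    ## along s * w in the original space — that image is the batch-bias
    ## axis used downstream (zero-variance genes keep weight 0)
    wFull <- rep(0, nrow(pooled))
    names(wFull) <- rownames(pooled)
    wFull[keep] <- w * s[keep]
    nrm <- sqrt(sum(wFull^2))
    if (nrm == 0) stop("degenerate DWD direction (all-zero)")
    wFull <- wFull / nrm
    sf <- rep(NA_real_, nrow(pooled)); names(sf) <- rownames(pooled)
    sf[keep] <- s[keep]
    new("DWDModel", direction = wFull, intercept = b,
        penaltyC = penaltyC, scaleFactors = sf,
        refMeanProjection = sum(rowMeans(xRef) * wFull),
        objective = fPrev)
}

#' Remove batch bias by shifting the new batch along the DWD direction
#'
#' Every new-batch sample x becomes
#' \code{x - ((muNew - muRef) . w) w}, so after adjustment the two batch
#' means have equal projection on the DWD direction while all components
#' orthogonal to w are untouched.  The reference batch is returned
#' unchanged.
#'
#' @param xRef,xNew the two batches fitted by \code{\link{fitDWD}}
#' @param model the fitted \linkS4class{DWDModel}
#' @return list with elements \code{ref} (identical to the input) and
#'   \code{new} (adjusted matrix, or \linkS4class{PlatformExpression} if
#'   the input was one)
#' @export
adjustBatches <- function(xRef, xNew, model) {
    mRef <- .asExprMatrix(xRef); mNew <- .asExprMatrix(xNew)
    w <- dwdDirection(model)
    if (!identical(rownames(mRef), names(w)) ||
        !identical(rownames(mNew), names(w)))
        stop("gene index mismatch between batches and DWD model")
    shift <- sum((rowMeans(mNew) - rowMeans(mRef)) * w) * w
    adj <- mNew - shift
    newOut <- if (is(xNew, "PlatformExpression"))
        PlatformExpression(adj, platform = platformName(xNew),
                           scale = exprScale(xNew)) else adj
    list(ref = xRef, new = newOut)
}

#' Principal-component / DWD diagnostic projections
#'
#' Coordinates of every pooled sample on the first three principal
#' components of the gene-centered pooled data, plus its projection on
#' the DWD direction as a fourth axis — the standard before/after
#' diagnostic view of a batch adjustment.
#'
#' @param xPooled gene x sample matrix (or
#'   \linkS4class{PlatformExpression}) of all samples
#' @param batchLabels character vector, one label per sample
#' @param model fitted \linkS4class{DWDModel}
#' @return data.frame with columns sample, batch, PC1, PC2, PC3, DWD
#' @export
pcDiagnostics <- function(xPooled, batchLabels, model) {
    m <- .asExprMatrix(xPooled)
    if (ncol(m) != length(batchLabels))
        stop("one batch label per pooled sample required")
    if (ncol(m) < 4L)
        stop("at least 4 samples needed for PC1-PC3 + DWD diagnostics")
    mc <- m - rowMeans(m)
    pc <- stats::prcomp(t(mc), center = FALSE, scale. = FALSE)
    scores <- pc$x[, seq_len(3L), drop = FALSE]
    if (ncol(scores) < 3L)
        scores <- cbind(scores, matrix(0, nrow(scores),
                                       3L - ncol(scores)))
    w <- dwdDirection(model)
    if (!identical(rownames(m), names(w)))
        stop("gene index mismatch between pooled matrix and DWD model")
    data.frame(sample = colnames(m), batch = batchLabels,
               PC1 = scores[, 1L], PC2 = scores[, 2L], PC3 = scores[, 3L],
               DWD = unname(drop(crossprod(mc, w))), row.names = NULL)
}
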