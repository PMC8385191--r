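## Independent brute-force oracles used to freeze expected values.
## Each is written as directly as possible from the definitions and
## shares no code with the package implementation.

## gene-wise KNN imputation: exhaustive distance computation, explicit
## weighted mean
bruteKnnImpute <- function(x, k) {
    out <- x
    for (g in seq_len(nrow(x))) {
        for (cc in seq_len(ncol(x))) {
            if (!is.na(x[g, cc])) next
            d <- rep(NA_real_, nrow(x))
            for (h in seq_len(nrow(x))) {
                if (h == g) next
                sh <- which(!is.na(x[g, ]) & !is.na(x[h, ]))
                if (!length(sh)) next
                d[h] <- sqrt(sum((x[g, sh] - x[h, sh])^2) / length(sh))
            }
            elig <- which(!is.na(d) & !is.na(x[, cc]))
            ord <- elig[order(d[elig], elig)]
            nb <- ord[seq_len(min(k, length(ord)))]
            if (any(d[nb] == 0)) {
                out[g, cc] <- mean(x[nb, cc][d[nb] == 0])
            } else {
                w <- 1 / d[nb]
                out[g, cc] <- sum(w * x[nb, cc]) / sum(w)
            }
        }
    }
    out
}

## per-sample loop background subtraction
bruteBackgroundSubtract <- function(v, ctlRows, floor = 1) {
    keep <- setdiff(rownames(v), ctlRows)
    out <- v[keep, , drop = FALSE]
    for (s in seq_len(ncol(v))) {
        bg <- mean(v[ctlRows, s])
        for (g in seq_len(nrow(out)))
            out[g, s] <- max(out[g, s] - bg, floor)
    }
    out
}

## per-sample geometric-mean division then log2
bruteHkNorm <- function(v, hk) {
    out <- v
    for (s in seq_len(ncol(v))) {
        gm <- prod(v[hk, s])^(1 / length(hk))
        out[, s] <- log2(v[, s] / gm)
    }
    out
}

## per-gene IQR scan for probe selection
bruteCollapse <- function(v, ann) {
    genes <- unique(toupper(ann$gene))
    pick <- character(0)
    for (g in genes) {
        probes <- ann$probe_id[toupper(ann$gene) == g]
        probes <- rownames(v)[rownames(v) %in% probes]
        iqrs <- sapply(probes, function(p) {
            q <- quantile(v[p, ], c(0.25, 0.75))
            q[2] - q[1]
        })
        pick <- c(pick, probes[which.max(iqrs)])
    }
    names(pick) <- genes
    pick
}

## rank (average ties) then Pearson
bruteSpearman <- function(x, y) {
    rx <- rank(x); ry <- rank(y)
    num <- sum((rx - mean(rx)) * (ry - mean(ry)))
    den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    if (den == 0) return(NA_real_)
    num / den
}

## direct kappa formula on a count table
bruteKappa <- function(tab) {
    n <- sum(tab)
    po <- sum(diag(tab)) / n
    pe <- 0
    for (i in seq_len(nrow(tab)))
        pe <- pe + sum(tab[i, ]) * sum(tab[, i]) / n^2
    (po - pe) / (1 - pe)
}

## hand-rolled product-limit estimator (censored tied with events stay
## at risk for the events at that time)
bruteKm <- function(times, events) {
    ts <- sort(unique(times))
    s <- 1
    out <- data.frame(time = numeric(), survival = numeric())
    for (t in ts) {
        atRisk <- sum(times >= t)
        d <- sum(times == t & events)
        if (atRisk > 0) s <- s * (1 - d / atRisk)
        out <- rbind(out, data.frame(time = t, survival = s))
    }
    out
}

## independent DWD objective: generic quasi-Newton solver (optim/BFGS)
## on a sphere parameterization of the direction, multi-start
dwdOracleObjective <- function(xRef, xNew, C) {
    pooled <- cbind(xRef, xNew)
    s <- apply(pooled, 1, sd)
    z <- pooled[s > 0, , drop = FALSE] / s[s > 0]
    y <- rep(c(1, -1), c(ncol(xRef), ncol(xNew)))
    loss <- function(par) {
        v <- par[-length(par)]; b <- par[length(par)]
        nv <- sqrt(sum(v^2))
        if (nv < 1e-12) return(1e10)
        w <- v / nv
        u <- y * (drop(crossprod(z, w)) + b)
        thr <- 1 / sqrt(C)
        sum(ifelse(u >= thr, 1 / u, 2 * sqrt(C) - C * u))
    }
    best <- Inf
    d <- nrow(z)
    set.seed(99)
    for (start in 1:8) {
        par0 <- c(rnorm(d), 0)
        fit <- optim(par0, loss, method = "BFGS",
                     control = list(maxit = 2000, reltol = 1e-14))
        best <- min(best, fit$value)
    }
    best
}

## small named matrix with dimnames, for quick fixtures
namedMatrix <- function(data, nr, nc, prefix = c("G", "S")) {
    matrix(data, nr, nc,
           dimnames = list(sprintf("%s%02d", prefix[1], seq_len(nr)),
                           sprintf("%s%02d", prefix[2], seq_len(nc))))
}
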