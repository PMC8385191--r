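## Synthetic paired two-platform cohorts with known ground truth.
##
## The generator emulates the study design the package targets: tumors
## drawn around subtype centroids on a log2 scale, a second platform
## related to the first by a per-gene affine distortion, optional
## probe-level expansion, matched normal tissues, and subtype-dependent
## exponential survival with uniform censoring.

## run expr under a fixed seed without disturbing the caller's RNG state
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(as.integer(seed))
    expr
}

.defaultIhcProbs <- function() {
    ## loosely mirrors the clinical composition of an nCounter-typed
    ## cohort: basal-like mostly HR-, HER2-enriched mostly HER2+,
    ## luminals mostly HR+/HER2-
    p <- rbind(
        "Basal-like"    = c(0.20, 0.17, 0.20, 0.34, 0.09),
        "HER2-enriched" = c(0.28, 0.07, 0.50, 0.11, 0.04),
        "LuminalA"      = c(0.13, 0.74, 0.07, 0.00, 0.06),
        "LuminalB"      = c(0.16, 0.80, 0.03, 0.00, 0.01),
        "Normal-like"   = c(0.10, 0.60, 0.10, 0.10, 0.10))
    colnames(p) <- IHC_PHENOTYPES
    p / rowSums(p)
}

#' Build a validated synthetic-cohort specification
#'
#' Defaults describe the emulated study: tumor subtype composition
#' Basal-like 23, HER2-enriched 28, LuminalA 55, LuminalB 37; 24 matched
#' normals; 50 genes; log2 noise SD 0.5; platform-B per-gene affine
#' distortion (scale in [0.8, 1.2], shift SD 0.5); per-subtype
#' exponential hazards calibrated so expected censoring over a uniform
#' [0, 11.6]-year censoring window is roughly 93/78/68/61 percent for
#' LuminalA/LuminalB/HER2-enriched/Basal-like.
#'
#' @param nPerSubtype named tumor counts per subtype
#' @param nGenes number of classifier genes
#' @param noiseSd per-gene Gaussian log2 noise SD
#' @param platformShiftSd SD of the platform-B additive per-gene shift
#' @param platformScaleRange range of the platform-B multiplicative
#'   per-gene factor
#' @param missingRate fraction of entries masked missing, in [0, 1)
#' @param probesPerGene probes per gene for the probe-level expansion
#' @param nNormalPairs matched normal samples to generate
#' @param hazard named per-subtype exponential event rates (1/years)
#' @param censorTimeMax upper bound of uniform censoring (years)
#' @param separation SD of centroid entries (log2 units)
#' @param ihcProbs subtype x phenotype probability matrix
#' @param seed integer seed; the same seed yields a bit-identical cohort
#' @return a \linkS4class{SyntheticCohortSpec}
#' @export
cohortSpec <- function(nPerSubtype = c("Basal-like" = 23,
                                       "HER2-enriched" = 28,
                                       "LuminalA" = 55, "LuminalB" = 37),
                       nGenes = 50, noiseSd = 0.5,
                       platformShiftSd = 0.5,
                       platformScaleRange = c(0.8, 1.2),
                       missingRate = 0, probesPerGene = 3,
                       nNormalPairs = 24,
                       hazard = c("Basal-like" = 0.095,
                                  "HER2-enriched" = 0.070,
                                  "LuminalA" = 0.013,
                                  "LuminalB" = 0.042,
                                  "Normal-like" = 0.010),
                       censorTimeMax = 11.6, separation = 1,
                       ihcProbs = .defaultIhcProbs(), seed = 1) {
    new("SyntheticCohortSpec", nPerSubtype = nPerSubtype,
        nGenes = nGenes, noiseSd = noiseSd,
        platformShiftSd = platformShiftSd,
        platformScaleRange = platformScaleRange,
        missingRate = missingRate, probesPerGene = probesPerGene,
        nNormalPairs = nNormalPairs, hazard = hazard,
        censorTimeMax = censorTimeMax, separation = separation,
        ihcProbs = ihcProbs, seed = seed)
}

#' Draw a synthetic subtype centroid table
#'
#' Centroid entries are iid Gaussian with SD \code{separation}; the draw
#' is rejected and retried until every pairwise Spearman correlation
#' between distinct centroids is below \code{maxRho}, so subtypes are
#' genuinely distinguishable by rank correlation.
#'
#' @param nGenes number of genes (>= 2)
#' @param subtypeLabels centroid column labels (default the five
#'   canonical subtypes)
#' @param separation SD of centroid entries (log2 units)
#' @param maxRho pairwise Spearman ceiling between distinct centroids
#' @param maxTries rejection-sampling cap before a hard error
#' @param seed integer seed
#' @return a complete \linkS4class{CentroidSet}
#' @export
makeCentroids <- function(nGenes = 50, subtypeLabels = PAM50_SUBTYPES,
                          separation = 1, maxRho = 0.3, maxTries = 100,
                          seed = 1) {
    if (nGenes < 2) stop("nGenes must be >= 2")
    .withSeed(seed, {
        for (try in seq_len(maxTries)) {
            v <- matrix(stats::rnorm(nGenes * length(subtypeLabels),
                                     sd = separation),
                        nGenes, length(subtypeLabels),
                        dimnames = list(sprintf("GENE%03d", seq_len(nGenes)),
                                        subtypeLabels))
            if (length(subtypeLabels) < 2L) return(CentroidSet(v))
            rho <- stats::cor(v, method = "spearman")
            if (max(abs(rho[upper.tri(rho)])) < maxRho)
                return(CentroidSet(v))
        }
        stop("could not draw centroids with pairwise |rho| < ", maxRho,
             " in ", maxTries, " tries; lower maxRho or raise nGenes")
    })
}

#' Generate a paired two-platform synthetic cohort
#'
#' Platform A samples are their subtype centroid plus iid Gaussian log2
#' noise; platform B applies a per-gene affine distortion
#' \code{a_g * A + b_g} (\code{a_g} uniform on the scale range,
#' \code{b_g} Gaussian) plus independent noise.  Entries are masked
#' missing at \code{missingRate}.  Survival times are exponential with
#' the subtype's hazard, censored uniformly on [0, censorTimeMax]; IHC
#' phenotypes are drawn from the spec's subtype-to-phenotype table.
#' Matched normals are appended when \code{nNormalPairs > 0}.
#'
#' @param spec a \linkS4class{SyntheticCohortSpec}
#' @param centroids a complete \linkS4class{CentroidSet} covering every
#'   subtype named in the spec
#' @return a \linkS4class{SyntheticCohort}
#' @export
generateCohort <- function(spec, centroids) {
    stopifnot(is(spec, "SyntheticCohortSpec"), is(centroids, "CentroidSet"))
    validObject(spec)
    cv <- centroidValues(centroids)
    if (anyNA(cv)) stop("centroids must be complete (no missing entries)")
    subs <- names(spec@nPerSubtype)[spec@nPerSubtype > 0]
    missing <- setdiff(subs, colnames(cv))
    if (length(missing))
        stop("centroid table lacks subtype(s): ",
             paste(missing, collapse = ", "))
    badHaz <- setdiff(subs, names(spec@hazard))
    if (length(badHaz))
        stop("no hazard for subtype(s): ", paste(badHaz, collapse = ", "))
    labels <- rep(subs, spec@nPerSubtype[subs])
    n <- length(labels)
    if (n == 0L) stop("spec requests zero tumor samples")
    ids <- sprintf("S%03d", seq_len(n))
    nG <- nrow(cv)
    .withSeed(spec@seed, {
        mu <- cv[, labels, drop = FALSE]
        a <- mu + matrix(stats::rnorm(nG * n, sd = spec@noiseSd), nG, n)
        scaleG <- stats::runif(nG, spec@platformScaleRange[1L],
                               spec@platformScaleRange[2L])
        shiftG <- stats::rnorm(nG, sd = spec@platformShiftSd)
        b <- a * scaleG + shiftG +
            matrix(stats::rnorm(nG * n, sd = spec@noiseSd), nG, n)
        colnames(a) <- colnames(b) <- ids
        rownames(a) <- rownames(b) <- rownames(cv)
        if (spec@missingRate > 0) {
            a[matrix(stats::runif(nG * n) < spec@missingRate, nG, n)] <- NA
            b[matrix(stats::runif(nG * n) < spec@missingRate, nG, n)] <- NA
        }
        ## survival: exponential event time vs uniform censoring
        rate <- spec@hazard[labels]
        tEvent <- ifelse(rate > 0, stats::rexp(n, pmax(rate, 1e-12)), Inf)
        tCens <- stats::runif(n, 0, spec@censorTimeMax)
        death <- tEvent <= tCens
        time <- pmin(tEvent, tCens)
        ## breast-cancer-specific composite is a thinned subset of deaths
        bc <- death & stats::runif(n) < 0.73
        ## IHC phenotype per subtype
        pheno <- vapply(labels, function(s)
            sample(colnames(spec@ihcProbs), 1L,
                   prob = spec@ihcProbs[s, ]), character(1))
        hr <- ifelse(pheno == "missing", "missing",
                     ifelse(substr(pheno, 1, 3) == "HR+",
                            "positive", "negative"))
        her2 <- ifelse(pheno == "missing", "missing",
                       ifelse(grepl("HER2\\+$", pheno),
                              "positive", "negative"))
        clinical <- data.frame(sample_id = ids, hr_status = hr,
                               her2_status = her2, followup_time = time,
                               event_death = death, event_bc = bc,
                               row.names = NULL)
        cohort <- new("SyntheticCohort",
                      exprA = PlatformExpression(a, platform = "ncounter",
                                                 scale = "log2"),
                      exprB = PlatformExpression(b, platform = "microarray",
                                                 scale = "log2"),
                      trueLabels = stats::setNames(labels, ids),
                      clinical = clinical, centroids = centroids,
                      normalExpr = NULL,
                      normalPairs = data.frame(normal_id = character(),
                                               tumor_id = character()))
        if (spec@nNormalPairs > 0)
            cohort <- generateNormalPairs(cohort, spec)
        cohort
    })
}

#' Append matched normal-tissue samples to a synthetic cohort
#'
#' Normals are drawn around the Normal-like centroid with the spec's
#' noise model, each linked to one tumor sample of the cohort.
#'
#' @param cohort a \linkS4class{SyntheticCohort}
#' @param spec the \linkS4class{SyntheticCohortSpec} (uses
#'   \code{nNormalPairs}, \code{noiseSd}, \code{seed})
#' @return the cohort with \code{normalExpr} and \code{normalPairs}
#'   filled in
#' @export
generateNormalPairs <- function(cohort, spec) {
    cv <- centroidValues(cohort@centroids)
    if (!"Normal-like" %in% colnames(cv))
        stop("centroid table has no Normal-like centroid")
    k <- spec@nNormalPairs
    if (k < 1) return(cohort)
    tumors <- names(cohort@trueLabels)
    if (k > length(tumors))
        stop("more normal pairs requested than tumors available")
    .withSeed(spec@seed + 1L, {
        nG <- nrow(cv)
        nm <- cv[, "Normal-like"] +
            matrix(stats::rnorm(nG * k, sd = spec@noiseSd), nG, k)
        dimnames(nm) <- list(rownames(cv), sprintf("N%03d", seq_len(k)))
        cohort@normalExpr <- nm
        cohort@normalPairs <- data.frame(normal_id = colnames(nm),
                                         tumor_id = tumors[seq_len(k)],
                                         row.names = NULL)
        cohort
    })
}

#' Expand a gene-level matrix into a probe-level matrix
#'
#' Each gene emits \code{probesPerGene} probe rows: the gene value plus
#' a probe-specific offset and Gaussian noise.  One designated probe per
#' gene draws its noise SD from \code{maxSdRange} and the rest from
#' \code{otherSdRange}, so exactly one probe per gene has maximal IQR in
#' expectation; the designated probe IDs are returned as ground truth.
#' With \code{probesPerGene = 1} the input passes through unchanged (one
#' probe per gene, no noise), so collapsing recovers the input exactly.
#'
#' @param expr gene-level log2 matrix or
#'   \linkS4class{PlatformExpression}
#' @param probesPerGene probes emitted per gene (>= 1)
#' @param maxSdRange noise-SD range of the designated high-variance
#'   probe
#' @param otherSdRange noise-SD range of the remaining probes
#' @param offsetSd SD of the per-probe additive offset
#' @param seed integer seed
#' @return list: \code{probes} (probe-level
#'   \linkS4class{PlatformExpression}), \code{annotation} (data.frame
#'   probe_id, gene), \code{truth} (named character, the max-SD probe
#'   per gene)
#' @export
expandToProbes <- function(expr, probesPerGene = 3,
                           maxSdRange = c(1.2, 1.8),
                           otherSdRange = c(0.05, 0.3),
                           offsetSd = 0.3, seed = 1) {
    if (probesPerGene < 1) stop("probesPerGene must be >= 1")
    m <- .asExprMatrix(expr)
    gn <- rownames(m); ns <- ncol(m)
    probeIds <- as.vector(t(outer(gn, seq_len(probesPerGene),
                                  function(g, j) paste0(g, "_p", j))))
    ann <- data.frame(probe_id = probeIds,
                      gene = rep(gn, each = probesPerGene))
    .withSeed(seed, {
        out <- matrix(NA_real_, length(probeIds), ns,
                      dimnames = list(probeIds, colnames(m)))
        truth <- character(length(gn)); names(truth) <- gn
        for (i in seq_along(gn)) {
            if (probesPerGene == 1L) {
                out[paste0(gn[i], "_p1"), ] <- m[i, ]
                truth[i] <- paste0(gn[i], "_p1")
                next
            }
            big <- sample.int(probesPerGene, 1L)
            truth[i] <- paste0(gn[i], "_p", big)
            for (j in seq_len(probesPerGene)) {
                sdj <- if (j == big)
                    stats::runif(1, maxSdRange[1L], maxSdRange[2L])
                else stats::runif(1, otherSdRange[1L], otherSdRange[2L])
                out[paste0(gn[i], "_p", j), ] <-
                    m[i, ] + stats::rnorm(1, sd = offsetSd) +
                    stats::rnorm(ns, sd = sdj)
            }
        }
        plat <- if (is(expr, "PlatformExpression")) platformName(expr)
                else "microarray"
        list(probes = PlatformExpression(out, platform = plat,
                                         scale = "log2"),
             annotation = ann, truth = truth)
    })
}

#' Emulate raw digital counts (with control rows) from log2 abundances
#'
#' Builds a counts-scale matrix the digital-count preprocessing chain
#' can be tested on end-to-end: gene counts are
#' \code{content_s * 2^(x + scaleLog2)} plus an additive background,
#' housekeeper rows carry constant true levels times the same per-sample
#' content factor, and negative-control rows carry background only.
#' With \code{poisson = FALSE} counts are exact expectations, so
#' background subtraction + housekeeping normalization recovers the
#' input up to a per-gene constant; with \code{poisson = TRUE} counts
#' are Poisson draws.
#'
#' @param expr gene-level log2 matrix or
#'   \linkS4class{PlatformExpression} of true relative abundances
#' @param scaleLog2 log2 sequencing-depth offset added to every gene
#' @param contentSd SD (log2) of the per-sample content factor
#' @param backgroundMean mean background count added to every row
#' @param nNegativeControls number of negative-control rows
#' @param housekeeperLog2 named log2 levels of the housekeeper rows
#' @param poisson draw Poisson counts (TRUE) or use exact expectations
#' @param seed integer seed
#' @return list: \code{counts} (counts-scale
#'   \linkS4class{PlatformExpression} including housekeeper and NEG_*
#'   rows), \code{negativeControls} (row IDs), \code{housekeepers}
#' @export
emulateCounts <- function(expr, scaleLog2 = 9, contentSd = 0.25,
                          backgroundMean = 10, nNegativeControls = 8,
                          housekeeperLog2 = stats::setNames(
                              c(11, 8, 10.5, 7, 8.5, 10),
                              DEFAULT_HOUSEKEEPERS),
                          poisson = TRUE, seed = 1) {
    m <- .asExprMatrix(expr)
    if (anyNA(m)) stop("emulateCounts needs a complete matrix")
    ns <- ncol(m)
    negIds <- sprintf("NEG_%d", seq_len(nNegativeControls))
    .withSeed(seed, {
        content <- 2^stats::rnorm(ns, sd = contentSd)
        lam <- rbind(
            sweep(2^(m + scaleLog2), 2L, content, `*`),
            outer(2^housekeeperLog2, content),
            matrix(0, nNegativeControls, ns)) + backgroundMean
        rownames(lam) <- c(rownames(m), names(housekeeperLog2), negIds)
        colnames(lam) <- colnames(m)
        counts <- if (poisson)
            matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam),
                   dimnames = dimnames(lam))
        else lam
        list(counts = PlatformExpression(counts, platform = "ncounter",
                                         scale = "counts"),
             negativeControls = negIds,
             housekeepers = names(housekeeperLog2))
    })
}
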