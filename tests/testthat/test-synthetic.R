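test_that("synthetic centroids are deterministic and rank-separated", {
    a <- makeCentroids(nGenes = 50, seed = 19)
    b <- makeCentroids(nGenes = 50, seed = 19)
    expect_identical(centroidValues(a), centroidValues(b))
    rho <- cor(centroidValues(a), method = "spearman")
    expect_lt(max(abs(rho[upper.tri(rho)])), 0.3)
    ## single-subtype centroid has no separation constraint
    one <- makeCentroids(nGenes = 10, subtypeLabels = "LuminalA", seed = 1)
    expect_identical(dim(one), c(10L, 1L))
    expect_error(makeCentroids(nGenes = 1), "nGenes")
    ## infeasible separation errors after bounded retries
    expect_error(makeCentroids(nGenes = 3, maxRho = 1e-6, maxTries = 5),
                 "tries")
})

test_that("cohorts are bit-identical under a seed and vary across seeds", {
    cen <- makeCentroids(seed = 4)
    spec <- cohortSpec(seed = 23, missingRate = 0.05)
    c1 <- generateCohort(spec, cen)
    c2 <- generateCohort(spec, cen)
    expect_identical(exprValues(c1@exprA), exprValues(c2@exprA))
    expect_identical(exprValues(c1@exprB), exprValues(c2@exprB))
    expect_identical(c1@clinical, c2@clinical)
    expect_identical(c1@normalExpr, c2@normalExpr)
    c3 <- generateCohort(cohortSpec(seed = 24, missingRate = 0.05), cen)
    expect_false(identical(exprValues(c1@exprA), exprValues(c3@exprA)))
    ## the generator does not disturb the caller's RNG stream
    set.seed(77); before <- rnorm(1)
    set.seed(77); invisible(generateCohort(spec, cen)); after <- rnorm(1)
    expect_identical(before, after)
})

test_that("cohort structure is internally consistent", {
    cen <- makeCentroids(seed = 4)
    spec <- cohortSpec(seed = 23, missingRate = 0.05)
    coh <- generateCohort(spec, cen)
    a <- exprValues(coh@exprA); b <- exprValues(coh@exprB)
    expect_identical(colnames(a), colnames(b))
    expect_identical(colnames(a), names(coh@trueLabels))
    expect_identical(coh@clinical$sample_id, colnames(a))
    expect_identical(platformName(coh@exprA), "ncounter")
    expect_identical(platformName(coh@exprB), "microarray")
    expect_gt(sum(is.na(a)), 0)   # missingness applied
    expect_identical(nrow(coh@normalPairs), 24L)
    expect_true(all(coh@normalPairs$tumor_id %in% colnames(a)))
    expect_identical(colnames(coh@normalExpr), coh@normalPairs$normal_id)
    tab <- table(coh@trueLabels)
    expect_identical(as.vector(tab[names(spec@nPerSubtype)]),
                     as.integer(spec@nPerSubtype))
    expect_true(all(coh@clinical$followup_time >= 0))
    expect_true(all(coh@clinical$followup_time <= spec@censorTimeMax |
                    coh@clinical$event_death))
})

test_that("classification recovers true labels at stated noise levels", {
    cen <- makeCentroids(seed = 4)
    ## noiseless limit: exact recovery on both platforms
    c0 <- generateCohort(cohortSpec(noiseSd = 0, platformShiftSd = 0,
                                    platformScaleRange = c(1, 1),
                                    nNormalPairs = 0, seed = 31), cen)
    for (m in list(exprValues(c0@exprA), exprValues(c0@exprB))) {
        calls <- suppressWarnings(suppressMessages(
            classifyCohort(m, cen, "SSP5", checkCentering = FALSE)))
        expect_identical(unname(callLabels(calls)), unname(c0@trueLabels))
    }
    ## noise 0.5, 50 per subtype: >= 95% recovery on platform A
    spec <- cohortSpec(nPerSubtype = setNames(rep(50, 4),
                                              PAM50_SUBTYPES[1:4]),
                       noiseSd = 0.5, nNormalPairs = 0, seed = 37)
    coh <- generateCohort(spec, cen)
    calls <- suppressWarnings(suppressMessages(
        classifyCohort(coh@exprA, cen, "SSP5", checkCentering = FALSE)))
    expect_gte(mean(callLabels(calls) == coh@trueLabels), 0.95)
})

test_that("probe expansion is deterministic, annotated, and collapsible", {
    cen <- makeCentroids(seed = 4)
    coh <- generateCohort(cohortSpec(nNormalPairs = 0, seed = 41), cen)
    b <- coh@exprB
    ## probesPerGene = 1 round-trips exactly through collapseProbes
    ex1 <- expandToProbes(b, probesPerGene = 1, seed = 5)
    back <- collapseProbes(ex1$probes, ex1$annotation)
    expect_equal(exprValues(back), exprValues(b)[rownames(exprValues(back)), ],
                 tolerance = 1e-12)
    ## determinism under seed
    ex2 <- expandToProbes(b, probesPerGene = 3, seed = 5)
    ex3 <- expandToProbes(b, probesPerGene = 3, seed = 5)
    expect_identical(exprValues(ex2$probes), exprValues(ex3$probes))
    ## the designated high-variance probe is selected for >= 95% of genes
    sel <- suppressMessages(collapseProbes(ex2$probes, ex2$annotation))
    iqr <- apply(exprValues(ex2$probes), 1, function(r)
        diff(quantile(r, c(0.25, 0.75))))
    picked <- vapply(rownames(exprValues(sel)), function(g) {
        probes <- ex2$annotation$probe_id[toupper(ex2$annotation$gene) == g]
        probes[which.max(iqr[probes])]
    }, character(1))
    expect_gte(mean(picked == ex2$truth[names(picked)]), 0.95)
})

test_that("matched normals are Normal-like by construction", {
    cen <- makeCentroids(seed = 4)
    spec <- cohortSpec(noiseSd = 0, seed = 43)
    coh <- generateCohort(spec, cen)
    calls <- suppressWarnings(suppressMessages(
        classifyCohort(coh@normalExpr, cen, "SSP5",
                       checkCentering = FALSE)))
    expect_true(all(callLabels(calls) == "Normal-like"))
    ## pairing plumbing round-trips through normalPairSummary
    s <- normalPairSummary(callLabels(calls), coh@trueLabels,
                           coh@normalPairs)
    expect_identical(s$nNormalLike, 24L)
    ## missing Normal-like centroid is a hard error
    cen4 <- cen[, PAM50_SUBTYPES[1:4]]
    coh4 <- generateCohort(cohortSpec(nNormalPairs = 0, seed = 2), cen4)
    expect_error(generateNormalPairs(coh4, spec), "Normal-like")
})

test_that("emulated digital counts run the preprocessing chain end-to-end", {
    cen <- makeCentroids(nGenes = 30, seed = 8)
    coh <- generateCohort(cohortSpec(nPerSubtype = c("LuminalA" = 6,
                                                     "Basal-like" = 6),
                                     nGenes = 30, nNormalPairs = 0,
                                     seed = 47), cen)
    truth <- exprValues(coh@exprA)
    ## exact expectations: pipeline recovers input up to per-gene constants
    em <- emulateCounts(truth, poisson = FALSE, seed = 3)
    bs <- backgroundSubtract(em$counts, em$negativeControls)
    hk <- housekeepingNormalize(bs, em$housekeepers)
    rec <- exprValues(hk)[rownames(truth), ]
    resid <- rec - truth
    expect_lt(max(abs(sweep(resid, 1, rowMeans(resid)))), 1e-6)
    ## Poisson mode still classifies correctly after the chain
    emp <- emulateCounts(truth, poisson = TRUE, seed = 3)
    hkp <- housekeepingNormalize(
        backgroundSubtract(emp$counts, emp$negativeControls),
        emp$housekeepers)
    calls <- suppressWarnings(suppressMessages(classifyCohort(
        exprValues(hkp)[rownames(truth), ], cen, "SSP5",
        checkCentering = FALSE, minGenes = 25)))
    expect_gte(mean(callLabels(calls) == coh@trueLabels), 0.9)
})

test_that("cohort spec validation rejects impossible settings", {
    expect_error(cohortSpec(missingRate = 1), "missingRate")
    expect_error(cohortSpec(noiseSd = -1), "noiseSd")
    expect_error(cohortSpec(probesPerGene = 0), "probesPerGene")
    cen <- makeCentroids(seed = 1)
    expect_error(generateCohort(cohortSpec(nPerSubtype = c(Foo = 5)), cen),
                 "Foo")
    expect_error(generateCohort(
        cohortSpec(nPerSubtype = c("LuminalA" = 0), nNormalPairs = 0), cen),
        "zero tumor")
})

test_that("cross-platform kappa falls as the platform shift grows", {
    cen <- makeCentroids(seed = 5)
    kap <- function(shiftSd, seed) {
        spec <- cohortSpec(nPerSubtype = setNames(rep(15, 4),
                                                  PAM50_SUBTYPES[1:4]),
                           platformShiftSd = shiftSd, nNormalPairs = 0,
                           seed = seed)
        coh <- generateCohort(spec, cen)
        a <- suppressWarnings(suppressMessages(callLabels(
            classifyCohort(coh@exprA, cen, "SSP2",
                           checkCentering = FALSE))))
        b <- suppressWarnings(suppressMessages(callLabels(
            classifyCohort(coh@exprB, cen, "SSP2",
                           checkCentering = FALSE))))
        cohensKappa(confusionMatrix(a, b))@kappa
    }
    grid <- c(0, 1.5, 3)
    meanK <- sapply(grid, function(s)
        mean(sapply(1:20, function(r) kap(s, 1000 + r))))
    ## monotone (in expectation) over the 3-point grid, 20 replicates
    expect_gte(meanK[1], meanK[2])
    expect_gt(meanK[2], meanK[3])
    ## and the strong-shift condition visibly degrades agreement
    expect_lt(meanK[3], 0.95)
})
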