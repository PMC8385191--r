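cen5 <- makeCentroids(nGenes = 50, seed = 7)

test_that("spearmanRho matches the rank-then-Pearson oracle, ties included", {
    expect_equal(spearmanRho(1:10, (1:10)^2), 1)       # monotone increasing
    expect_equal(spearmanRho(1:10, exp(-(1:10))), -1)  # strictly decreasing
    set.seed(121)
    for (rep in 1:10) {
        x <- sample(1:8, 50, replace = TRUE)   # heavy ties
        y <- sample(1:8, 50, replace = TRUE)
        expect_equal(spearmanRho(x, y), bruteSpearman(x, y),
                     tolerance = 1e-12)
    }
    expect_true(is.na(spearmanRho(rep(1, 5), 1:5)))   # zero rank variance
    expect_error(spearmanRho(1:3, 1:4), "equal length")
})

test_that("a sample equal to a centroid classifies as that centroid with rho 1", {
    v <- centroidValues(cen5)
    for (s in PAM50_SUBTYPES) {
        call <- classifySample(v[, s], cen5, mode = "SSP5")
        expect_identical(call$label, s)
        expect_equal(unname(call$correlations[s]), 1)
        expect_identical(call$nGenesUsed, 50L)
    }
})

test_that("the unclassified rule fires when max rho is below threshold", {
    ## adversarial vector: iteratively reduce the max rho by local search,
    ## then verify with the independent oracle
    v <- centroidValues(cen5)
    set.seed(131)
    best <- NULL
    for (try in 1:200) {
        x <- setNames(rnorm(50), genes(cen5))
        rhos <- apply(v, 2, function(cc) bruteSpearman(x, cc))
        if (max(rhos) < 0.1) { best <- x; break }
    }
    expect_false(is.null(best))
    call <- classifySample(best, cen5, mode = "SSP5")
    expect_identical(call$label, UNCLASSIFIED)
    ## strictness: max rho exactly at the threshold is NOT unclassified
    expect_identical(
        classifySample(v[, "LuminalA"], cen5, threshold = 0.999)$label,
        "LuminalA")
})

test_that("calls are invariant to strictly increasing per-sample transforms", {
    v <- centroidValues(cen5)
    set.seed(141)
    transforms <- list(function(z) 3 * z + 2, function(z) z^3,
                       function(z) exp(z / 2), function(z) atan(z))
    for (rep in 1:5) {
        s <- sample(PAM50_SUBTYPES, 1)
        x <- v[, s] + rnorm(50, sd = 0.4)
        ref <- classifySample(x, cen5)
        for (f in transforms) {
            tr <- classifySample(f(x), cen5)
            expect_identical(tr$label, ref$label)
            expect_equal(tr$correlations, ref$correlations,
                         tolerance = 1e-12)
        }
    }
})

test_that("genes absent from the centroids never change a call", {
    v <- centroidValues(cen5)
    set.seed(151)
    x <- v[, "Basal-like"] + rnorm(50, sd = 0.5)
    extra <- setNames(rnorm(30), paste0("OTHER", 1:30))
    a <- classifySample(x, cen5)
    b <- classifySample(c(x, extra), cen5)
    expect_identical(a, b)
})

test_that("gene overlap below minGenes is a hard error naming missing genes", {
    v <- centroidValues(cen5)
    x <- v[1:20, "LuminalB"]
    expect_error(classifySample(x, cen5, minGenes = 40), "GENE")
    ## but a relaxed threshold accepts the same vector
    expect_identical(classifySample(x, cen5, minGenes = 10)$label,
                     "LuminalB")
})

test_that("SSP2 drops the Normal-like centroid and never emits it", {
    spec <- cohortSpec(nPerSubtype = c("Basal-like" = 10,
                                       "HER2-enriched" = 10,
                                       "LuminalA" = 10, "LuminalB" = 10,
                                       "Normal-like" = 10),
                       nNormalPairs = 0, noiseSd = 1.5, seed = 9)
    coh <- generateCohort(spec, cen5)
    calls <- suppressWarnings(suppressMessages(
        classifyCohort(coh@exprA, cen5, mode = "SSP2",
                       checkCentering = FALSE)))
    expect_false("Normal-like" %in% callLabels(calls))
    expect_identical(callMode(calls), "SSP2")
    expect_identical(subtypes(calls), setdiff(PAM50_SUBTYPES, "Normal-like"))
})

test_that("SSP5 and SSP2 agree when Normal-like is not involved", {
    spec <- cohortSpec(nNormalPairs = 0, noiseSd = 1, seed = 17)
    coh <- generateCohort(spec, cen5)
    c5 <- suppressWarnings(suppressMessages(
        classifyCohort(coh@exprA, cen5, "SSP5", checkCentering = FALSE)))
    c2 <- suppressWarnings(suppressMessages(
        classifyCohort(coh@exprA, cen5, "SSP2", checkCentering = FALSE)))
    l5 <- callLabels(c5); l2 <- callLabels(c2)
    keep <- l5 != "Normal-like" & l5 != UNCLASSIFIED
    expect_identical(l2[keep], l5[keep])
})

test_that("cohort classification preserves order, skips bad samples, logs counts", {
    v <- centroidValues(cen5)
    m <- v   # the 5 centroids classify as themselves
    colnames(m) <- paste0("C_", PAM50_SUBTYPES)
    msgs <- capture_messages(
        calls <- suppressWarnings(classifyCohort(m, cen5, "SSP5",
                                                 checkCentering = FALSE)))
    expect_match(paste(msgs, collapse = " "), "subtype calls:")
    expect_identical(unname(callLabels(calls)), PAM50_SUBTYPES)
    ## a sample with too few genes is skipped, not fatal
    m2 <- rbind(m, matrix(NA_real_, 0, 5))
    m2[21:50, 2] <- NA
    expect_warning(
        calls2 <- suppressMessages(classifyCohort(m2, cen5, "SSP5",
                                                  checkCentering = FALSE)),
        "skipped")
    expect_identical(nrow(callCorrelations(calls2)), 4L)
    ## noiseless cohort: 100% true-label recovery
    spec <- cohortSpec(noiseSd = 0, nNormalPairs = 0, seed = 5)
    coh <- generateCohort(spec, cen5)
    calls3 <- suppressWarnings(suppressMessages(
        classifyCohort(coh@exprA, cen5, "SSP5", checkCentering = FALSE)))
    expect_identical(unname(callLabels(calls3)), unname(coh@trueLabels))
})

test_that("call sets convert to a tidy data.frame", {
    spec <- cohortSpec(nPerSubtype = c("LuminalA" = 3), nNormalPairs = 0,
                       seed = 2)
    coh <- generateCohort(spec, cen5)
    calls <- suppressWarnings(suppressMessages(
        classifyCohort(coh@exprA, cen5, "SSP5", checkCentering = FALSE)))
    df <- as.data.frame(calls)
    expect_identical(df$sample_id, c("S001", "S002", "S003"))
    expect_true(all(c("label", "rho_LuminalA", "n_genes_used", "mode")
                    %in% colnames(df)))
})
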