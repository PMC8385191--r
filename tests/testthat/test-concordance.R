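test_that("confusion matrix tallies paired calls and books unclassified pairs", {
    ids <- sprintf("P%02d", 1:6)
    ref <- setNames(c("LuminalA", "LuminalA", "Basal-like", "LuminalB",
                      "LuminalA", "HER2-enriched"), ids)
    test <- setNames(c("LuminalA", "LuminalB", "Basal-like", "LuminalB",
                       UNCLASSIFIED, "HER2-enriched"), ids)
    res <- confusionMatrix(ref, test)
    expect_identical(res@nPairsTotal, 6L)
    expect_identical(res@nUnclassifiedExcluded, 1L)
    expect_identical(sum(res@table), 5L)
    expect_identical(res@table["LuminalB", "LuminalA"], 1L)
    ## identical call lists give a diagonal matrix
    resId <- confusionMatrix(ref, ref)
    expect_identical(sum(resId@table), sum(diag(resId@table)))
    ## unpaired sample is a hard error listing the ID
    expect_error(confusionMatrix(ref[-1], test), "P01")
})

test_that("random paired labels match a brute-force tally", {
    set.seed(161)
    classes <- PAM50_SUBTYPES[1:4]
    for (rep in 1:5) {
        ids <- sprintf("Q%03d", 1:60)
        ref <- setNames(sample(c(classes, UNCLASSIFIED), 60, TRUE,
                               prob = c(rep(0.23, 4), 0.08)), ids)
        test <- setNames(sample(c(classes, UNCLASSIFIED), 60, TRUE,
                                prob = c(rep(0.23, 4), 0.08)), ids)
        res <- confusionMatrix(ref, test, classes = classes)
        for (i in classes) for (j in classes)
            expect_identical(res@table[i, j],
                             sum(test == i & ref == j))
        expect_identical(res@nUnclassifiedExcluded,
                         sum(ref == UNCLASSIFIED | test == UNCLASSIFIED))
    }
})

test_that("per-class accuracy divides diagonal cells by reference column totals", {
    tab <- loadFixture("T4")$counts
    res <- perClassAccuracy(concordanceFromTable(tab, 1L))
    acc <- res@perClassAccuracy
    expect_identical(acc$numerator, c(3L, 13L, 5L, 20L))
    expect_identical(acc$denominator, c(7L, 16L, 20L, 20L))
    expect_equal(acc$proportion, c(3/7, 13/16, 5/20, 1))
    ## diagonal-only matrix: every defined accuracy is 1, empty class NA
    d <- diag(c(2L, 0L, 5L)); dimnames(d) <- list(letters[1:3], letters[1:3])
    accD <- perClassAccuracy(concordanceFromTable(d))@perClassAccuracy
    expect_equal(accD$proportion, c(1, NA, 1))
})

test_that("overall agreement is the diagonal proportion over classified pairs", {
    res <- overallAgreement(concordanceFromTable(loadFixture("T4")$counts, 1L))
    expect_identical(res@agreementCount, 41)
    expect_equal(res@agreementProportion, 41 / 63)
    z <- matrix(c(0L, 2L, 3L, 0L), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
    expect_identical(overallAgreement(concordanceFromTable(z))@agreementCount, 0)
    e <- matrix(0L, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
    expect_error(overallAgreement(concordanceFromTable(e)), "empty")
})

test_that("Cohen's kappa follows the standard unweighted formula", {
    ## perfect agreement
    d <- diag(c(5L, 7L, 9L)); dimnames(d) <- list(letters[1:3], letters[1:3])
    expect_equal(cohensKappa(concordanceFromTable(d))@kappa, 1)
    ## independence: p_o == p_e gives kappa 0
    ind <- outer(c(2L, 2L), c(3L, 3L))
    dimnames(ind) <- list(c("a", "b"), c("a", "b"))
    expect_equal(cohensKappa(concordanceFromTable(ind))@kappa, 0,
                 tolerance = 1e-14)
    ## random tables match the independent formula oracle
    set.seed(171)
    for (rep in 1:10) {
        t <- matrix(rpois(16, 6), 4, 4,
                    dimnames = list(PAM50_SUBTYPES[1:4], PAM50_SUBTYPES[1:4]))
        storage.mode(t) <- "integer"
        expect_equal(cohensKappa(concordanceFromTable(t))@kappa,
                     bruteKappa(t), tolerance = 1e-12)
    }
    ## degenerate marginals are rejected
    one <- matrix(5L, 1, 1, dimnames = list("a", "a"))
    expect_error(cohensKappa(concordanceFromTable(one)), "2 classes")
})

test_that("kappa formula agrees with a resampling estimate on a random table", {
    ## draw paired labels with the table's joint distribution; the
    ## kappa of a large resample converges to the formula value
    tab <- loadFixture("T4")$counts
    set.seed(181)
    joint <- tab / sum(tab)
    idx <- sample(length(joint), 2e4, TRUE, prob = as.vector(joint))
    big <- matrix(tabulate(idx, length(joint)), nrow(tab), ncol(tab),
                  dimnames = dimnames(tab))
    storage.mode(big) <- "integer"
    k1 <- cohensKappa(concordanceFromTable(tab))@kappa
    k2 <- cohensKappa(concordanceFromTable(big))@kappa
    expect_equal(k1, k2, tolerance = 0.03)   # Monte-Carlo error
})

test_that("agreement statistics are invariant to simultaneous class permutation", {
    tab <- loadFixture("T4")$counts
    perm <- c(3, 1, 4, 2)
    p <- tab[perm, perm]
    a <- cohensKappa(overallAgreement(concordanceFromTable(tab, 1L)))
    b <- cohensKappa(overallAgreement(concordanceFromTable(p, 1L)))
    expect_equal(a@agreementProportion, b@agreementProportion)
    expect_equal(a@kappa, b@kappa, tolerance = 1e-14)
})

test_that("IHC crosstab counts calls against phenotypes with explicit missing", {
    clin <- data.frame(
        sample_id = sprintf("S%02d", 1:6),
        hr_status = c("positive", "positive", "negative", "negative",
                      "missing", "positive"),
        her2_status = c("positive", "negative", "positive", "negative",
                        "negative", "missing"),
        followup_time = rep(1, 6), event_death = FALSE, event_bc = FALSE)
    calls <- setNames(c("LuminalB", "LuminalA", "HER2-enriched",
                        "Basal-like", "LuminalA", "LuminalA"),
                      clin$sample_id)
    ct <- ihcCrosstab(calls, clin)
    expect_identical(ct$counts["HR+/HER2+", "LuminalB"], 1L)
    expect_identical(ct$counts["missing", "LuminalA"], 2L)
    expect_equal(ct$fractions["HR+/HER2-", "LuminalA"], 1)  # 1/1 non-missing
    expect_error(ihcCrosstab(calls[-1], clin), "S01")
    ## all-missing IHC: fractions undefined
    clin2 <- clin; clin2$hr_status <- "missing"
    ct2 <- ihcCrosstab(calls, clin2)
    expect_true(all(is.na(ct2$fractions)))
})

test_that("matched-normal summary reports normal-like and tumor-matching counts", {
    t2 <- loadFixture("T2")$counts
    pairs <- expandPairTable(t2)
    s <- normalPairSummary(pairs$normal, pairs$tumor, pairs$pairs)
    expect_identical(s$nNormals, 24L)
    expect_identical(s$nNormalLike, 16L)
    expect_equal(s$fracNormalLike, 16 / 24)
    expect_identical(s$nNotNormalLike, 8L)
    expect_identical(s$nMatchingTumor, 1L)
    expect_equal(s$fracMatchingTumor, 1 / 8)
    ## all normals Normal-like: part (b) is vacuous (NA)
    nl <- setNames(rep("Normal-like", 3), c("N1", "N2", "N3"))
    tl <- setNames(c("LuminalA", "LuminalB", "Basal-like"),
                   c("T1", "T2", "T3"))
    pr <- data.frame(normal_id = names(nl), tumor_id = names(tl))
    s2 <- normalPairSummary(nl, tl, pr)
    expect_identical(s2$nNotNormalLike, 0L)
    expect_true(is.na(s2$fracMatchingTumor))
    expect_error(normalPairSummary(nl, tl,
                                   data.frame(normal_id = "N9",
                                              tumor_id = "T1")), "N9")
})
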