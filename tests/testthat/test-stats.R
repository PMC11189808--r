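test_that("Grubbs statistic flags the most extreme point", {
    g <- grubbsStatistic(c(1, 1, 1, 5))
    expect_equal(g$G, 1.5)   # sd = 2, |5 - 2| / 2
    expect_identical(g$index, 4L)

    sym <- grubbsStatistic(c(-1, 0, 1))
    expect_equal(sym$G, 1)
    expect_identical(sym$index, 1L)  # tie broken to the first extreme

    expect_error(grubbsStatistic(c(2, 2, 2)), "non-zero variance")
    expect_error(grubbsStatistic(c(1, 2)), "n >= 3")
})

test_that("Grubbs critical value matches the t-quantile formula", {
    for (n in c(5L, 10L, 25L)) for (a in c(0.05, 0.01)) {
        tq <- qt(1 - a / (2 * n), n - 2)
        expect_equal(grubbsCritical(n, a),
                     (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2)),
                     tolerance = 1e-6)
    }
    gc <- vapply(4:30, grubbsCritical, numeric(1L), alpha = 0.05)
    expect_true(all(diff(gc) > 0))  # increasing in n at fixed alpha
    # alpha -> 0 limit is (n-1)/sqrt(n)
    expect_equal(grubbsCritical(10L, 1e-14), 9 / sqrt(10), tolerance = 1e-3)
    expect_error(grubbsCritical(2L), "n >= 3")
})

test_that("outlier removal drops only points exceeding the critical value", {
    x <- c(8.1, 8.2, 7.9, 8.0, 14.0)
    ro <- removeOutliers(x, alpha = 0.05)
    expect_identical(ro$removed, 5L)
    expect_equal(ro$values, x[-5L])
    # independent confirmation the point really exceeds G_crit
    expect_gt(grubbsStatistic(x)$G, grubbsCritical(5L, 0.05))

    tame <- c(8.1, 8.2, 7.9, 8.0, 8.3)
    expect_identical(removeOutliers(tame)$removed, integer(0))
    expect_equal(removeOutliers(tame)$values, tame)
    expect_identical(removeOutliers(x, maxRemovals = 0L)$removed, integer(0))
    expect_identical(removeOutliers(c(1, 1, 1, 50), maxRemovals = 2L)$removed, 4L)
})

test_that("unpaired t-test matches the textbook formulas", {
    same <- unpairedT(c(1, 2, 3), c(1, 2, 3))
    expect_equal(same$t, 0)
    expect_equal(same$p, 1)

    x <- c(5.1, 4.8, 5.6, 4.9, 5.3)
    y <- c(4.2, 4.5, 3.9, 4.4, 4.1)
    st <- unpairedT(x, y, "student")
    sp2 <- (4 * var(x) + 4 * var(y)) / 8
    tOracle <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 5 + 1 / 5))
    expect_equal(st$t, tOracle, tolerance = 1e-10)
    expect_equal(st$df, 8)
    expect_equal(st$p, 2 * pt(-abs(tOracle), 8), tolerance = 1e-10)

    we <- unpairedT(x, y, "welch")
    vr <- var(x) / 5 + var(y) / 5
    dfOracle <- vr^2 / ((var(x) / 5)^2 / 4 + (var(y) / 5)^2 / 4)
    expect_equal(we$t, (mean(x) - mean(y)) / sqrt(vr), tolerance = 1e-10)
    expect_equal(we$df, dfOracle, tolerance = 1e-10)

    sw <- unpairedT(y, x, "student")
    expect_equal(sw$t, -st$t)
    expect_equal(sw$p, st$p)
    expect_error(unpairedT(c(1), c(1, 2)), "n >= 2")
    expect_error(unpairedT(c(1, 1), c(1, 1)), "degenerate")
})

test_that("Braak stratification keeps stage 0-3 controls vs stage 5-6 cases", {
    rec <- data.frame(
        sample_id = paste0("s", 1:8),
        group = c(rep("control", 4L), rep("case", 4L)),
        braak = c(0L, 1L, 3L, 2L, 4L, 5L, 6L, 6L))
    out <- stratifyBraak(rec)
    expect_identical(sum(out$group == "case"), 3L)     # the Braak-4 case drops
    expect_identical(sum(out$group == "control"), 4L)  # all controls <= 3 kept

    rec$braak[2L] <- NA_integer_
    expect_warning(out2 <- stratifyBraak(rec), "missing Braak")
    expect_identical(attr(out2, "droppedMissingBraak"), "s2")

    only4 <- data.frame(sample_id = c("c1", "c2", "a1"),
                        group = c("control", "control", "case"),
                        braak = c(1L, 2L, 4L))
    expect_error(stratifyBraak(only4), "empty case stratum")
})

test_that("compareGroups applies exclusions in the fixed order", {
    tbl <- simulateSignatureCohort(nControl = 8L, nCase = 10L,
                                   thetaControl = 0.05, thetaCase = 0.15,
                                   depth = 10000L, nSnpCarriersCase = 2L,
                                   seed = 31L)
    cmp <- compareGroups(tbl, "mismatch_rate")
    expect_identical(length(cmp@excludedSnp), 2L)
    expect_identical(cmp@nCase,
                     10L - 2L - length(cmp@excludedOutliers))
    expect_lt(pValue(cmp), 0.05)
    expect_lt(cmp@meanControl, cmp@meanCase)

    # carriers sit at ~zero signal: without exclusion they would drag the
    # case mean; with it the estimate reflects the non-carrier stoichiometry
    expect_true(all(tbl$mismatch_rate[tbl$snp_status == "carrier"] < 0.01))
})

test_that("compareGroups is invariant to input record order", {
    tbl <- simulateSignatureCohort(nControl = 6L, nCase = 6L,
                                   thetaControl = 0.08, thetaCase = 0.08,
                                   depth = 5000L, seed = 77L)
    a <- compareGroups(tbl, "jump_rate")
    set.seed(1)
    b <- compareGroups(tbl[sample(nrow(tbl)), ], "jump_rate")
    expect_equal(comparisonAsList(a), comparisonAsList(b))
})

test_that("Grubbs removal never fires in groups smaller than three", {
    tbl <- data.frame(sample_id = c("c1", "c2", "a1", "a2"),
                      group = c("control", "control", "case", "case"),
                      braak = c(1L, 2L, 5L, 6L),
                      snp_status = "non_carrier",
                      mismatch_rate = c(0.01, 0.012, 0.05, 0.5))
    cmp <- compareGroups(tbl, "mismatch_rate")
    expect_identical(cmp@excludedOutliers, character(0))
    expect_identical(cmp@nCase, 2L)
})

test_that("stratified comparison flows through compareGroups", {
    tbl <- simulateSignatureCohort(nControl = 10L, nCase = 12L,
                                   thetaControl = 0.05, thetaCase = 0.15,
                                   depth = 10000L, seed = 13L)
    cmp <- compareGroups(tbl, "mismatch_rate", stratify = TRUE)
    expect_identical(cmp@stratification, "case Braak 5-6 vs control Braak 0-3")
    expect_lte(cmp@nCase, 12L)
    expect_lt(pValue(cmp), 0.05)
})

test_that("rejection rate rises with the group stoichiometry difference", {
    set.seed(99)
    rate <- vapply(c(0, 0.03, 0.10), function(delta) {
        mean(vapply(seq_len(60L), function(i) {
            tbl <- simulateSignatureCohort(nControl = 8L, nCase = 8L,
                                           thetaControl = 0.05,
                                           thetaCase = 0.05 + delta,
                                           depth = 10000L)
            pValue(compareGroups(tbl, "mismatch_rate")) < 0.05
        }, logical(1L)))
    }, numeric(1L))
    expect_true(all(diff(rate) >= 0))
    expect_lt(rate[1L], 0.2)
    expect_gt(rate[3L], 0.8)
})
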