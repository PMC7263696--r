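test_that("plate-count normalisation follows the dilution arithmetic", {
    expect_equal(normalizeCount(0, 100), 0)
    # independent unit analysis: selective plate density 20*100/0.2 =
    # 1e4 cfu/ml, permissive 100*1e5/0.1 = 1e8 cells/ml, ratio * 1e7
    expect_equal(normalizeCount(20, 100), 1000)
    same <- PlatingDesign(sel_dilution = 1, sel_volume_ml = 0.1,
                          perm_dilution = 1, perm_volume_ml = 0.1)
    expect_equal(normalizeCount(5, 50, same), 1e6)
    expect_error(normalizeCount(5, 0), "perm_count")
})

test_that("normalisation is homogeneous in each count", {
    base <- normalizeCount(7, 120)
    expect_equal(normalizeCount(21, 120), 3 * base)
    expect_equal(normalizeCount(7, 360), base / 3)
})

test_that("the median equation solver is exact and monotone", {
    expect_equal(leaCoulsonM(1.24), 1, tolerance = 1e-9)
    # plugging m = 2 into r/m - ln m = 1.24 gives r = 2 * (1.24 + ln 2)
    expect_equal(leaCoulsonM(2 * (1.24 + log(2))), 2, tolerance = 1e-9)
    expect_equal(leaCoulsonM(11.6), gridLeaCoulson(11.6),
                 tolerance = 5e-7)
    expect_true(is.na(leaCoulsonM(0)))
    expect_true(is.na(leaCoulsonM(-3)))
    ms <- vapply(c(0.5, 1.24, 3, 11.6, 80, 1500), leaCoulsonM, numeric(1))
    expect_true(all(diff(ms) > 0))
})

test_that("median of the count distribution round-trips through the solver", {
    for (m in c(2, 5, 10, 15)) {
        med <- ldQuantile(m, 0.5)
        expect_lt(abs(leaCoulsonM(med) / m - 1), 0.15)
    }
})

test_that("rate estimation reproduces every intermediate on noiseless data", {
    # 5 cultures; hand arithmetic with the default design:
    # normalised = 5000 * sel / perm
    test <- FluctuationTest(c(2, 0, 1, 4, 30), rep(100, 5))
    est <- estimateRate(test)
    norm <- 5000 * c(2, 0, 1, 4, 30) / 100
    expect_equal(est$median_r, median(norm))
    expect_equal(est$m_hat, leaCoulsonM(median(norm)))
    expect_equal(est$rate, est$m_hat / 1e7)
    expect_identical(est$status, "ok")
    # even number of cultures: median is the mean of the central pair
    est4 <- estimateRate(FluctuationTest(c(1, 2, 3, 4), rep(100, 4)))
    expect_equal(est4$median_r, 5000 * 2.5 / 100)
})

test_that("degenerate fluctuation tests are flagged, not estimated", {
    zero <- estimateRate(FluctuationTest(rep(0, 5), rep(100, 5)))
    expect_identical(zero$status, "indeterminate")
    expect_true(is.na(zero$rate))
    # cultures without viable counts are dropped with a warning
    expect_warning(
        est <- estimateRate(FluctuationTest(c(5, 5, 5), c(100, 0, 100))),
        "dropped")
    expect_identical(est$status, "ok")
    expect_error(
        suppressWarnings(estimateRate(FluctuationTest(c(1, 1), c(0, 0)))),
        "no usable cultures")
    # jackpot-dominated test: most cultures near the normalisation ceiling
    jack <- FluctuationTest(c(2000, 2000, 2000, 1, 1), rep(1, 5))
    expect_identical(estimateRate(jack)$status, "indeterminate")
    expect_gt(estimateRate(jack)$jackpot_fraction, 0.5)
})

test_that("one-sided pooled t-test matches the textbook computation", {
    expect_equal(tTestOneSided(c(1, 2, 3), c(1, 2, 3)), 0.5)
    expect_gt(tTestOneSided(c(1, 2, 3), c(2, 3, 4)), 0.5)
    # hand-pooled statistic: t = 2 / sqrt(1 * 2/3) on 4 df
    t_hand <- 2 / sqrt(2 / 3)
    expect_equal(tTestOneSided(c(3, 4, 5), c(1, 2, 3)),
                 1 - pt(t_hand, 4), tolerance = 1e-10)
    expect_equal(round(tTestOneSided(c(3, 4, 5), c(1, 2, 3)), 4), 0.0352)
    expect_error(tTestOneSided(c(1), c(1, 2)), "insufficient")
})

test_that("two-stage triage applies the rate cutoff then the t-test", {
    wt <- c(1.0e-5, 1.2e-5, 1.1e-5)
    first <- c(tsa1 = 1.23e-4, weak = 1.5e-5, flat = 3e-5, slm3 = NA)
    reps <- list(tsa1 = c(1.2e-4, 1.3e-4, 1.15e-4),
                 flat = c(1.1e-5, 1.0e-5, 1.2e-5))
    out <- triageStrains(first, reps, wt)
    verdict <- setNames(out$verdict, out$strain)
    expect_identical(verdict[["tsa1"]], "validated")
    expect_lt(out$p_value[out$strain == "tsa1"], 0.05)
    expect_identical(verdict[["weak"]], "rejected-stage1")
    expect_identical(verdict[["flat"]], "rejected-stage2")
    expect_identical(verdict[["slm3"]], "indeterminate")
    expect_error(triageStrains(first, reps, numeric(0)), "wild-type")
})

test_that("degenerate thresholds validate every determinate strain", {
    wt <- c(1.0e-5, 1.2e-5)
    first <- c(a = 1e-9, b = 5e-5)
    reps <- list(a = c(1e-9, 2e-9), b = c(4e-5, 6e-5))
    out <- triageStrains(first, reps, wt, rate_cutoff = 1e-300,
                         alpha = 1 - 1e-12)
    expect_true(all(out$verdict == "validated"))
})

test_that("batch estimation groups by strain and test", {
    d <- PlatingDesign()
    tab <- data.frame(strain = rep(c("a", "b"), each = 4),
                      test = rep(c(1, 1, 2, 2), 2),
                      culture = rep(1:2, 4),
                      sel_count = c(1, 3, 2, 2, 10, 12, 9, 13),
                      perm_count = 100)
    est <- estimateRates(tab, d)
    expect_identical(nrow(est), 4L)
    direct <- estimateRate(FluctuationTest(c(10, 12), c(100, 100), d))
    expect_equal(est$rate[est$strain == "b" & est$test == "1"],
                 direct$rate)
})
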