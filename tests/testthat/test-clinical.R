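test_that("the adjudicator honours every criterion branch", {
    crit <- exacerbationCriteria()
    # criterion 1 alone
    call <- classifyExacerbation(handSeries(careSeeking = TRUE), crit)
    expect_true(verdict(call))
    expect_true(call@criterion1)
    expect_false(call@criterion2)
    # criterion 2 via albuterol
    call <- classifyExacerbation(
        handSeries(symptomDelta = 12, symptomDays = 3L,
                   extraPuffs = 5, puffDays = 2L), crit)
    expect_true(verdict(call))
    expect_identical(call@objectiveChanges, "albuterol")
    # criterion 2 via FEV1 decline
    call <- classifyExacerbation(
        handSeries(symptomDelta = 12, symptomDays = 2L, fev1Drop = 0.12),
        crit)
    expect_true(verdict(call))
    expect_identical(call@objectiveChanges, "fev1")
    # criterion 2 via PEF decline
    call <- classifyExacerbation(
        handSeries(symptomDelta = 12, symptomDays = 2L, pefDrop = 0.25,
                   pefDays = 2L), crit)
    expect_true(verdict(call))
    expect_identical(call@objectiveChanges, "pef")
    # symptoms without an objective change do not qualify
    call <- classifyExacerbation(
        handSeries(symptomDelta = 12, symptomDays = 3L), crit)
    expect_false(verdict(call))
    # an objective change without the symptom increase does not qualify
    call <- classifyExacerbation(
        handSeries(extraPuffs = 6, puffDays = 3L), crit)
    expect_false(verdict(call))
    # thresholds are inclusive but one day short fails
    call <- classifyExacerbation(
        handSeries(symptomDelta = 10, symptomDays = 1L,
                   extraPuffs = 4, puffDays = 2L), crit)
    expect_false(verdict(call))
    # non-asthmatic subjects are trivially negative
    call <- classifyExacerbation(
        handSeries(group = "Healthy", symptomDelta = 20,
                   symptomDays = 5L, extraPuffs = 6, puffDays = 3L), crit)
    expect_false(verdict(call))
    expect_match(callEvidence(call)$note, "non-asthmatic")
})

test_that("the evidence trace reports the per-day comparisons", {
    call <- classifyExacerbation(
        handSeries(symptomDelta = 12, symptomDays = 3L,
                   extraPuffs = 5, puffDays = 2L))
    ev <- callEvidence(call)
    expect_equal(ev$symptomDaysOver, 3L)
    expect_equal(ev$albuterolDaysOver, 2L)
    expect_equal(ev$baselineSymptomMean, 10)
    expect_equal(ev$bestBaselinePef, 400)
})

test_that("Friedman test matches the rank-sum formula", {
    mono <- rbind(c(1, 2, 3), c(2, 5, 9), c(0, 4, 8))
    out <- friedmanRankTest(mono)
    expect_equal(unname(out$statistic), 6)
    # all ties: degenerate 0 statistic with p = 1
    flat <- rbind(c(2, 2, 2), c(7, 7, 7))
    out <- friedmanRankTest(flat)
    expect_equal(unname(out$statistic), 0)
    expect_equal(out$p.value, 1)
    # block exchangeability
    set.seed(7)
    tab <- matrix(stats::rnorm(15), 5, 3)
    a <- friedmanRankTest(tab)
    b <- friedmanRankTest(tab[sample(5), ])
    expect_equal(a$statistic, b$statistic)
    # agreement with the hand formula on random untied tables
    for (i in 1:20) {
        tab <- matrix(stats::rnorm(15), 5, 3)
        expect_equal(unname(friedmanRankTest(tab)$statistic),
                     bruteFriedman(tab), tolerance = 1e-10)
    }
    expect_warning(friedmanRankTest(rbind(c(1, 2, NA), c(1, 2, 3),
                                          c(2, 1, 3))),
                   "dropped")
    expect_error(
        suppressWarnings(friedmanRankTest(rbind(c(1, 2, NA), c(1, 2, 3)))),
        ">= 2 complete blocks")
})

test_that("Mann-Whitney U matches enumeration and is rank-invariant", {
    out <- mannWhitneyU(1:3, 4:6)
    expect_equal(unname(out$statistic), 0)
    expect_equal(out$p.value, 0.1)
    # identical multisets give U = n1 n2 / 2
    out <- mannWhitneyU(c(1, 2, 3), c(1, 2, 3))
    expect_equal(unname(out$statistic), 4.5)
    # scale invariance
    a <- mannWhitneyU(c(1, 5, 9), c(2, 3, 11))
    b <- mannWhitneyU(2 * c(1, 5, 9), 2 * c(2, 3, 11))
    expect_equal(a$statistic, b$statistic)
    expect_equal(a$p.value, b$p.value)
    expect_error(mannWhitneyU(numeric(0), 1:3), "non-empty")
})

test_that("exact Mann-Whitney p equals brute force for all n1, n2 <= 6", {
    set.seed(11)
    for (n1 in 2:6) for (n2 in 2:6) {
        x <- stats::rnorm(n1)
        y <- stats::rnorm(n2)
        ours <- mannWhitneyU(x, y)
        ref <- bruteMWU(x, y)
        expect_equal(unname(ours$statistic), ref$U)
        expect_equal(ours$p.value, ref$p)
        # and with ties
        xt <- sample(1:3, n1, replace = TRUE)
        yt <- sample(1:3, n2, replace = TRUE)
        ours <- mannWhitneyU(xt, yt)
        ref <- bruteMWU(xt, yt)
        expect_equal(ours$p.value, ref$p)
    }
})

test_that("exact Mann-Whitney p agrees with wilcox.test on untied data", {
    set.seed(12)
    for (i in 1:10) {
        x <- stats::rnorm(5); y <- stats::rnorm(6)
        ours <- mannWhitneyU(x, y)
        ref <- stats::wilcox.test(x, y, exact = TRUE)
        expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
    }
})

test_that("large-sample Mann-Whitney uses the tie-corrected normal", {
    set.seed(13)
    x <- stats::rnorm(30); y <- stats::rnorm(35, 0.8)
    ours <- mannWhitneyU(x, y)
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
})

test_that("Spearman correlation handles monotone and tied inputs", {
    expect_equal(unname(spearmanRank(1:5, (1:5)^3)$estimate), 1)
    expect_equal(unname(spearmanRank(1:5, -(1:5)^3)$estimate), -1)
    r <- spearmanRank(c(1, 2, 3), c(1, 1, 2))
    expect_equal(unname(r$estimate), sqrt(3) / 2, tolerance = 1e-10)
    expect_error(spearmanRank(c(1, 1, 1), 1:3), "constant")
    expect_error(spearmanRank(1:2, 1:2), "n >= 3")
    # t approximation at larger n agrees with cor.test
    set.seed(14)
    x <- stats::rnorm(20); y <- x + stats::rnorm(20)
    ours <- spearmanRank(x, y)
    ref <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
    expect_equal(unname(ours$estimate), unname(ref$estimate),
                 tolerance = 1e-10)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
})

test_that("qPCR normalization follows the two-reference delta-Ct rule", {
    expect_equal(normalizeQpcr(25, c(20, 22)), 0.0625)
    expect_equal(normalizeQpcr(21, c(20, 22)), 1.0)
    # fold change of identical samples is 1
    expect_equal(normalizeQpcr(25, c(20, 22)) /
                 normalizeQpcr(25, c(20, 22)), 1.0)
    # invariance to a common Ct shift
    expect_equal(normalizeQpcr(25 + 3, c(20, 22) + 3),
                 normalizeQpcr(25, c(20, 22)))
    expect_error(normalizeQpcr(46, c(20, 22)), "\\(0, 45\\)")
})
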