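# Closed-form OLS via the normal equations, independent of stats::lm.
olsOracle <- function(x, y) {
    X <- cbind(1, x)
    solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# Spearman via explicit average ranks then the Pearson product-moment
# formula, independent of stats::cor(method = "spearman").
spearmanOracle <- function(x, y) {
    rx <- rank(x, ties.method = "average")
    ry <- rank(y, ties.method = "average")
    num <- sum((rx - mean(rx)) * (ry - mean(ry)))
    num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

test_that("ages map to decade bins with inclusive bounds", {
    b <- datasetBinning("1000FCP")
    expect_equal(as.character(assignAgeGroups(35, b)), "31-40")
    expect_equal(as.character(assignAgeGroups(30, b)), "21-30")
    expect_equal(as.character(assignAgeGroups(75, b)), "71+")
    expect_message(g <- assignAgeGroups(c(17, 25), b), "excluded")
    expect_true(is.na(g[1]) && !is.na(g[2]))
})

test_that("balancedSplit reproduces the published bookkeeping", {
    s1 <- balancedSplit(458, 39, seed = 1)
    expect_equal(s1@m, 39L)
    expect_equal(2L * s1@m, 78L)
    expect_equal(s1@k, 419L)
    s2 <- balancedSplit(458, 85, seed = 1)
    expect_equal(c(s2@m, 2L * s2@m, s2@k), c(85L, 170L, 373L))
    s3 <- balancedSplit(12, 12, seed = 1)
    expect_equal(s3@k, 0L)
    expect_error(balancedSplit(0, 5), "at least one")
})

test_that("balancedSplit training and residual sets are disjoint and seeded", {
    s <- balancedSplit(100, 30, seed = 42)
    expect_length(intersect(s@trainYoung, s@residual), 0)
    expect_length(union(s@trainYoung, s@residual), 100)
    expect_identical(balancedSplit(100, 30, seed = 42)@trainYoung,
                     s@trainYoung)
    expect_false(identical(balancedSplit(100, 30, seed = 43)@trainYoung,
                           s@trainYoung))
})

test_that("the linear SVM separates separable clouds and respects sign", {
    set.seed(1)
    x <- rbind(matrix(rnorm(100, -3), ncol = 2),
               matrix(rnorm(100, 3), ncol = 2))
    lab <- rep(c("young", "aged"), each = 50)
    m <- trainClassifier(x, lab)
    expect_equal(mean(predictClassifier(m, x) == lab), 1.0)

    x1 <- matrix(c(rep(-1, 20), rep(1, 20)) + rnorm(40, 0, 0.05), ncol = 1)
    m1 <- trainClassifier(x1, rep(c("young", "aged"), each = 20))
    expect_equal(as.character(predictClassifier(m1, matrix(c(-2, 2), ncol = 1))),
                 c("young", "aged"))
    expect_error(trainClassifier(x, rep("young", 100)), "single class")
})

test_that("random labels on noise give chance-level held-out accuracy", {
    set.seed(8)
    x <- matrix(rnorm(400 * 10), ncol = 10)
    lab <- sample(rep(c("young", "aged"), each = 200))
    m <- trainClassifier(x[1:200, ], lab[1:200])
    acc <- validationAccuracy(m, x[201:400, ], lab[201:400])
    expect_gt(acc, 0.4)
    expect_lt(acc, 0.6)
})

test_that("validationAccuracy counts correct residual decisions", {
    set.seed(2)
    x <- rbind(matrix(rnorm(40, -2), ncol = 2), matrix(rnorm(40, 2), ncol = 2))
    lab <- rep(c("young", "aged"), each = 10)
    m <- trainClassifier(x, lab)
    v <- matrix(rnorm(6, -3, 0.1), ncol = 2)
    expect_equal(validationAccuracy(m, v, "young"), 1.0)
    expect_equal(validationAccuracy(m, v, "aged"), 0.0)
    expect_equal(validationAccuracy(m, rbind(v[1:2, ], -v[3, ]), "young"),
                 2 / 3, tolerance = 1e-12)
    expect_message(ar <- validationAccuracy(m, x[0, , drop = FALSE], "young"),
                   "k = 0")
    expect_true(is.na(ar))
})

test_that("percentAgedByAge tallies per distinct age", {
    pred <- factor(c("aged", "aged", "young", "young", "aged"),
                   levels = c("young", "aged"))
    s <- percentAgedByAge(pred, c(41, 41, 41, 52, 52))
    expect_equal(s$age, c(41L, 52L))
    expect_equal(s$percentAged, c(200 / 3, 50))
    expect_equal(s$n, c(3L, 2L))
    allY <- percentAgedByAge(factor(rep("young", 3),
                                    levels = c("young", "aged")), rep(60, 3))
    expect_equal(allY$percentAged, 0)
    allA <- percentAgedByAge(factor(rep("aged", 3),
                                    levels = c("young", "aged")), rep(60, 3))
    expect_equal(allA$percentAged, 100)
})

test_that("sliding window averages raw percentages over observed ages", {
    s <- data.frame(age = 41:45, percentAged = c(0, 100, 0, 100, 0),
                    n = rep(2L, 5))
    sm <- slidingWindow(s, 5)
    expect_equal(sm$percentAged[3], 40)   # mean of all five points
    expect_equal(sm$percentAged[1], mean(c(0, 100, 0)))  # truncated edge
    expect_identical(slidingWindow(s, 1), s)
    const <- data.frame(age = 1:5, percentAged = rep(50, 5), n = 1L)
    expect_equal(slidingWindow(const, 5), const)
    expect_error(slidingWindow(s, 4), "odd")
    expect_error(slidingWindow(s[0, ], 5), "empty")
})

test_that("smoothed values stay within the raw range of each window", {
    set.seed(5)
    for (r in 1:10) {
        s <- data.frame(age = sort(sample(30:70, 25)),
                        percentAged = runif(25, 0, 100), n = 1L)
        sm <- slidingWindow(s, 5)
        for (i in seq_len(nrow(s))) {
            w <- s$percentAged[abs(s$age - s$age[i]) <= 2]
            expect_gte(sm$percentAged[i], min(w))
            expect_lte(sm$percentAged[i], max(w))
        }
    }
})

test_that("poolTailAges merges sparse terminal ages subject-weighted", {
    s <- data.frame(age = c(70, 77, 80, 85),
                    percentAged = c(50, 100, 0, 100), n = c(10L, 2L, 1L, 1L))
    p <- poolTailAges(s, 77)
    expect_equal(nrow(p), 2)
    expect_equal(p$age[2], 77L)
    expect_equal(p$n[2], 4L)
    expect_equal(p$percentAged[2], 100 * 3 / 4)
})

test_that("fitLinearTrend equals the normal-equations oracle", {
    exact <- fitLinearTrend(data.frame(age = 0:2,
                                       percentAged = c(0, 2, 4), n = 1L))
    expect_equal(unname(exact), c(0, 2), tolerance = 1e-12)
    const <- fitLinearTrend(data.frame(age = c(40, 50, 66),
                                       percentAged = rep(50, 3), n = 1L))
    expect_equal(unname(const), c(50, 0), tolerance = 1e-12)
    set.seed(9)
    s <- data.frame(age = 31:70,
                    percentAged = 20 + 0.9 * (31:70) + rnorm(40, 0, 5),
                    n = 1L)
    got <- fitLinearTrend(s)
    want <- olsOracle(s$age - min(s$age), s$percentAged)
    expect_equal(unname(got), unname(want), tolerance = 1e-9)
    expect_error(fitLinearTrend(s[1, ]), "2 distinct ages")
})

test_that("Spearman monotonicity matches a rank-then-Pearson oracle", {
    inc <- data.frame(age = 1:6, percentAged = c(1, 5, 20, 33, 70, 90), n = 1L)
    expect_equal(spearmanMonotonicity(inc), 1.0)
    dec <- inc; dec$percentAged <- rev(dec$percentAged)
    expect_equal(spearmanMonotonicity(dec), -1.0)
    set.seed(4)
    for (r in 1:10) {
        ties <- data.frame(age = 1:15,
                           percentAged = sample(c(0, 25, 50, 75, 100), 15,
                                                replace = TRUE), n = 1L)
        if (sd(ties$percentAged) == 0) next
        expect_equal(spearmanMonotonicity(ties),
                     spearmanOracle(ties$age, ties$percentAged),
                     tolerance = 1e-9)
    }
    const <- data.frame(age = 1:4, percentAged = rep(10, 4), n = 1L)
    expect_warning(rho <- spearmanMonotonicity(const), "constant")
    expect_equal(rho, 0)
})

test_that("hypothesis selection covers the fallback branches", {
    # interval 1 without a credible trend has no published label
    expect_equal(selectHypothesis(1, 60, -0.2, 0.1), "inconclusive")
    # interval 2: rising from a low intercept is H2
    expect_equal(selectHypothesis(2, 30, 0.4, 0.3), "H2")
    # interval 3: a significant inverted U is H2
    x <- 1:40
    s <- data.frame(age = 20 + x,
                    percentAged = 80 - 0.15 * (x - 20)^2 + rnorm(40, 0, 2),
                    n = 1L)
    rho <- spearmanMonotonicity(s)
    expect_equal(selectHypothesis(3, 50, 0, rho, series = s), "H2")
    # interval 3 without curvature evidence falls to H3
    expect_equal(selectHypothesis(3, 45.12, -0.176, -0.161), "H3")
    expect_error(selectHypothesis(4, 1, 1, 1), "1, 2 or 3")
})

test_that("runMonotonicity recovers the simulated regimes", {
    b <- presetBinning()
    mono <- generateCohort(scenarioPreset("monotone", seed = 21))
    r1 <- runMonotonicity(mono, 1, b, seed = 5)
    expect_equal(hypothesis(r1), "H1")
    expect_gt(spearmanRho(r1), 0.8)
    expect_gt(r1@validationAccuracy, 0.9)
    expect_equal(r1@m, 40L)
    expect_equal(r1@k, 160L)
    expect_equal(sum(r1@rawSeries$n), 160)

    plat <- generateCohort(scenarioPreset("plateau", seed = 22))
    r2 <- suppressWarnings(runMonotonicity(plat, 2, b, seed = 5))
    expect_equal(hypothesis(r2), "H3")
    expect_gt(r2@beta0, 50)
})

test_that("width-1 smoothing reproduces the no-window pipeline", {
    cc <- generateCohort(scenarioPreset("monotone", seed = 30))
    r <- suppressWarnings(runMonotonicity(cc, 1, presetBinning(),
                                          window = 1, seed = 2))
    expect_identical(r@rawSeries, r@smoothedSeries)
    expect_equal(r@beta0, r@rawBeta0)
    expect_equal(r@spearmanRho, r@rawSpearmanRho)
})

test_that("identical cohort and seed give identical results", {
    cc <- generateCohort(scenarioPreset("null", seed = 31))
    r1 <- runMonotonicity(cc, 1, presetBinning(), seed = 7)
    r2 <- runMonotonicity(cc, 1, presetBinning(), seed = 7)
    for (sl in c("beta0", "beta1", "spearmanRho", "validationAccuracy",
                 "hypothesis"))
        expect_identical(slot(r1, sl), slot(r2, sl))
    expect_identical(r1@rawSeries, r2@rawSeries)
})

test_that("training, validation and test subjects never overlap", {
    # reconstruct the three sets the pipeline uses and check disjointness
    cc <- generateCohort(scenarioPreset("null", seed = 32))
    b <- presetBinning()
    groups <- assignAgeGroups(cc, b)
    sc <- intervalScenario(1, b)
    youngIdx <- which(as.integer(groups) == sc@youngBin)
    agedIdx <- which(as.integer(groups) == sc@agedBin)
    sp <- balancedSplit(length(youngIdx), length(agedIdx), seed = 7)
    train <- c(youngIdx[sp@trainYoung], agedIdx[sp@trainAged])
    resid <- youngIdx[sp@residual]
    testIdx <- which(as.integer(groups) %in% sc@testBins)
    expect_length(intersect(train, resid), 0)
    expect_length(intersect(train, testIdx), 0)
    expect_length(intersect(resid, testIdx), 0)
    expect_equal(length(train) + length(resid) + length(testIdx), ncol(cc))
})

test_that("interval scenarios partition the bins as designed", {
    b <- datasetBinning("camCAN")
    s1 <- intervalScenario(1, b)
    expect_equal(c(s1@youngBin, s1@agedBin), c(1L, 7L))
    expect_equal(s1@testBins, 2:6)
    s2 <- intervalScenario(2, b)
    expect_equal(s2@testBins, 3:7)
    s3 <- intervalScenario(3, b)
    expect_equal(c(s3@youngBin, s3@agedBin), c(6L, 7L))
    expect_equal(s3@testBins, 1:5)
    two <- AgeBinning(c("a", "b"), c(18, 41), c(40, 80))
    expect_error(intervalScenario(2, two), "no test bins")
})
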