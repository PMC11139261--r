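# Welch's t and its Satterthwaite p-value from the closed-form formulas.
welchOracle <- function(x, y) {
    v1 <- var(x) / length(x); v2 <- var(y) / length(y)
    t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
    list(t = t, p = 2 * pt(-abs(t), df))
}

test_that("per-subject counts follow the strict threshold rule", {
    cc <- tinyCohort()
    tab <- fcCountsPerSubject(cc, 0.6)
    expect_equal(tab$nPos, c(1L, 0L, 0L))
    expect_equal(tab$nNeg, c(1L, 0L, 0L))
    expect_equal(tab$nTotal, tab$nPos + tab$nNeg)
    # identical subjects give identical rows
    f <- rbind(c(0.8, -0.7, 0.1), c(0.8, -0.7, 0.1))
    cc2 <- ConnectomeCohort(f, age = c(30, 30), sex = c("M", "M"), nRois = 3)
    t2 <- fcCountsPerSubject(cc2, 0.6)
    expect_identical(t2$nTotal[1], t2$nTotal[2])
})

test_that("group mean counts match a binomial exceedance oracle", {
    # zero-mean Fisher-z edges with s.d. s: each edge independently exceeds
    # |rho| = thr with p = 2 * (1 - pnorm(atanh(thr) / s)), so per-subject
    # totals are Binomial(E, p)
    s <- 0.4; thr <- 0.6; n <- 150
    cfg <- cohortConfig(nRois = 30,
                        groupSpec = data.frame(ageLo = 20, ageHi = 40,
                                               nMale = n / 2, nFemale = n / 2),
                        baseZ = 0, driftProfile = "null", driftMagnitude = 0,
                        sdBase = s, seed = 12)
    counts <- fcCountsPerSubject(generateCohort(cfg), thr)
    E <- featureDimension(30)
    p <- 2 * (1 - pnorm(atanh(thr) / s))
    se <- sqrt(E * p * (1 - p) / n)
    expect_lt(abs(mean(counts$nTotal) - E * p), 2.58 * se)
})

test_that("Welch test matches the closed-form oracle and is symmetric", {
    x <- c(12, 15, 11, 19, 14, 13)
    y <- c(21, 25, 24, 28)
    got <- ttestVsReference(x, y)
    want <- welchOracle(x, y)
    expect_equal(got$t, want$t, tolerance = 1e-9)
    expect_equal(got$p, want$p, tolerance = 1e-9)
    swapped <- ttestVsReference(y, x)
    expect_equal(swapped$t, -got$t, tolerance = 1e-12)
    expect_equal(swapped$p, got$p, tolerance = 1e-12)

    same <- ttestVsReference(x, x)
    expect_equal(same$t, 0)
    expect_equal(same$p, 1)
    expect_false(same$significant)
    big <- ttestVsReference(x + 1000, y)
    expect_true(big$significant)
    expect_error(ttestVsReference(1, y), "at least 2")
})

test_that("summarizeFC aggregates per group with the youngest as reference", {
    cfg <- cohortConfig(nRois = 12,
                        groupSpec = data.frame(ageLo = c(18, 41, 61),
                                               ageHi = c(30, 50, 80),
                                               nMale = c(15, 15, 15),
                                               nFemale = c(15, 15, 15)),
                        driftProfile = "linear_monotone",
                        driftMagnitude = -0.02, affectedFraction = 0.5,
                        baseZ = c(0.8, 0.6), sdBase = 0.1, seed = 13)
    cc <- generateCohort(cfg)
    b <- AgeBinning(c("young", "mid", "old"), c(18, 41, 61), c(30, 50, 80))
    tab <- summarizeFC(cc, b, threshold = 0.6)
    expect_equal(tab$group, c("young", "mid", "old"))
    expect_true(all(is.na(tab[tab$group == "young",
                              c("pPos", "pNeg", "pTotal")])))
    # per-subject totals are sums, so means add up exactly
    expect_equal(tab$meanTotal, tab$meanPos + tab$meanNeg)
    # a strong monotone decrease is significant for the oldest group
    expect_lt(tab$meanTotal[3], tab$meanTotal[1])
    expect_true(tab$sigTotal[3])
})

test_that("identical counts give zero s.d. and no significance", {
    f <- matrix(rep(c(0.9, -0.8, 0.1), 6), nrow = 6, byrow = TRUE)
    cc <- ConnectomeCohort(f, age = c(25, 25, 25, 45, 45, 45),
                           sex = rep("F", 6), nRois = 3)
    b <- AgeBinning(c("y", "o"), c(18, 41), c(40, 80))
    tab <- summarizeFC(cc, b)
    expect_equal(tab$sdTotal, c(0, 0))
    expect_false(any(tab$sigTotal))
})

test_that("sex strata are emitted even when empty, tests skipped", {
    f <- matrix(runif(5 * 3, -0.4, 0.4), nrow = 5)
    cc <- ConnectomeCohort(f, age = c(25, 26, 27, 45, 46),
                           sex = c("F", "F", "M", "M", "M"), nRois = 3)
    b <- AgeBinning(c("y", "o"), c(18, 41), c(40, 80))
    tab <- summarizeFC(cc, b, stratifySex = TRUE)
    fo <- tab[tab$stratum == "F" & tab$group == "o", ]
    expect_equal(nrow(fo), 1)
    expect_equal(fo$nSubjects, 0)
    expect_true(fo$testSkipped)
    # stratified counts sum to the pooled counts per group
    for (g in c("y", "o")) {
        ns <- tab$nSubjects[tab$group == g]
        expect_equal(ns[1], ns[2] + ns[3])
    }
})

test_that("mean counts are monotone non-increasing across thresholds", {
    cc <- generateCohort(cohortConfig(
        nRois = 15, groupSpec = data.frame(ageLo = c(18, 51),
                                           ageHi = c(40, 80),
                                           nMale = c(10, 10),
                                           nFemale = c(10, 10)),
        baseZ = c(0.7, 0.4), sdBase = 0.3, driftProfile = "null",
        driftMagnitude = 0, seed = 14))
    b <- AgeBinning(c("y", "o"), c(18, 51), c(40, 80))
    tabs <- thresholdSensitivity(cc, b, thresholds = c(0.45, 0.6, 0.7))
    m <- sapply(tabs, function(t) t$meanTotal)
    expect_true(all(apply(m, 1, function(v) all(diff(v) <= 0))))
    # a single threshold reduces to summarizeFC
    expect_equal(thresholdSensitivity(cc, b, thresholds = 0.6)[["0.6"]],
                 summarizeFC(cc, b, threshold = 0.6))
    # nothing survives when every |rho| is below the lowest threshold
    low <- ConnectomeCohort(matrix(runif(4 * 3, -0.3, 0.3), nrow = 4),
                            age = c(20, 21, 60, 61), sex = rep("M", 4),
                            nRois = 3)
    tl <- summarizeFC(low, b, threshold = 0.45)
    expect_equal(tl$meanTotal, c(0, 0))
})

test_that("filterCohort applies intersection semantics", {
    cc <- tinyCohort()
    eo <- filterCohort(cc, eyes = "open")
    expect_equal(ncol(eo), 2)
    expect_true(all(eyesState(eo) == "open"))
    both <- filterCohort(cc, site = "A", sex = "F")
    expect_equal(ncol(both), 1)
    expect_equal(sexes(both), "F")
    expect_warning(none <- filterCohort(cc, site = "Z"), "no subjects")
    expect_equal(ncol(none), 0)
    expect_equal(metadata(both)$filters[[1]]$nKept, 1)
})
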