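#' Percent classified as aged at each age
#'
#' Tallies, for every distinct integer age in the test interval, the
#' percentage of subjects the classifier assigned to the aged class. Ages
#' with no subjects do not appear.
#'
#' @param predictions factor of \code{"young"}/\code{"aged"} decisions.
#' @param ages integer ages, one per prediction.
#' @return data.frame with columns \code{age}, \code{percentAged},
#'   \code{n}, ordered by age.
#' @examples
#' percentAgedByAge(factor(c("aged", "aged", "young")), c(41, 41, 41))
#' @export
percentAgedByAge <- function(predictions, ages) {
    if (length(predictions) != length(ages))
        stop("predictions and ages must have equal length")
    ages <- as.integer(ages)
    agedN <- tapply(predictions == "aged", ages, sum)
    n <- tapply(ages, ages, length)
    a <- as.integer(names(n))
    out <- data.frame(age = a,
                      percentAged = 100 * as.numeric(agedN) / as.numeric(n),
                      n = as.integer(n))
    out[order(out$age), , drop = FALSE]
}

#' Sliding-window smoothing of an age series
#'
#' Replaces the percentage at each observed age \eqn{a} by the unweighted
#' mean of the raw percentages at observed ages within
#' \eqn{[a - h, a + h]}, \eqn{h = (w-1)/2} for an odd window width \eqn{w}
#' in years (default 5). At the interval edges the window truncates to the
#' available ages. Width 1 is the identity (the no-smoothing variant).
#'
#' @param series data.frame as returned by \code{\link{percentAgedByAge}}.
#' @param width odd window width in years, >= 1.
#' @return data.frame of the same shape with smoothed \code{percentAged}.
#' @export
slidingWindow <- function(series, width = 5L) {
    width <- as.integer(width)
    if (is.na(width) || width < 1L || width %% 2L == 0L)
        stop("width must be an odd integer >= 1")
    if (nrow(series) == 0L) stop("empty series")
    if (width == 1L) return(series)
    h <- (width - 1L) %/% 2L
    sm <- vapply(series$age, function(a) {
        mean(series$percentAged[abs(series$age - a) <= h])
    }, numeric(1))
    out <- series
    out$percentAged <- sm
    out
}

#' Pool sparse terminal ages into a single point
#'
#' Ages at or beyond \code{cutoffAge} are merged into one terminal point at
#' \code{cutoffAge} whose percentage is computed over all pooled subjects
#' (subject-weighted), mirroring the practice of ending the abscissa at a
#' pooled "77+"-style point when few subjects exist at the extreme ages.
#'
#' @param series data.frame as returned by \code{\link{percentAgedByAge}}.
#' @param cutoffAge age at which pooling starts.
#' @return data.frame with one row per retained age.
#' @export
poolTailAges <- function(series, cutoffAge) {
    tail <- series$age >= cutoffAge
    if (sum(tail) <= 1L) return(series)
    pooled <- data.frame(
        age = as.integer(cutoffAge),
        percentAged = 100 * sum(series$percentAged[tail] / 100 *
                                  series$n[tail]) / sum(series$n[tail]),
        n = sum(series$n[tail]))
    rbind(series[!tail, , drop = FALSE], pooled)
}

#' Least-squares linear trend of an age series
#'
#' Ordinary least squares of the percentage classified as aged on age. By
#' default age is measured in years since the youngest test age
#' (\code{origin = "interval_start"}), so the intercept \eqn{\beta_0} is
#' the fitted percentage at the start of the interval; \code{"age_zero"}
#' uses raw age.
#'
#' @param series data.frame with columns \code{age}, \code{percentAged}.
#' @param origin \code{"interval_start"} or \code{"age_zero"}.
#' @return named numeric \code{c(beta0, beta1)} (percent, percent/year).
#' @examples
#' fitLinearTrend(data.frame(age = 0:2, percentAged = c(0, 2, 4), n = 1))
#' @export
fitLinearTrend <- function(series, origin = c("interval_start", "age_zero")) {
    origin <- match.arg(origin)
    if (length(unique(series$age)) < 2L)
        stop("need at least 2 distinct ages for a linear fit")
    x <- series$age - if (origin == "interval_start") min(series$age) else 0
    fit <- stats::lm(series$percentAged ~ x)
    cf <- stats::coef(fit)
    c(beta0 = unname(cf[1L]), beta1 = unname(cf[2L]))
}

#' Spearman rank correlation between age and percent aged
#'
#' The monotonicity measure: Spearman's rank correlation (average ranks for
#' ties) between the ages of an age series and its percentages. A constant
#' series, for which the correlation is mathematically undefined, returns 0
#' with a warning.
#'
#' @param series data.frame with columns \code{age}, \code{percentAged}.
#' @return rho in [-1, 1].
#' @export
spearmanMonotonicity <- function(series) {
    if (nrow(series) < 2L) stop("need at least 2 points")
    if (stats::sd(series$percentAged) == 0) {
        warning("constant series: Spearman correlation undefined, returning 0")
        return(0)
    }
    stats::cor(series$age, series$percentAged, method = "spearman")
}

#' Select the prominent aging-trajectory hypothesis
#'
#' Maps the trend statistics of an interval to one of the candidate
#' trajectories: H1 (monotone increase), H2 (increase from a low intercept
#' for interval 2; inverted-U for interval 3) or H3 (flat). The rule is a
#' configurable formalisation of the narrative assignment:
#' \itemize{
#'   \item every interval: H1 iff \eqn{\rho_s \ge} \code{rhoThreshold}
#'     (default 0.5) and \eqn{\beta_1 > 0};
#'   \item interval 2 fallback: H2 iff \eqn{\beta_1 > 0} and
#'     \eqn{\beta_0 <} \code{interceptThreshold} (default 50), else H3;
#'   \item interval 3 fallback: H2 iff a quadratic fit to \code{series} has
#'     significantly negative curvature (p < \code{curvatureAlpha}), else
#'     H3;
#'   \item interval 1 fallback: \code{"inconclusive"} (no published case
#'     required it).
#' }
#'
#' @param intervalId 1, 2 or 3.
#' @param beta0,beta1 linear-trend intercept (percent) and slope
#'   (percent/year).
#' @param rho Spearman rank correlation of the series.
#' @param series optional age series, needed only for the interval-3
#'   inverted-U (quadratic curvature) check.
#' @param rhoThreshold minimum rho for H1.
#' @param interceptThreshold maximum beta0 for interval-2 H2.
#' @param curvatureAlpha significance level of the curvature test.
#' @return one of \code{"H1"}, \code{"H2"}, \code{"H3"},
#'   \code{"inconclusive"}.
#' @examples
#' selectHypothesis(1, 31.58, 0.952, 0.7)    # H1
#' selectHypothesis(2, 82.159, 0.1, 0.149)   # H3
#' @export
selectHypothesis <- function(intervalId, beta0, beta1, rho, series = NULL,
                             rhoThreshold = 0.5, interceptThreshold = 50,
                             curvatureAlpha = 0.05) {
    intervalId <- as.integer(intervalId)
    if (!intervalId %in% 1:3) stop("intervalId must be 1, 2 or 3")
    stopifnot(is.finite(beta0), is.finite(beta1), is.finite(rho))
    if (rho >= rhoThreshold && beta1 > 0) return("H1")
    if (intervalId == 1L) return("inconclusive")
    if (intervalId == 2L) {
        if (beta1 > 0 && beta0 < interceptThreshold) return("H2")
        return("H3")
    }
    # interval 3: H2 is an inverted-U, identified by significantly
    # negative curvature of a quadratic fit
    if (!is.null(series) && length(unique(series$age)) >= 3L) {
        x <- series$age - min(series$age)
        fit <- stats::lm(series$percentAged ~ x + I(x^2))
        sm <- summary(fit)$coefficients
        if (nrow(sm) >= 3L && is.finite(sm[3L, 4L]) &&
            sm[3L, 1L] < 0 && sm[3L, 4L] < curvatureAlpha)
            return("H2")
    }
    "H3"
}

#' Run the full monotonicity pipeline for one interval
#'
#' Executes the whole chain on a cohort: bin assignment, balanced
#' extrema-group split, linear-SVM training, residual validation (AR),
#' classification of the unseen test interval, per-age percent-aged
#' series, optional terminal-age pooling, sliding-window smoothing, linear
#' trend fit, Spearman monotonicity and hypothesis selection. Trend and
#' Spearman statistics are computed on the smoothed series (the primary
#' statistics) and also on the raw series.
#'
#' @param cohort a \linkS4class{ConnectomeCohort}.
#' @param intervalId 1, 2 or 3.
#' @param binning an \linkS4class{AgeBinning}; bins with no subjects are
#'   dropped before building the scenario.
#' @param window odd sliding-window width in years (1 = no smoothing).
#' @param cost SVM regularisation parameter.
#' @param seed integer RNG seed for the balanced subsample.
#' @param dataset label recorded in the result.
#' @param tailCutoff optional age at which sparse terminal ages are pooled
#'   (\code{\link{poolTailAges}}); \code{NULL} disables pooling.
#' @param tailMinCount pooling is applied only if every age at or beyond
#'   \code{tailCutoff} has fewer than this many subjects.
#' @return a \linkS4class{MonotonicityResult}.
#' @examples
#' cc <- generateCohort(scenarioPreset("monotone"))
#' binning <- AgeBinning(c("18-30", "31-40", "41-50", "51-60", "61-70",
#'                         "71-85"),
#'                       c(18, 31, 41, 51, 61, 71),
#'                       c(30, 40, 50, 60, 70, 85))
#' res <- runMonotonicity(cc, 1, binning, seed = 7)
#' res
#' @export
runMonotonicity <- function(cohort, intervalId, binning, window = 5L,
                            cost = 1, seed = 1L, dataset = "cohort",
                            tailCutoff = NULL, tailMinCount = 3L) {
    groups <- assignAgeGroups(cohort, binning)
    present <- table(groups) > 0
    if (!all(present)) {
        keep <- names(present)[present]
        binning <- AgeBinning(keep,
                              binning@ageLo[match(keep, binning@labels)],
                              binning@ageHi[match(keep, binning@labels)])
        groups <- factor(as.character(groups), levels = keep)
    }
    sc <- intervalScenario(intervalId, binning)
    youngIdx <- which(as.integer(groups) == sc@youngBin)
    agedIdx <- which(as.integer(groups) == sc@agedBin)
    if (length(youngIdx) == 0L || length(agedIdx) == 0L)
        stop("a training bin contains no subjects")
    split <- balancedSplit(length(youngIdx), length(agedIdx), seed = seed)
    trainIdx <- c(youngIdx[split@trainYoung], agedIdx[split@trainAged])
    trainLab <- rep(c("young", "aged"), each = split@m)
    residIdx <- if (split@largerClass == "young")
        youngIdx[split@residual] else agedIdx[split@residual]

    fm <- t(featureMatrix(cohort))
    model <- trainClassifier(fm[trainIdx, , drop = FALSE], trainLab,
                             cost = cost)
    ar <- validationAccuracy(model, fm[residIdx, , drop = FALSE],
                             split@largerClass)

    testIdx <- which(as.integer(groups) %in% sc@testBins)
    pred <- predictClassifier(model, fm[testIdx, , drop = FALSE])
    raw <- percentAgedByAge(pred, ages(cohort)[testIdx])
    if (!is.null(tailCutoff)) {
        tail <- raw$age >= tailCutoff
        if (any(tail) && all(raw$n[tail] < tailMinCount))
            raw <- poolTailAges(raw, tailCutoff)
    }
    smooth <- slidingWindow(raw, width = window)
    trS <- fitLinearTrend(smooth)
    rhoS <- spearmanMonotonicity(smooth)
    trR <- fitLinearTrend(raw)
    rhoR <- spearmanMonotonicity(raw)
    hyp <- selectHypothesis(intervalId, trS[["beta0"]], trS[["beta1"]],
                            rhoS, series = smooth)
    new("MonotonicityResult", scenario = sc, dataset = dataset,
        m = split@m, k = split@k, validationAccuracy = ar,
        rawSeries = raw, smoothedSeries = smooth,
        beta0 = trS[["beta0"]], beta1 = trS[["beta1"]], spearmanRho = rhoS,
        rawBeta0 = trR[["beta0"]], rawBeta1 = trR[["beta1"]],
        rawSpearmanRho = rhoR, hypothesis = hyp,
        window = as.integer(window), seed = as.integer(seed))
}
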