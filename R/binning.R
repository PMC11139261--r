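#' Decade-based binning schemes of the reference datasets
#'
#' The published age-group schemes of the four cohorts the analysis was
#' designed around: \code{"1000FCP"} (and its \code{"NKI-RS"} constituent
#' centre) with bins 21--30 through 71+, \code{"SRPBS"} with 18--30 through
#' 61+ (the sparse 61--70 and 71+ decades pooled), and \code{"camCAN"} with
#' 18--30 through 81+.
#'
#' @param dataset dataset label.
#' @return an \linkS4class{AgeBinning}.
#' @examples
#' datasetBinning("camCAN")
#' @export
datasetBinning <- function(dataset = c("1000FCP", "SRPBS", "camCAN",
                                       "NKI-RS")) {
    dataset <- match.arg(dataset)
    switch(dataset,
        "1000FCP" = ,
        "NKI-RS" = AgeBinning(
            c("21-30", "31-40", "41-50", "51-60", "61-70", "71+"),
            c(21, 31, 41, 51, 61, 71), c(30, 40, 50, 60, 70, Inf)),
        "SRPBS" = AgeBinning(
            c("18-30", "31-40", "41-50", "51-60", "61+"),
            c(18, 31, 41, 51, 61), c(30, 40, 50, 60, Inf)),
        "camCAN" = AgeBinning(
            c("18-30", "31-40", "41-50", "51-60", "61-70", "71-80", "81+"),
            c(18, 31, 41, 51, 61, 71, 81), c(30, 40, 50, 60, 70, 80, Inf)))
}

#' Published per-group subject counts of the reference datasets
#'
#' The (male, female) subject counts per age group of the four reference
#' cohorts, aligned with \code{\link{datasetBinning}}. These printed counts
#' are the inputs from which the balanced-training bookkeeping (training,
#' validation and test sizes per interval) is reproduced.
#'
#' @param dataset dataset label.
#' @return data.frame with columns \code{label}, \code{nMale},
#'   \code{nFemale}, \code{n}.
#' @examples
#' datasetGroupSizes("1000FCP")
#' @export
datasetGroupSizes <- function(dataset = c("1000FCP", "SRPBS", "camCAN",
                                          "NKI-RS")) {
    dataset <- match.arg(dataset)
    b <- datasetBinning(dataset)
    counts <- switch(dataset,
        "1000FCP" = cbind(c(215, 44, 40, 38, 22, 14),
                          c(243, 41, 79, 81, 45, 25)),
        # 61+ pools the published 61-70 (30, 31) and 71+ (8, 3) decades
        "SRPBS" = cbind(c(227, 81, 48, 29, 38),
                        c(100, 45, 67, 40, 34)),
        "camCAN" = cbind(c(35, 56, 43, 54, 56, 55, 23),
                         c(44, 49, 58, 47, 48, 62, 22)),
        "NKI-RS" = cbind(c(37, 8, 16, 12, 13, 11),
                         c(28, 19, 55, 55, 32, 21)))
    data.frame(label = binLabels(b), nMale = counts[, 1L],
               nFemale = counts[, 2L], n = rowSums(counts))
}

#' Assign subjects to age bins
#'
#' Maps each subject's age to the unique bin containing it. Subjects whose
#' age falls outside every bin are excluded (returned as \code{NA}) with a
#' message reporting how many were dropped.
#'
#' @param x a \linkS4class{ConnectomeCohort} or a numeric vector of ages.
#' @param binning an \linkS4class{AgeBinning}.
#' @return factor of bin labels (levels in bin order), \code{NA} for
#'   excluded subjects.
#' @examples
#' assignAgeGroups(c(25, 35, 90), datasetBinning("SRPBS"))
#' @export
setGeneric("assignAgeGroups",
           function(x, binning) standardGeneric("assignAgeGroups"))

#' @rdname assignAgeGroups
setMethod("assignAgeGroups", "numeric", function(x, binning) {
    validObject(binning)
    idx <- rep(NA_integer_, length(x))
    for (b in seq_len(nBins(binning))) {
        inb <- x >= binning@ageLo[b] & x <= binning@ageHi[b]
        idx[inb] <- b
    }
    nOut <- sum(is.na(idx))
    if (nOut > 0)
        message(nOut, " subject(s) outside all age bins were excluded")
    factor(binning@labels[idx], levels = binning@labels)
})

#' @rdname assignAgeGroups
setMethod("assignAgeGroups", "ConnectomeCohort", function(x, binning) {
    assignAgeGroups(as.numeric(ages(x)), binning)
})

#' Build the interval scenario for a binning
#'
#' Encodes the three test designs on an ordered binning: interval 1 trains
#' on the first and last bins and tests everything between; interval 2
#' trains on the first two bins and tests all later bins; interval 3 trains
#' on the last two bins and tests all earlier bins.
#'
#' @param intervalId 1, 2 or 3.
#' @param binning an \linkS4class{AgeBinning} with at least 3 bins.
#' @return an \linkS4class{IntervalScenario}.
#' @examples
#' intervalScenario(1, datasetBinning("1000FCP"))
#' @export
intervalScenario <- function(intervalId, binning) {
    validObject(binning)
    nb <- nBins(binning)
    intervalId <- as.integer(intervalId)
    if (!intervalId %in% 1:3) stop("intervalId must be 1, 2 or 3")
    if (nb < 3L)
        stop("interval scenarios need at least 3 bins; binning has ", nb,
             " so there are no test bins")
    sc <- switch(intervalId,
        new("IntervalScenario", intervalId = 1L, youngBin = 1L,
            agedBin = nb, testBins = seq(2L, nb - 1L)),
        new("IntervalScenario", intervalId = 2L, youngBin = 1L,
            agedBin = 2L, testBins = seq(3L, nb)),
        new("IntervalScenario", intervalId = 3L, youngBin = nb - 1L,
            agedBin = nb, testBins = seq_len(nb - 2L)))
    validObject(sc)
    sc
}

#' Balanced-training bookkeeping from group counts alone
#'
#' Given the per-bin subject counts and an interval, computes the balanced
#' per-class training size \eqn{m = \min(N_1, N_2)}, total training size
#' \eqn{2m}, residual validation count \eqn{k = \max(N_1, N_2) - m} and the
#' test-set size (sum of the unseen bins).
#'
#' @param nPerBin integer vector of subject counts per bin, in bin order.
#' @param intervalId 1, 2 or 3.
#' @return list with \code{m}, \code{trainingSize}, \code{k},
#'   \code{testSize}.
#' @examples
#' scenarioBookkeeping(datasetGroupSizes("1000FCP")$n, 1)
#' @export
scenarioBookkeeping <- function(nPerBin, intervalId) {
    nb <- length(nPerBin)
    b <- AgeBinning(paste0("b", seq_len(nb)), seq_len(nb) * 10,
                    seq_len(nb) * 10 + 9)
    sc <- intervalScenario(intervalId, b)
    n1 <- nPerBin[sc@youngBin]; n2 <- nPerBin[sc@agedBin]
    m <- min(n1, n2)
    list(m = as.integer(m), trainingSize = as.integer(2L * m),
         k = as.integer(max(n1, n2) - m),
         testSize = as.integer(sum(nPerBin[sc@testBins])))
}
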