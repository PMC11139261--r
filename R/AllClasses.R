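#' @import methods
#' @importFrom S4Vectors DataFrame metadata SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' ConnectomeCohort: a cohort of subjects with connectivity features
#'
#' An S4 container for a cohort of resting-state fMRI subjects, extending
#' \linkS4class{SummarizedExperiment}. The single assay, \code{"features"},
#' holds one column per subject and one row per unordered ROI pair (edge):
#' the Pearson correlation between the two regions' time courses. Edges are
#' ordered row-major along the upper triangle of the \eqn{R \times R}
#' correlation matrix, i.e. (1,2), (1,3), ..., (1,R), (2,3), ... so the
#' feature vector has length \eqn{R(R-1)/2} (see
#' \code{\link{featureDimension}}).
#'
#' Subject metadata live in \code{colData}: \code{age} (integer years),
#' \code{sex} (\code{"M"}/\code{"F"}), \code{site} (recording centre) and
#' \code{eyes} (\code{"open"}, \code{"closed"} or \code{NA}). The ROI count
#' is stored in \code{metadata(x)$nRois}.
#'
#' @slot .Data inherited SummarizedExperiment representation.
#'
#' @seealso \code{\link{ConnectomeCohort}} (constructor),
#'   \code{\link{generateCohort}}, \code{\link{readCohort}}
#' @exportClass ConnectomeCohort
setClass("ConnectomeCohort", contains = "SummarizedExperiment")

setValidity("ConnectomeCohort", function(object) {
    msg <- NULL
    R <- metadata(object)$nRois
    if (is.null(R) || !is.numeric(R) || length(R) != 1L || R < 2)
        return("metadata(x)$nRois must be a single integer >= 2")
    if (!"features" %in% SummarizedExperiment::assayNames(object))
        return("assay 'features' is missing")
    if (nrow(object) != R * (R - 1) / 2)
        msg <- c(msg, sprintf("number of edges (%d) != R(R-1)/2 = %d for R = %d",
                              nrow(object), R * (R - 1) / 2, R))
    cd <- colData(object)
    req <- c("age", "sex", "site", "eyes")
    miss <- setdiff(req, colnames(cd))
    if (length(miss))
        return(paste("colData lacks columns:", paste(miss, collapse = ", ")))
    if (ncol(object) > 0) {
        if (any(!is.finite(cd$age)) || any(cd$age < 0))
            msg <- c(msg, "ages must be finite and >= 0")
        if (!all(cd$sex %in% c("M", "F")))
            msg <- c(msg, "sex must be 'M' or 'F'")
        f <- assay(object, "features")
        if (any(!is.finite(f)) || any(f < -1) || any(f > 1))
            msg <- c(msg, "features must be finite correlations in [-1, 1]")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a ConnectomeCohort
#'
#' @param features numeric matrix of edge correlations with one row per
#'   subject and \eqn{R(R-1)/2} columns in row-major upper-triangle order
#'   (the orientation feature CSV files use). Stored internally with edges
#'   in rows, subjects in columns.
#' @param age integer vector of ages in years, one per subject.
#' @param sex character vector, \code{"M"} or \code{"F"}.
#' @param nRois number of ROIs \eqn{R}; the feature count must equal
#'   \eqn{R(R-1)/2}.
#' @param id subject identifiers (unique); defaults to \code{S1, S2, ...}.
#' @param site recording-centre label per subject.
#' @param eyes arousal state per subject: \code{"open"}, \code{"closed"} or
#'   \code{NA}.
#' @param metadata list of extra cohort-level metadata.
#'
#' @return a \linkS4class{ConnectomeCohort}.
#' @examples
#' f <- matrix(runif(3 * 3, -0.5, 0.5), nrow = 3)
#' cc <- ConnectomeCohort(f, age = c(25, 40, 70), sex = c("M", "F", "M"),
#'                        nRois = 3)
#' cc
#' @export
ConnectomeCohort <- function(features, age, sex, nRois,
                             id = NULL, site = "unknown", eyes = NA_character_,
                             metadata = list()) {
    features <- as.matrix(features)
    n <- nrow(features)
    if (is.null(id)) id <- paste0("S", seq_len(n))
    if (anyDuplicated(id))
        stop("duplicated subject ids: ",
             paste(unique(id[duplicated(id)]), collapse = ", "))
    nRois <- as.integer(nRois)
    E <- featureDimension(nRois)
    if (ncol(features) != E)
        stop(sprintf("feature vectors have length %d but R = %d ROIs requires R(R-1)/2 = %d",
                     ncol(features), nRois, E))
    cd <- DataFrame(age = as.integer(age),
                    sex = as.character(sex),
                    site = rep_len(as.character(site), n),
                    eyes = rep_len(as.character(eyes), n),
                    row.names = id)
    fm <- t(features)
    rownames(fm) <- edgeNames(nRois)
    colnames(fm) <- id
    md <- c(list(nRois = nRois), metadata)
    se <- SummarizedExperiment(assays = list(features = fm),
                               colData = cd, metadata = md)
    new("ConnectomeCohort", se)
}

#' CohortConfig: parameters of the synthetic connectome-cohort generator
#'
#' Describes a synthetic cohort in terms of its age-group structure and a
#' Fisher-z additive edge model: each edge's latent z-value is a class
#' baseline (within- or between-network) plus an age-drift term (applied to
#' a fixed random subset of edges, scaled per sex) plus Gaussian
#' inter-subject noise whose s.d. may itself depend on age; observed
#' correlations are \code{tanh} of the latent z. See
#' \code{\link{cohortConfig}} for the fields.
#'
#' @seealso \code{\link{cohortConfig}}, \code{\link{scenarioPreset}},
#'   \code{\link{generateCohort}}
#' @exportClass CohortConfig
setClass("CohortConfig", representation(
    nRois = "integer",
    nTimepoints = "integer",
    groupSpec = "data.frame",
    baseZ = "numeric",
    nBlocks = "integer",
    driftProfile = "character",
    driftMagnitude = "numeric",
    affectedFraction = "numeric",
    sdProfile = "character",
    sdBase = "numeric",
    plateauAge = "numeric",
    sexEffectMultiplier = "numeric",
    sites = "character",
    eyes = "character",
    seed = "integer"
))

setValidity("CohortConfig", function(object) {
    msg <- NULL
    if (object@nRois < 2L) msg <- c(msg, "nRois must be >= 2")
    gs <- object@groupSpec
    need <- c("ageLo", "ageHi", "nMale", "nFemale")
    if (!all(need %in% colnames(gs)))
        return(paste("groupSpec needs columns:", paste(need, collapse = ", ")))
    if (nrow(gs) < 1L) msg <- c(msg, "groupSpec must have at least one row")
    num <- unlist(gs[need])
    if (any(!is.finite(num))) msg <- c(msg, "groupSpec values must be finite")
    if (any(gs$nMale < 0) || any(gs$nFemale < 0))
        msg <- c(msg, "group counts must be >= 0")
    if (any(gs$ageHi < gs$ageLo)) msg <- c(msg, "ageHi < ageLo in groupSpec")
    if (!all(is.finite(object@baseZ)))
        msg <- c(msg, "baseZ must be finite")
    if (!object@driftProfile %in%
          c("linear_monotone", "plateau_after", "inverted_u", "null"))
        msg <- c(msg, "unknown driftProfile")
    if (!object@sdProfile %in% c("constant", "inverted_u", "decreasing"))
        msg <- c(msg, "unknown sdProfile")
    if (!is.finite(object@driftMagnitude))
        msg <- c(msg, "driftMagnitude must be finite")
    if (!is.finite(object@affectedFraction) ||
          object@affectedFraction < 0 || object@affectedFraction > 1)
        msg <- c(msg, "affectedFraction must lie in [0, 1]")
    if (!is.finite(object@sdBase) || object@sdBase <= 0)
        msg <- c(msg, "sdBase must be a positive finite s.d.")
    if (!is.finite(object@sexEffectMultiplier))
        msg <- c(msg, "sexEffectMultiplier must be finite")
    if (is.null(msg)) TRUE else msg
})

#' AgeBinning: an ordered decade-style age-group scheme
#'
#' Ordered, non-overlapping age bins with inclusive bounds, e.g. the
#' decade-based groups 21--30, 31--40, ..., 71+ used for large multi-site
#' rsfMRI cohorts. \code{ageHi = Inf} encodes an open-ended terminal bin.
#'
#' @slot labels bin labels.
#' @slot ageLo,ageHi inclusive bounds per bin.
#' @seealso \code{\link{AgeBinning}}, \code{\link{datasetBinning}},
#'   \code{\link{assignAgeGroups}}
#' @exportClass AgeBinning
setClass("AgeBinning", representation(
    labels = "character", ageLo = "numeric", ageHi = "numeric"))

setValidity("AgeBinning", function(object) {
    n <- length(object@labels)
    if (length(object@ageLo) != n || length(object@ageHi) != n)
        return("labels, ageLo, ageHi must have equal length")
    if (n == 0L) return("binning must contain at least one bin")
    if (any(object@ageHi < object@ageLo)) return("ageHi < ageLo")
    if (is.unsorted(object@ageLo, strictly = TRUE))
        return("bins must be ordered by increasing ageLo")
    if (n > 1L && any(object@ageLo[-1L] <= object@ageHi[-n]))
        return("bins overlap")
    TRUE
})

#' Construct an AgeBinning
#'
#' @param labels character bin labels.
#' @param ageLo,ageHi numeric inclusive bounds (use \code{Inf} for an
#'   open-ended last bin).
#' @return an \linkS4class{AgeBinning}.
#' @examples
#' AgeBinning(c("21-30", "31-40", "41+"), c(21, 31, 41), c(30, 40, Inf))
#' @export
AgeBinning <- function(labels, ageLo, ageHi) {
    new("AgeBinning", labels = as.character(labels),
        ageLo = as.numeric(ageLo), ageHi = as.numeric(ageHi))
}

#' IntervalScenario: which bins train the classifier and which are tested
#'
#' The three designs for probing monotonic brain aging: train on the two
#' extreme age groups and test everything in between (interval 1); train on
#' the two youngest groups and test all older subjects (interval 2); train
#' on the two oldest groups and test all younger subjects (interval 3).
#'
#' @slot intervalId 1, 2 or 3.
#' @slot youngBin,agedBin indices of the training bins.
#' @slot testBins indices of the unseen test bins.
#' @seealso \code{\link{intervalScenario}}
#' @exportClass IntervalScenario
setClass("IntervalScenario", representation(
    intervalId = "integer", youngBin = "integer",
    agedBin = "integer", testBins = "integer"))

setValidity("IntervalScenario", function(object) {
    msg <- NULL
    if (!object@intervalId %in% 1:3) msg <- c(msg, "intervalId must be 1, 2 or 3")
    if (object@youngBin >= object@agedBin)
        msg <- c(msg, "youngBin must precede agedBin")
    if (any(object@testBins %in% c(object@youngBin, object@agedBin)))
        msg <- c(msg, "testBins must be disjoint from the training bins")
    if (length(object@testBins) < 1L)
        msg <- c(msg, "scenario has no test bins")
    if (is.null(msg)) TRUE else msg
})

#' BalancedSplit: the balanced training draw and its residual
#'
#' Given group sizes \eqn{N_1} (young) and \eqn{N_2} (aged), training uses
#' \eqn{m = \min(N_1, N_2)} subjects per class -- all of the smaller group
#' and a seeded uniform subsample of the larger -- and the
#' \eqn{k = \max(N_1,N_2) - m} left-out subjects of the larger group form
#' the validation (residual) set.
#'
#' @slot m training size per class.
#' @slot k residual (validation) size.
#' @slot trainYoung,trainAged indices (within each group) used for training.
#' @slot residual indices of the larger group left out for validation.
#' @slot largerClass \code{"young"} or \code{"aged"}: which group was
#'   subsampled.
#' @slot seed RNG seed used for the draw.
#' @seealso \code{\link{balancedSplit}}
#' @exportClass BalancedSplit
setClass("BalancedSplit", representation(
    m = "integer", k = "integer",
    trainYoung = "integer", trainAged = "integer",
    residual = "integer", largerClass = "character", seed = "integer"))

setValidity("BalancedSplit", function(object) {
    msg <- NULL
    if (length(object@trainYoung) != object@m ||
        length(object@trainAged) != object@m)
        msg <- c(msg, "training sets must each have m subjects")
    if (length(object@residual) != object@k)
        msg <- c(msg, "residual set must have k subjects")
    train <- if (identical(object@largerClass, "young"))
        object@trainYoung else object@trainAged
    if (length(intersect(train, object@residual)))
        msg <- c(msg, "residual overlaps the training draw")
    if (is.null(msg)) TRUE else msg
})

#' MonotonicityResult: full output of one interval analysis
#'
#' Bundles the bookkeeping (m, k), the validation accuracy AR, the raw and
#' smoothed percent-classified-aged series, the linear-trend coefficients
#' and Spearman rank correlation for both series, and the selected
#' aging-trajectory hypothesis.
#'
#' @slot scenario the \linkS4class{IntervalScenario} analysed.
#' @slot dataset dataset label.
#' @slot m,k balanced training size per class and residual count.
#' @slot validationAccuracy AR in [0, 1], or \code{NA} when k = 0.
#' @slot rawSeries,smoothedSeries data.frames with columns \code{age},
#'   \code{percentAged}, \code{n}.
#' @slot beta0,beta1,spearmanRho trend fit and monotonicity of the smoothed
#'   series (x measured in years since the youngest test age).
#' @slot rawBeta0,rawBeta1,rawSpearmanRho same statistics on the raw series.
#' @slot hypothesis selected label: \code{"H1"}, \code{"H2"}, \code{"H3"}
#'   or \code{"inconclusive"}.
#' @slot window sliding-window width in years (1 = no smoothing).
#' @slot seed RNG seed of the run.
#' @seealso \code{\link{runMonotonicity}}
#' @exportClass MonotonicityResult
setClass("MonotonicityResult", representation(
    scenario = "IntervalScenario", dataset = "character",
    m = "integer", k = "integer", validationAccuracy = "numeric",
    rawSeries = "data.frame", smoothedSeries = "data.frame",
    beta0 = "numeric", beta1 = "numeric", spearmanRho = "numeric",
    rawBeta0 = "numeric", rawBeta1 = "numeric", rawSpearmanRho = "numeric",
    hypothesis = "character", window = "integer", seed = "integer"))
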