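#' @include AllClasses.R
NULL

#' Accessors for ConnectomeCohort and result objects
#'
#' \code{nRois} returns the ROI count R; \code{featureMatrix} the edge
#' correlation matrix (edges in rows, subjects in columns); \code{ages},
#' \code{sexes}, \code{sites} and \code{eyesState} the subject metadata
#' columns; \code{nBins} and \code{binLabels} describe an
#' \linkS4class{AgeBinning}; \code{hypothesis}, \code{trendFit} and
#' \code{spearmanRho} extract the headline statistics of a
#' \linkS4class{MonotonicityResult}.
#'
#' @param x a \linkS4class{ConnectomeCohort}, \linkS4class{AgeBinning} or
#'   \linkS4class{MonotonicityResult} as appropriate.
#' @return the requested component.
#' @name cohort-accessors
#' @aliases nRois featureMatrix ages sexes sites eyesState nBins binLabels
#'   hypothesis trendFit spearmanRho
#' @examples
#' cfg <- scenarioPreset("null")
#' cc <- generateCohort(cfg)
#' nRois(cc); head(ages(cc)); table(sexes(cc))
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("nRois", function(x) standardGeneric("nRois"))
#' @rdname cohort-accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @rdname cohort-accessors
#' @export
setGeneric("ages", function(x) standardGeneric("ages"))
#' @rdname cohort-accessors
#' @export
setGeneric("sexes", function(x) standardGeneric("sexes"))
#' @rdname cohort-accessors
#' @export
setGeneric("sites", function(x) standardGeneric("sites"))
#' @rdname cohort-accessors
#' @export
setGeneric("eyesState", function(x) standardGeneric("eyesState"))
#' @rdname cohort-accessors
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))
#' @rdname cohort-accessors
#' @export
setGeneric("binLabels", function(x) standardGeneric("binLabels"))
#' @rdname cohort-accessors
#' @export
setGeneric("hypothesis", function(x) standardGeneric("hypothesis"))
#' @rdname cohort-accessors
#' @export
setGeneric("trendFit", function(x) standardGeneric("trendFit"))
#' @rdname cohort-accessors
#' @export
setGeneric("spearmanRho", function(x) standardGeneric("spearmanRho"))

#' @rdname cohort-accessors
setMethod("nRois", "ConnectomeCohort", function(x) metadata(x)$nRois)
#' @rdname cohort-accessors
setMethod("featureMatrix", "ConnectomeCohort",
          function(x) assay(x, "features"))
#' @rdname cohort-accessors
setMethod("ages", "ConnectomeCohort", function(x) colData(x)$age)
#' @rdname cohort-accessors
setMethod("sexes", "ConnectomeCohort", function(x) colData(x)$sex)
#' @rdname cohort-accessors
setMethod("sites", "ConnectomeCohort", function(x) colData(x)$site)
#' @rdname cohort-accessors
setMethod("eyesState", "ConnectomeCohort", function(x) colData(x)$eyes)

#' @rdname cohort-accessors
setMethod("nBins", "AgeBinning", function(x) length(x@labels))
#' @rdname cohort-accessors
setMethod("binLabels", "AgeBinning", function(x) x@labels)

#' @rdname cohort-accessors
setMethod("hypothesis", "MonotonicityResult", function(x) x@hypothesis)
#' @rdname cohort-accessors
setMethod("trendFit", "MonotonicityResult",
          function(x) c(beta0 = x@beta0, beta1 = x@beta1))
#' @rdname cohort-accessors
setMethod("spearmanRho", "MonotonicityResult", function(x) x@spearmanRho)

setMethod("show", "ConnectomeCohort", function(object) {
    cat("ConnectomeCohort with", ncol(object), "subjects,",
        nRois(object), "ROIs (", nrow(object), "edges )\n")
    if (ncol(object) > 0) {
        cat("  ages:", min(ages(object)), "-", max(ages(object)),
            " sex: ", sum(sexes(object) == "M"), "M /",
            sum(sexes(object) == "F"), "F\n")
        cat("  sites:", paste(unique(sites(object)), collapse = ", "), "\n")
    }
})

setMethod("show", "AgeBinning", function(object) {
    cat("AgeBinning with", nBins(object), "bins:\n")
    hi <- ifelse(is.finite(object@ageHi), object@ageHi, "")
    cat(" ", paste0(object@labels, " [", object@ageLo, ", ",
                    ifelse(hi == "", "Inf", hi), "]", collapse = "  "), "\n")
})

setMethod("show", "IntervalScenario", function(object) {
    cat("IntervalScenario", object@intervalId,
        ": train bins (", object@youngBin, ",", object@agedBin,
        "), test bins", paste(object@testBins, collapse = ","), "\n")
})

setMethod("show", "BalancedSplit", function(object) {
    cat("BalancedSplit: m =", object@m, "per class (training size",
        2L * object@m, "), k =", object@k, "residual from the",
        object@largerClass, "group\n")
})

setMethod("show", "MonotonicityResult", function(object) {
    cat("MonotonicityResult [", object@dataset, ", interval",
        object@scenario@intervalId, "]\n")
    ar <- if (is.na(object@validationAccuracy)) "NA (k = 0)"
          else sprintf("%.3f", object@validationAccuracy)
    cat(sprintf("  training size %d (m = %d/class), residual k = %d, AR = %s\n",
                2L * object@m, object@m, object@k, ar))
    cat(sprintf("  test subjects: %d over %d ages\n",
                sum(object@rawSeries$n), nrow(object@rawSeries)))
    cat(sprintf("  smoothed (window %d): beta0 = %.3f, beta1 = %.3f, Spearman rho = %.3f\n",
                object@window, object@beta0, object@beta1, object@spearmanRho))
    cat(sprintf("  raw:                 beta0 = %.3f, beta1 = %.3f, Spearman rho = %.3f\n",
                object@rawBeta0, object@rawBeta1, object@rawSpearmanRho))
    cat("  selected hypothesis:", object@hypothesis, "\n")
})
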