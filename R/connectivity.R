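#' Number of unique edge features for R ROIs
#'
#' The connectivity pattern of a subject with \eqn{R} regions of interest
#' consists of the \eqn{R(R-1)/2} Pearson correlations between distinct
#' ROI pairs; parcellations of 42, 140 and 808 regions yield 861, 9730 and
#' 326,028 features respectively.
#'
#' @param nRois integer number of ROIs, at least 2.
#' @return integer \eqn{R(R-1)/2}.
#' @examples
#' featureDimension(42)   # 861
#' featureDimension(140)  # 9730
#' @export
featureDimension <- function(nRois) {
    nRois <- as.integer(nRois)
    if (length(nRois) != 1L || is.na(nRois) || nRois < 2L)
        stop("nRois must be a single integer >= 2")
    as.integer(nRois * (nRois - 1L) / 2L)
}

#' Edge index table for the upper triangle, row-major
#'
#' The fixed edge order used throughout the package: for \eqn{i < j},
#' pairs are enumerated (1,2), (1,3), ..., (1,R), (2,3), ..., (R-1,R).
#'
#' @param nRois integer number of ROIs.
#' @return two-column integer matrix (\code{i}, \code{j}) with
#'   \eqn{R(R-1)/2} rows.
#' @examples
#' edgePairs(4)
#' @export
edgePairs <- function(nRois) {
    nRois <- as.integer(nRois)
    i <- rep.int(seq_len(nRois - 1L), times = (nRois - 1L):1L)
    j <- sequence((nRois - 1L):1L) + i
    cbind(i = i, j = j)
}

edgeNames <- function(nRois, roiNames = NULL) {
    ep <- edgePairs(nRois)
    if (is.null(roiNames)) roiNames <- paste0("ROI", seq_len(nRois))
    paste0(roiNames[ep[, 1L]], "_", roiNames[ep[, 2L]])
}

#' Pearson-correlation features from ROI time courses
#'
#' Computes the Pearson correlation coefficient between the time courses of
#' every unordered ROI pair and returns them as a feature vector in the
#' package's fixed row-major upper-triangle order (see
#' \code{\link{edgePairs}}).
#'
#' @param timecourses numeric T x R matrix: one column per ROI, one row per
#'   time point. Column names, when present, name the edges.
#' @return named numeric vector of length \eqn{R(R-1)/2}, all values in
#'   [-1, 1].
#' @examples
#' tc <- matrix(rnorm(300), ncol = 3)
#' pccFeatures(tc)
#' @export
pccFeatures <- function(timecourses) {
    tc <- as.matrix(timecourses)
    if (!is.numeric(tc)) stop("timecourses must be numeric")
    Tn <- nrow(tc); R <- ncol(tc)
    if (R < 2L) stop("need at least 2 ROI columns")
    if (Tn < 3L) stop("need at least 3 time points, got ", Tn)
    v <- apply(tc, 2L, stats::var)
    if (any(v == 0)) {
        bad <- which(v == 0)
        nm <- colnames(tc)
        lab <- if (is.null(nm)) paste0("ROI", bad) else nm[bad]
        stop("zero-variance ROI column(s): ", paste(lab, collapse = ", "))
    }
    cm <- stats::cor(tc)
    ep <- edgePairs(R)
    out <- cm[ep]
    names(out) <- edgeNames(R, colnames(tc))
    out
}

#' Rebuild a correlation matrix from an edge feature vector
#'
#' Inverse of the upper-triangle row-major vectorisation: places the
#' \eqn{R(R-1)/2} edge values back into a symmetric \eqn{R \times R} matrix
#' with unit diagonal.
#'
#' @param features numeric edge vector of length \eqn{R(R-1)/2}.
#' @param nRois number of ROIs R.
#' @return symmetric R x R matrix.
#' @examples
#' vecToCorr(c(0.2, -0.1, 0.5), nRois = 3)
#' @export
vecToCorr <- function(features, nRois) {
    nRois <- as.integer(nRois)
    E <- featureDimension(nRois)
    if (length(features) != E)
        stop(sprintf("expected %d edge values for R = %d, got %d",
                     E, nRois, length(features)))
    m <- diag(nrow = nRois)
    ep <- edgePairs(nRois)
    m[ep] <- features
    m[ep[, c(2L, 1L)]] <- features
    m
}

#' Count signed supra-threshold connections
#'
#' For a subject's edge-correlation vector, counts the connections whose
#' correlation strictly exceeds the magnitude threshold, separately for the
#' positive (\eqn{\rho > t}) and negative / anticorrelated
#' (\eqn{\rho < -t}) directions; the total is their sum. The customary
#' threshold is 0.6, with 0.45 and 0.7 used for sensitivity analyses.
#' Boundary values equal to the threshold are excluded (strict inequality).
#'
#' @param features numeric edge-correlation vector.
#' @param threshold magnitude threshold in (0, 1).
#' @return one-row data.frame with columns \code{nPos}, \code{nNeg},
#'   \code{nTotal}, \code{threshold}.
#' @examples
#' countFC(c(0.7, -0.65, 0.6, 0.59, -0.2), 0.6)   # 1 positive, 1 negative
#' @export
countFC <- function(features, threshold) {
    if (!is.numeric(threshold) || length(threshold) != 1L ||
        is.na(threshold) || threshold <= 0 || threshold >= 1)
        stop("threshold must be a single value in (0, 1)")
    if (any(!is.finite(features)))
        stop("features must be finite")
    nPos <- sum(features > threshold)
    nNeg <- sum(features < -threshold)
    data.frame(nPos = nPos, nNeg = nNeg, nTotal = nPos + nNeg,
               threshold = threshold)
}
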