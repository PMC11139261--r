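#' Balanced training split of two age groups
#'
#' With \eqn{N_1} young and \eqn{N_2} aged subjects, trains on
#' \eqn{m = \min(N_1, N_2)} subjects per class: the whole smaller group and
#' a seeded uniform random subsample of the larger. The
#' \eqn{k = \max(N_1, N_2) - m} left-out subjects of the larger group
#' become the validation (residual) set.
#'
#' @param nYoung,nAged group sizes \eqn{N_1}, \eqn{N_2} (>= 1).
#' @param seed integer RNG seed for the subsample draw.
#' @return a \linkS4class{BalancedSplit}; indices are within-group
#'   (1..N of each group).
#' @examples
#' balancedSplit(458, 39, seed = 1)   # m = 39, training 78, k = 419
#' @export
balancedSplit <- function(nYoung, nAged, seed = 1L) {
    nYoung <- as.integer(nYoung); nAged <- as.integer(nAged)
    if (is.na(nYoung) || is.na(nAged) || nYoung < 1L || nAged < 1L)
        stop("both groups must contain at least one subject")
    m <- min(nYoung, nAged)
    k <- max(nYoung, nAged) - m
    larger <- if (nYoung >= nAged) "young" else "aged"
    keep <- withSeed(seed, sample.int(max(nYoung, nAged), m))
    resid <- setdiff(seq_len(max(nYoung, nAged)), keep)
    split <- if (larger == "young")
        new("BalancedSplit", m = m, k = k, trainYoung = sort(keep),
            trainAged = seq_len(nAged), residual = sort(resid),
            largerClass = larger, seed = as.integer(seed))
    else
        new("BalancedSplit", m = m, k = k, trainYoung = seq_len(nYoung),
            trainAged = sort(keep), residual = sort(resid),
            largerClass = larger, seed = as.integer(seed))
    validObject(split)
    split
}

#' Train the linear max-margin age-group classifier
#'
#' Fits a binary support-vector machine with a linear kernel (hinge loss,
#' L2 regularisation, cost \code{C}) to class-balanced training data.
#' Features are standardised per edge using the training-set mean and s.d.;
#' the same transform is stored with the model and applied to any data it
#' later classifies. Constant (zero-s.d.) features are left unscaled.
#'
#' @param x numeric training matrix, one row per subject.
#' @param labels factor or character vector with levels \code{"young"} and
#'   \code{"aged"}.
#' @param cost SVM regularisation parameter C (default 1).
#' @return an object of class \code{"fcClassifier"}: the fitted SVM plus
#'   the standardisation parameters.
#' @seealso \code{\link{predictClassifier}}, \code{\link{validationAccuracy}}
#' @export
trainClassifier <- function(x, labels, cost = 1) {
    x <- as.matrix(x)
    labels <- factor(as.character(labels), levels = c("young", "aged"))
    if (anyNA(labels)) stop("labels must be 'young' or 'aged'")
    if (nlevels(droplevels(labels)) < 2L)
        stop("training data contain a single class")
    if (any(!is.finite(x))) stop("training features must be finite")
    ctr <- colMeans(x)
    scl <- apply(x, 2L, stats::sd)
    scl[scl == 0] <- 1
    xs <- scale(x, center = ctr, scale = scl)
    fit <- e1071::svm(xs, labels, kernel = "linear", cost = cost,
                      scale = FALSE)
    structure(list(svm = fit, center = ctr, scale = scl, cost = cost),
              class = "fcClassifier")
}

#' Classify subjects as young or aged
#'
#' Applies the stored training standardisation, evaluates the SVM decision
#' function and thresholds it at zero. A decision value of exactly zero is
#' assigned \code{"aged"} (a measure-zero tie-break).
#'
#' @param object an \code{"fcClassifier"} from \code{\link{trainClassifier}}.
#' @param x numeric matrix of subjects to classify (rows).
#' @return factor with levels \code{c("young", "aged")}.
#' @export
predictClassifier <- function(object, x) {
    stopifnot(inherits(object, "fcClassifier"))
    x <- as.matrix(x)
    xs <- scale(x, center = object$center, scale = object$scale)
    pr <- stats::predict(object$svm, xs, decision.values = TRUE)
    d <- drop(attr(pr, "decision.values"))
    # orient the decision value so that positive means the first label of
    # the libsvm ordering; map sign to class explicitly for the tie rule
    first <- object$svm$levels[object$svm$labels[1L]]
    aged <- if (identical(first, "aged")) d >= 0 else d <= 0
    factor(ifelse(aged, "aged", "young"), levels = c("young", "aged"))
}

#' Validation accuracy on the residual set
#'
#' The accuracy rate (AR): the fraction of the \eqn{k} left-out residual
#' subjects from the larger training group that the classifier assigns to
#' their true class. With \eqn{k = 0} (equal group sizes) the AR is
#' undefined and \code{NA} is returned with a message.
#'
#' @param object an \code{"fcClassifier"}.
#' @param x residual feature matrix (k rows).
#' @param truth true class of the residual subjects (\code{"young"} or
#'   \code{"aged"}, recycled if scalar).
#' @return AR in [0, 1], or \code{NA} when k = 0.
#' @export
validationAccuracy <- function(object, x, truth) {
    x <- as.matrix(x)
    if (nrow(x) == 0L) {
        message("no residual subjects (k = 0): AR is not applicable")
        return(NA_real_)
    }
    truth <- factor(rep_len(as.character(truth), nrow(x)),
                    levels = c("young", "aged"))
    pred <- predictClassifier(object, x)
    mean(pred == truth)
}
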