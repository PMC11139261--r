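#' Per-subject signed connection counts
#'
#' Applies \code{\link{countFC}} to every subject of a cohort: the number
#' of edges whose correlation strictly exceeds the magnitude threshold, in
#' the positive and negative (anticorrelation) directions and in total.
#'
#' @param cohort a \linkS4class{ConnectomeCohort}.
#' @param threshold magnitude threshold in (0, 1); 0.6 is the customary
#'   value, 0.45 and 0.7 the sensitivity settings.
#' @return data.frame with one row per subject: \code{id}, \code{age},
#'   \code{sex}, \code{nPos}, \code{nNeg}, \code{nTotal},
#'   \code{threshold}.
#' @export
fcCountsPerSubject <- function(cohort, threshold = 0.6) {
    fm <- featureMatrix(cohort)
    counts <- apply(fm, 2L, function(f) {
        cnt <- countFC(f, threshold)
        c(cnt$nPos, cnt$nNeg)
    })
    data.frame(id = colnames(fm), age = ages(cohort), sex = sexes(cohort),
               nPos = counts[1L, ], nNeg = counts[2L, ],
               nTotal = counts[1L, ] + counts[2L, ],
               threshold = threshold, row.names = NULL)
}

#' Welch two-sample t-test against a reference group
#'
#' Two-sided unequal-variance (Welch) t-test of \code{values} against
#' \code{referenceValues}, with significance declared at p < 0.05. Chosen
#' over the pooled-variance test because group variances of connection
#' counts differ visibly across age groups.
#'
#' @param values numeric sample of the group under test (>= 2 values).
#' @param referenceValues numeric sample of the reference (youngest) group.
#' @param alpha significance level.
#' @return list with \code{t}, \code{p}, \code{significant}.
#' @examples
#' ttestVsReference(c(10, 12, 9, 14), c(20, 22, 19, 25))
#' @export
ttestVsReference <- function(values, referenceValues, alpha = 0.05) {
    if (length(values) < 2L || length(referenceValues) < 2L)
        stop("both samples need at least 2 values")
    if (stats::sd(values) == 0 && stats::sd(referenceValues) == 0) {
        if (isTRUE(all.equal(mean(values), mean(referenceValues))))
            return(list(t = 0, p = 1, significant = FALSE))
        stop("degenerate samples: both have zero variance")
    }
    ht <- stats::t.test(values, referenceValues, var.equal = FALSE)
    list(t = unname(ht$statistic), p = ht$p.value,
         significant = ht$p.value < alpha)
}

#' Per-age-group (and per-sex) connection-count summary
#'
#' For each age bin -- and optionally separately for male and female
#' subjects -- computes the mean and sample s.d. (n - 1 denominator) of the
#' positive, negative and total supra-threshold connection counts, and
#' Welch-tests each count class against the youngest bin present within the
#' same sex stratum (p < 0.05). The reference rows carry \code{NA}
#' p-values; strata with fewer than 2 subjects are summarised but their
#' test is skipped (\code{testSkipped = TRUE}).
#'
#' @param cohort a \linkS4class{ConnectomeCohort}.
#' @param binning an \linkS4class{AgeBinning}.
#' @param threshold magnitude threshold in (0, 1).
#' @param stratifySex also emit per-sex rows (\code{stratum} "M"/"F") in
#'   addition to the pooled \code{"all"} rows.
#' @param adjust p-value adjustment across the non-reference tests of each
#'   stratum: \code{"none"} (default, fixed p < 0.05 criterion) or
#'   \code{"BH"}.
#' @return data.frame with one row per (bin, stratum): subject counts,
#'   means/s.d.s, p-values and significance flags per count class.
#' @export
summarizeFC <- function(cohort, binning, threshold = 0.6,
                        stratifySex = FALSE, adjust = c("none", "BH")) {
    adjust <- match.arg(adjust)
    counts <- fcCountsPerSubject(cohort, threshold)
    counts$group <- assignAgeGroups(cohort, binning)
    counts <- counts[!is.na(counts$group), , drop = FALSE]
    if (nrow(counts) == 0L) stop("no subjects fall inside the binning")
    strata <- if (stratifySex) c("all", "M", "F") else "all"
    out <- NULL
    for (st in strata) {
        sub <- if (st == "all") counts else counts[counts$sex == st, ,
                                                   drop = FALSE]
        present <- levels(droplevels(sub$group))
        if (length(present) == 0L) next
        ref <- present[1L]
        rows <- lapply(levels(counts$group), function(g) {
            gi <- sub[sub$group == g, , drop = FALSE]
            row <- data.frame(group = g, stratum = st, nSubjects = nrow(gi),
                              meanPos = mean(gi$nPos), sdPos = stats::sd(gi$nPos),
                              meanNeg = mean(gi$nNeg), sdNeg = stats::sd(gi$nNeg),
                              meanTotal = mean(gi$nTotal),
                              sdTotal = stats::sd(gi$nTotal),
                              pPos = NA_real_, pNeg = NA_real_,
                              pTotal = NA_real_, sigPos = FALSE,
                              sigNeg = FALSE, sigTotal = FALSE,
                              testSkipped = FALSE, threshold = threshold)
            refDat <- sub[sub$group == ref, , drop = FALSE]
            if (g != ref) {
                if (nrow(gi) < 2L || nrow(refDat) < 2L) {
                    row$testSkipped <- TRUE
                } else {
                    for (cls in c("Pos", "Neg", "Total")) {
                        v <- gi[[paste0("n", cls)]]
                        rv <- refDat[[paste0("n", cls)]]
                        p <- if (stats::sd(v) == 0 && stats::sd(rv) == 0) 1
                             else ttestVsReference(v, rv)$p
                        row[[paste0("p", cls)]] <- p
                    }
                }
            }
            row
        })
        tab <- do.call(rbind, rows)
        for (cls in c("Pos", "Neg", "Total")) {
            pc <- paste0("p", cls)
            if (adjust == "BH") {
                idx <- !is.na(tab[[pc]])
                tab[[pc]][idx] <- stats::p.adjust(tab[[pc]][idx],
                                                  method = "BH")
            }
            tab[[paste0("sig", cls)]] <- !is.na(tab[[pc]]) & tab[[pc]] < 0.05
        }
        out <- rbind(out, tab)
    }
    rownames(out) <- NULL
    out
}

#' Connection-count summaries across several thresholds
#'
#' Repeats \code{\link{summarizeFC}} for each threshold (e.g. 0.45, 0.6,
#' 0.7). Because the counting inequality is strict, every per-group mean
#' count is monotone non-increasing in the threshold.
#'
#' @param cohort a \linkS4class{ConnectomeCohort}.
#' @param binning an \linkS4class{AgeBinning}.
#' @param thresholds numeric vector of thresholds in (0, 1).
#' @param ... passed to \code{\link{summarizeFC}}.
#' @return named list of summary tables, one per threshold.
#' @export
thresholdSensitivity <- function(cohort, binning,
                                 thresholds = c(0.45, 0.6, 0.7), ...) {
    out <- lapply(thresholds, function(t)
        summarizeFC(cohort, binning, threshold = t, ...))
    names(out) <- as.character(thresholds)
    out
}

#' Filter a cohort by site, arousal state or sex
#'
#' Intersection semantics: subjects must match every provided predicate.
#' Used to repeat analyses on a single recording centre or on eyes-open
#' subjects only. An empty result is returned (with a warning), not an
#' error.
#'
#' @param cohort a \linkS4class{ConnectomeCohort}.
#' @param site,eyes,sex optional values to keep (vectors allowed);
#'   \code{NULL} means no constraint.
#' @return the filtered \linkS4class{ConnectomeCohort}; the applied filter
#'   is recorded in \code{metadata(x)$filters}.
#' @examples
#' cc <- generateCohort(scenarioPreset("null"))
#' filterCohort(cc, sex = "F")
#' @export
filterCohort <- function(cohort, site = NULL, eyes = NULL, sex = NULL) {
    keep <- rep(TRUE, ncol(cohort))
    if (!is.null(site)) keep <- keep & sites(cohort) %in% site
    if (!is.null(eyes)) keep <- keep & eyesState(cohort) %in% eyes
    if (!is.null(sex)) keep <- keep & sexes(cohort) %in% sex
    out <- cohort[, keep]
    if (ncol(out) == 0L)
        warning("filter matched no subjects: returning an empty cohort")
    md <- metadata(out)
    md$filters <- c(md$filters,
                    list(list(site = site, eyes = eyes, sex = sex,
                              nKept = sum(keep))))
    metadata(out) <- md
    out
}

#' @importFrom S4Vectors metadata<-
NULL
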