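#' Read a cohort from metadata and feature tables
#'
#' Loads a subject metadata CSV (columns \code{id}, \code{age}, \code{sex};
#' optional \code{site}, \code{eyes}) and a feature CSV with one row per
#' subject: an \code{id} column followed by the \eqn{R(R-1)/2} edge
#' correlations in row-major upper-triangle order. Rows are matched by id;
#' duplicated or mismatched ids and inconsistent feature lengths are
#' rejected with informative errors.
#'
#' @param metaPath path to the metadata CSV.
#' @param featuresPath path to the feature CSV.
#' @param nRois declared ROI count; when given, the feature length must
#'   equal \eqn{R(R-1)/2} exactly. When \code{NULL}, R is inferred from
#'   the feature length.
#' @return a \linkS4class{ConnectomeCohort}.
#' @seealso \code{\link{writeCohort}}
#' @export
readCohort <- function(metaPath, featuresPath, nRois = NULL) {
    meta <- utils::read.csv(metaPath, stringsAsFactors = FALSE)
    need <- c("id", "age", "sex")
    miss <- setdiff(need, colnames(meta))
    if (length(miss))
        stop("metadata lacks required columns: ", paste(miss, collapse = ", "))
    if (anyDuplicated(meta$id))
        stop("duplicated subject id(s) in metadata: ",
             paste(unique(meta$id[duplicated(meta$id)]), collapse = ", "))
    if (any(is.na(suppressWarnings(as.numeric(meta$age)))))
        stop("non-numeric ages in metadata")
    feat <- utils::read.csv(featuresPath, stringsAsFactors = FALSE,
                            check.names = FALSE)
    if (!"id" %in% colnames(feat))
        stop("feature table must have an 'id' column")
    if (anyDuplicated(feat$id))
        stop("duplicated subject id(s) in features: ",
             paste(unique(feat$id[duplicated(feat$id)]), collapse = ", "))
    if (!setequal(meta$id, feat$id))
        stop("metadata and feature ids do not match; missing from features: ",
             paste(setdiff(meta$id, feat$id), collapse = ", "),
             "; missing from metadata: ",
             paste(setdiff(feat$id, meta$id), collapse = ", "))
    feat <- feat[match(meta$id, feat$id), , drop = FALSE]
    fm <- as.matrix(feat[, setdiff(colnames(feat), "id"), drop = FALSE])
    storage.mode(fm) <- "double"
    E <- ncol(fm)
    if (!is.null(nRois)) {
        expected <- featureDimension(nRois)
        if (E != expected)
            stop(sprintf("feature vectors have length %d but R = %d ROIs requires %d",
                         E, as.integer(nRois), expected))
        R <- as.integer(nRois)
    } else {
        R <- (1 + sqrt(1 + 8 * E)) / 2
        if (abs(R - round(R)) > 1e-8)
            stop("feature length ", E, " is not R(R-1)/2 for any integer R; ",
                 "declare nRois explicitly")
        R <- as.integer(round(R))
    }
    ConnectomeCohort(fm, age = as.integer(meta$age), sex = meta$sex,
                     nRois = R, id = meta$id,
                     site = if ("site" %in% colnames(meta)) meta$site
                            else "unknown",
                     eyes = if ("eyes" %in% colnames(meta)) meta$eyes
                            else NA_character_)
}

#' Write a cohort as metadata and feature CSV files
#'
#' @param cohort a \linkS4class{ConnectomeCohort}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the two file paths written
#'   (\code{<prefix>_meta.csv}, \code{<prefix>_features.csv}).
#' @export
writeCohort <- function(cohort, dir, prefix = "cohort") {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    metaPath <- file.path(dir, paste0(prefix, "_meta.csv"))
    featPath <- file.path(dir, paste0(prefix, "_features.csv"))
    meta <- data.frame(id = colnames(cohort), age = ages(cohort),
                       sex = sexes(cohort), site = sites(cohort),
                       eyes = eyesState(cohort))
    utils::write.csv(meta, metaPath, row.names = FALSE)
    fm <- t(featureMatrix(cohort))
    feat <- data.frame(id = colnames(cohort), fm, check.names = FALSE)
    utils::write.csv(feat, featPath, row.names = FALSE)
    invisible(c(meta = metaPath, features = featPath))
}

#' Build a run configuration
#'
#' Assembles the settings of a full analysis: which intervals to run, the
#' binning, smoothing window, connection thresholds, subject filters, seed
#' and output directory.
#'
#' @param dataset dataset label (also selects
#'   \code{\link{datasetBinning}} when \code{binning} is \code{NULL} and
#'   the label is one of the reference datasets).
#' @param metaPath,featuresPath input CSV paths (may be \code{NULL} when a
#'   cohort object is passed to \code{\link{runFullAnalysis}} directly).
#' @param nRois declared ROI count or \code{NULL} to infer.
#' @param binning an \linkS4class{AgeBinning} or \code{NULL}.
#' @param intervals integer subset of 1:3.
#' @param window odd smoothing window in years.
#' @param thresholds connection-count thresholds.
#' @param site,eyes,sex optional subject filters.
#' @param stratifySex emit per-sex connection summaries.
#' @param seed integer RNG seed.
#' @param outDir output directory, or \code{NULL} to skip writing files.
#' @return a list of class \code{"RunConfig"}.
#' @export
runConfig <- function(dataset = "cohort", metaPath = NULL,
                      featuresPath = NULL, nRois = NULL, binning = NULL,
                      intervals = 1:3, window = 5L,
                      thresholds = c(0.45, 0.6, 0.7),
                      site = NULL, eyes = NULL, sex = NULL,
                      stratifySex = TRUE, seed = 1L, outDir = NULL) {
    if (is.null(binning) &&
        dataset %in% c("1000FCP", "SRPBS", "camCAN", "NKI-RS"))
        binning <- datasetBinning(dataset)
    cfg <- list(dataset = dataset, metaPath = metaPath,
                featuresPath = featuresPath, nRois = nRois,
                binning = binning, intervals = as.integer(intervals),
                window = as.integer(window),
                thresholds = as.numeric(thresholds),
                site = site, eyes = eyes, sex = sex,
                stratifySex = isTRUE(stratifySex), seed = as.integer(seed),
                outDir = outDir)
    class(cfg) <- "RunConfig"
    cfg
}

#' Read a run configuration from YAML
#'
#' Reads the fields of \code{\link{runConfig}} from a YAML file; a custom
#' binning is given as parallel lists \code{binning: \{labels, ageLo,
#' ageHi\}} (use \code{.inf} for an open last bin).
#'
#' @param path YAML file path.
#' @return a \code{"RunConfig"}.
#' @export
readRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    binning <- NULL
    if (!is.null(y$binning))
        binning <- AgeBinning(unlist(y$binning$labels),
                              unlist(y$binning$ageLo),
                              unlist(y$binning$ageHi))
    runConfig(dataset = if (is.null(y$dataset)) "cohort" else y$dataset,
              metaPath = y$metaPath, featuresPath = y$featuresPath,
              nRois = y$nRois, binning = binning,
              intervals = if (is.null(y$intervals)) 1:3
                          else unlist(y$intervals),
              window = if (is.null(y$window)) 5L else y$window,
              thresholds = if (is.null(y$thresholds)) c(0.45, 0.6, 0.7)
                           else unlist(y$thresholds),
              site = y$site, eyes = y$eyes, sex = y$sex,
              stratifySex = !isFALSE(y$stratifySex),
              seed = if (is.null(y$seed)) 1L else y$seed,
              outDir = y$outDir)
}

# Hash of the analytic settings (the output location is excluded, so the
# same analysis written to two places carries the same provenance hash).
configHash <- function(config) {
    flat <- config
    flat$outDir <- NULL
    flat$binning <- if (is.null(config$binning)) "" else
        paste(config$binning@labels, config$binning@ageLo,
              config$binning@ageHi, collapse = ";")
    fnv1aHash(vapply(flat, function(x)
        paste(format(x), collapse = ","), character(1)))
}

#' Run the complete analysis end-to-end
#'
#' Reproduces the full study on one cohort: for each requested interval the
#' monotonicity pipeline (\code{\link{runMonotonicity}}), and for each
#' threshold the per-decade connection-count summary
#' (\code{\link{summarizeFC}}, pooled and per sex when requested), after
#' applying any site/eyes/sex filters. Returns a machine-readable summary
#' whose \code{intervals} table carries, per interval: training size, test
#' size, \eqn{\beta_0}, \eqn{\beta_1}, Spearman rho, validation accuracy
#' AR, m, k and the selected hypothesis. When \code{config$outDir} is set,
#' writes \code{summary.json}, per-interval tidy series CSVs
#' (age, n, pctRaw, pctSmoothed) and one connection-summary CSV per
#' threshold; every file embeds the config hash and seed, so identical
#' config + seed reruns are byte-identical.
#'
#' @param config a \code{"RunConfig"} from \code{\link{runConfig}} or
#'   \code{\link{readRunConfig}}.
#' @param cohort optionally, an in-memory \linkS4class{ConnectomeCohort};
#'   when \code{NULL} the cohort is read from the config's CSV paths.
#' @return invisibly, a list with elements \code{summary} (the JSON
#'   payload as a list), \code{results} (the
#'   \linkS4class{MonotonicityResult} objects) and \code{fcTables}.
#' @export
runFullAnalysis <- function(config, cohort = NULL) {
    stopifnot(inherits(config, "RunConfig"))
    if (is.null(cohort)) {
        if (is.null(config$metaPath) || is.null(config$featuresPath))
            stop("config must provide metaPath and featuresPath, or pass a cohort")
        cohort <- readCohort(config$metaPath, config$featuresPath,
                             nRois = config$nRois)
    }
    if (!is.null(config$site) || !is.null(config$eyes) ||
        !is.null(config$sex))
        cohort <- filterCohort(cohort, site = config$site,
                               eyes = config$eyes, sex = config$sex)
    binning <- config$binning
    if (is.null(binning))
        stop("config has no binning and the dataset label is not a known scheme")
    results <- lapply(config$intervals, function(iv)
        runMonotonicity(cohort, iv, binning, window = config$window,
                        seed = config$seed, dataset = config$dataset))
    if (length(results))
        names(results) <- paste0("interval", config$intervals)
    ivTab <- do.call(rbind, lapply(results, function(r) data.frame(
        interval = r@scenario@intervalId, dataset = r@dataset,
        trainingSize = 2L * r@m, testSize = sum(r@rawSeries$n),
        beta0 = r@beta0, beta1 = r@beta1, spearman = r@spearmanRho,
        hypothesis = r@hypothesis, AR = r@validationAccuracy,
        m = r@m, k = r@k)))
    rownames(ivTab) <- NULL
    fcTables <- thresholdSensitivity(cohort, binning,
                                     thresholds = config$thresholds,
                                     stratifySex = config$stratifySex)
    summary <- list(dataset = config$dataset, seed = config$seed,
                    configHash = configHash(config),
                    nSubjects = ncol(cohort), nRois = nRois(cohort),
                    intervals = ivTab)
    if (!is.null(config$outDir)) {
        dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
        jsonlite::write_json(summary,
                             file.path(config$outDir, "summary.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        for (nm in names(results)) {
            r <- results[[nm]]
            tidy <- data.frame(age = r@rawSeries$age, n = r@rawSeries$n,
                               pctRaw = r@rawSeries$percentAged,
                               pctSmoothed = r@smoothedSeries$percentAged,
                               configHash = configHash(config),
                               seed = config$seed)
            utils::write.csv(tidy,
                             file.path(config$outDir,
                                       paste0("series_", nm, ".csv")),
                             row.names = FALSE)
        }
        for (tn in names(fcTables)) {
            tab <- fcTables[[tn]]
            tab$configHash <- configHash(config)
            tab$seed <- config$seed
            utils::write.csv(tab,
                             file.path(config$outDir,
                                       paste0("fc_summary_", tn, ".csv")),
                             row.names = FALSE)
        }
    }
    invisible(list(summary = summary, results = results,
                   fcTables = fcTables))
}
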