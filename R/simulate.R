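#' Configure a synthetic connectome cohort
#'
#' Builds a \linkS4class{CohortConfig} describing a synthetic rsfMRI cohort
#' under an additive Fisher-z edge model. Each subject's latent edge value is
#' \deqn{z_e = b_{c(e)} + d(a)\,s(\mathrm{sex})\,1[e \in A] +
#'   \varepsilon_e, \quad \varepsilon_e \sim N(0, \sigma(a)^2),}
#' where \eqn{b} is a per-edge-class baseline (within- vs between-network,
#' with ROIs partitioned into \code{nBlocks} contiguous latent networks),
#' \eqn{d(a)} an age-drift profile applied to a fixed random subset \eqn{A}
#' of edges, \eqn{s} a per-sex multiplier and \eqn{\sigma(a)} an
#' age-dependent inter-subject s.d. Observed correlations are
#' \eqn{\tanh(z)}, so they stay strictly inside (-1, 1) and effects are
#' additive on the z scale.
#'
#' @param nRois number of ROIs R (>= 2).
#' @param nTimepoints time-series length T used only in time-course mode.
#' @param groupSpec data.frame with columns \code{ageLo}, \code{ageHi},
#'   \code{nMale}, \code{nFemale}: one row per age group, ages inclusive.
#' @param baseZ length-2 numeric \code{c(within, between)}: baseline
#'   Fisher-z per edge class.
#' @param nBlocks number of latent networks partitioning the ROIs.
#' @param driftProfile one of \code{"linear_monotone"},
#'   \code{"plateau_after"}, \code{"inverted_u"}, \code{"null"}.
#' @param driftMagnitude Fisher-z units per year of age.
#' @param affectedFraction fraction of edges in [0, 1] receiving the drift.
#' @param sdProfile one of \code{"constant"}, \code{"inverted_u"},
#'   \code{"decreasing"}: shape of the inter-subject s.d. across age.
#' @param sdBase baseline inter-subject s.d. in Fisher-z units (> 0).
#' @param plateauAge age (years) at which \code{"plateau_after"} drift
#'   stops accruing.
#' @param sexEffectMultiplier drift multiplier applied to male subjects
#'   (females get 1).
#' @param sites recording-centre labels assigned round-robin.
#' @param eyes arousal-state labels (\code{"open"}, \code{"closed"},
#'   \code{NA}) assigned round-robin.
#' @param seed integer RNG seed; the same config generates byte-identical
#'   cohorts.
#' @return a validated \linkS4class{CohortConfig}.
#' @seealso \code{\link{scenarioPreset}}, \code{\link{generateCohort}}
#' @examples
#' cfg <- cohortConfig(nRois = 10,
#'                     groupSpec = data.frame(ageLo = c(18, 71),
#'                                            ageHi = c(30, 80),
#'                                            nMale = c(2, 2),
#'                                            nFemale = c(2, 2)))
#' generateCohort(cfg)
#' @export
cohortConfig <- function(nRois = 20L,
                         nTimepoints = 150L,
                         groupSpec = defaultGroupSpec(),
                         baseZ = c(within = 0.35, between = 0.10),
                         nBlocks = 4L,
                         driftProfile = c("linear_monotone", "plateau_after",
                                          "inverted_u", "null"),
                         driftMagnitude = 0.01,
                         affectedFraction = 0.3,
                         sdProfile = c("constant", "inverted_u", "decreasing"),
                         sdBase = 0.15,
                         plateauAge = 40,
                         sexEffectMultiplier = 1,
                         sites = "synthetic",
                         eyes = NA_character_,
                         seed = 1L) {
    driftProfile <- match.arg(driftProfile)
    sdProfile <- match.arg(sdProfile)
    if (length(baseZ) == 1L) baseZ <- c(within = baseZ, between = baseZ)
    new("CohortConfig",
        nRois = as.integer(nRois), nTimepoints = as.integer(nTimepoints),
        groupSpec = as.data.frame(groupSpec), baseZ = as.numeric(baseZ),
        nBlocks = as.integer(nBlocks), driftProfile = driftProfile,
        driftMagnitude = as.numeric(driftMagnitude),
        affectedFraction = as.numeric(affectedFraction),
        sdProfile = sdProfile, sdBase = as.numeric(sdBase),
        plateauAge = as.numeric(plateauAge),
        sexEffectMultiplier = as.numeric(sexEffectMultiplier),
        sites = as.character(sites), eyes = as.character(eyes),
        seed = as.integer(seed))
}

#' Default six-decade synthetic group structure
#'
#' Six decade-style bins spanning 18--85 years with a deliberately large
#' youngest group (100 male + 100 female) and 20 + 20 subjects in every
#' later bin, mirroring the right-skewed age distributions of large
#' multi-site rsfMRI cohorts and leaving a sizeable residual validation set
#' after balanced training.
#'
#' @return data.frame with columns \code{ageLo}, \code{ageHi},
#'   \code{nMale}, \code{nFemale}.
#' @export
defaultGroupSpec <- function() {
    data.frame(ageLo = c(18, 31, 41, 51, 61, 71),
               ageHi = c(30, 40, 50, 60, 70, 85),
               nMale = c(100, 20, 20, 20, 20, 20),
               nFemale = c(100, 20, 20, 20, 20, 20))
}

#' Named generator presets for qualitative aging regimes
#'
#' Fully populated \linkS4class{CohortConfig}s codifying the qualitative
#' regimes the analysis is designed to detect:
#' \describe{
#'   \item{monotone}{edge strength drifts linearly (0.01 z/year on 30\% of
#'     edges) across 18--85, about 4.5 noise s.d. over the span.}
#'   \item{plateau}{the same drift but only up to age 40, flat afterwards.}
#'   \item{null}{no age effect at all.}
#'   \item{inverted_u_variance}{monotone drift plus an inverted-U
#'     inter-subject s.d. peaking in middle age.}
#'   \item{sex_accentuated}{monotone drift 1.5 times stronger in males.}
#' }
#'
#' @param name preset name.
#' @param seed RNG seed stored in the config.
#' @return a \linkS4class{CohortConfig}.
#' @examples
#' scenarioPreset("monotone")
#' @export
scenarioPreset <- function(name = c("monotone", "plateau", "null",
                                    "inverted_u_variance", "sex_accentuated"),
                           seed = 1L) {
    name <- match.arg(name)
    switch(name,
        monotone = cohortConfig(driftProfile = "linear_monotone", seed = seed),
        plateau = cohortConfig(driftProfile = "plateau_after",
                               plateauAge = 40, seed = seed),
        null = cohortConfig(driftProfile = "null", driftMagnitude = 0,
                            seed = seed),
        inverted_u_variance = cohortConfig(driftProfile = "linear_monotone",
                                           sdProfile = "inverted_u",
                                           seed = seed),
        sex_accentuated = cohortConfig(driftProfile = "linear_monotone",
                                       sexEffectMultiplier = 1.5, seed = seed))
}

ageRange <- function(config) {
    c(lo = min(config@groupSpec$ageLo), hi = max(config@groupSpec$ageHi))
}

# Age-drift d(a) in Fisher-z units, anchored at the youngest configured age.
driftAt <- function(config, age) {
    r <- ageRange(config); lo <- r[["lo"]]; hi <- r[["hi"]]
    mag <- config@driftMagnitude
    switch(config@driftProfile,
        null = rep(0, length(age)),
        linear_monotone = mag * (age - lo),
        plateau_after = mag * (pmin(age, config@plateauAge) - lo),
        inverted_u = {
            mid <- (lo + hi) / 2
            mag * ((hi - lo) / 2 - abs(age - mid))
        })
}

# Inter-subject s.d. sigma(a) in Fisher-z units.
sdAt <- function(config, age) {
    r <- ageRange(config); lo <- r[["lo"]]; hi <- r[["hi"]]
    s <- config@sdBase
    switch(config@sdProfile,
        constant = rep(s, length(age)),
        inverted_u = {
            mid <- (lo + hi) / 2; half <- (hi - lo) / 2
            s * (1 + 0.75 * (1 - ((age - mid) / half)^2))
        },
        decreasing = s * (1.3 - 0.6 * (age - lo) / (hi - lo)))
}

# Per-edge class baseline: within-block vs between-block, blocks contiguous.
baseZVector <- function(config) {
    R <- config@nRois
    block <- sort(rep_len(seq_len(config@nBlocks), R))
    ep <- edgePairs(R)
    ifelse(block[ep[, 1L]] == block[ep[, 2L]],
           config@baseZ[[1L]], config@baseZ[[2L]])
}

# The fixed random subset of edges receiving drift; first draw under the
# config seed, so generateCohort reproduces it.
affectedEdges <- function(config) {
    E <- featureDimension(config@nRois)
    nAff <- floor(config@affectedFraction * E)
    withSeed(config@seed, sample.int(E, nAff))
}

#' Noise-free latent edge means at a given age
#'
#' Returns the population mean Fisher-z value of every edge at \code{age}
#' for a given sex, i.e. the generator's signal component without the
#' inter-subject noise. Useful for checking drift monotonicity.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @param age age in years (scalar).
#' @param sex \code{"M"} or \code{"F"}.
#' @return numeric vector of length \eqn{R(R-1)/2} of latent z means.
#' @export
latentEdgeMeans <- function(config, age, sex = "F") {
    stopifnot(length(age) == 1L, sex %in% c("M", "F"))
    base <- baseZVector(config)
    aff <- affectedEdges(config)
    mult <- if (sex == "M") config@sexEffectMultiplier else 1
    z <- base
    z[aff] <- z[aff] + driftAt(config, age) * mult
    z
}

#' Generate a synthetic cohort
#'
#' Draws one subject per slot in \code{groupSpec(config)}: ages uniform on
#' the group's integer range, latent edge z-values from the additive
#' Fisher-z model of \code{\link{cohortConfig}}, features
#' \eqn{\tanh(z)}. Deterministic given the config (which carries the seed).
#'
#' In time-course mode (\code{timecourses = TRUE}) each subject's sampled
#' correlation pattern is used as a latent correlation matrix from which a
#' \eqn{T \times R} Gaussian time-course matrix is simulated
#' (\code{\link{generateTimecourses}}); the stored features are then the
#' empirical Pearson correlations of those time courses, exercising
#' \code{\link{pccFeatures}} end-to-end. The time courses themselves are
#' kept in \code{metadata(x)$timecourses}.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @param timecourses logical; simulate ROI time courses per subject
#'   (slower) instead of emitting model correlations directly.
#' @return a \linkS4class{ConnectomeCohort}.
#' @examples
#' cc <- generateCohort(scenarioPreset("null"))
#' cc
#' @export
generateCohort <- function(config, timecourses = FALSE) {
    validObject(config)
    gs <- config@groupSpec
    if (any(!is.finite(unlist(gs[c("ageLo", "ageHi")]))))
        stop("generator groups must have finite age bounds")
    R <- config@nRois
    E <- featureDimension(R)
    base <- baseZVector(config)
    n <- sum(gs$nMale + gs$nFemale)
    withSeed(config@seed, {
        aff <- sample.int(E, floor(config@affectedFraction * E))
        sex <- character(0); age <- integer(0)
        for (g in seq_len(nrow(gs))) {
            ng <- gs$nMale[g] + gs$nFemale[g]
            sex <- c(sex, rep(c("M", "F"), c(gs$nMale[g], gs$nFemale[g])))
            age <- c(age, sample(seq(gs$ageLo[g], gs$ageHi[g]), ng,
                                 replace = TRUE))
        }
        mult <- ifelse(sex == "M", config@sexEffectMultiplier, 1)
        drift <- driftAt(config, age)
        sds <- sdAt(config, age)
        feat <- matrix(0, nrow = n, ncol = E)
        for (s in seq_len(n)) {
            z <- base + stats::rnorm(E, 0, sds[s])
            z[aff] <- z[aff] + drift[s] * mult[s]
            feat[s, ] <- tanh(z)
        }
        tcList <- NULL
        if (timecourses) {
            tcList <- vector("list", n)
            for (s in seq_len(n)) {
                C <- nearestPSDCorr(vecToCorr(feat[s, ], R))
                tc <- MASS::mvrnorm(config@nTimepoints,
                                    mu = rep(0, R), Sigma = C)
                tcList[[s]] <- tc
                feat[s, ] <- pccFeatures(tc)
            }
        }
        id <- sprintf("S%04d", seq_len(n))
        if (!is.null(tcList)) names(tcList) <- id
        cc <- ConnectomeCohort(
            feat, age = age, sex = sex, nRois = R, id = id,
            site = rep_len(config@sites, n),
            eyes = rep_len(config@eyes, n),
            metadata = c(list(config = config, affectedEdges = aff),
                         if (!is.null(tcList)) list(timecourses = tcList)))
        cc
    })
}

#' Nearest positive-semidefinite correlation matrix
#'
#' Eigenvalue clipping at zero followed by rescaling to unit diagonal:
#' the standard projection used before simulating Gaussian data from an
#' approximate correlation matrix.
#'
#' @param m symmetric matrix.
#' @return symmetric PSD matrix with unit diagonal.
#' @export
nearestPSDCorr <- function(m) {
    if (!isSymmetric(unname(m), tol = 1e-8)) stop("matrix must be symmetric")
    e <- eigen(m, symmetric = TRUE)
    v <- pmax(e$values, 0)
    s <- e$vectors %*% (v * t(e$vectors))
    d <- diag(s)
    d[d <= 0] <- 1
    s <- s / sqrt(outer(d, d))
    diag(s) <- 1
    (s + t(s)) / 2
}

#' Simulate ROI time courses with a target correlation structure
#'
#' Rows are drawn independently from a zero-mean multivariate Gaussian
#' whose correlation is the nearest-PSD projection of \code{latentCorr}
#' (see \code{\link{nearestPSDCorr}}); empirical correlations converge to
#' the target as T grows.
#'
#' @param latentCorr symmetric R x R correlation matrix (unit diagonal).
#' @param nTimepoints number of rows T to draw.
#' @param seed integer RNG seed.
#' @return numeric T x R matrix.
#' @examples
#' tc <- generateTimecourses(diag(3), 100, seed = 7)
#' @export
generateTimecourses <- function(latentCorr, nTimepoints, seed = 1L) {
    latentCorr <- as.matrix(latentCorr)
    if (!isSymmetric(unname(latentCorr), tol = 1e-8))
        stop("latentCorr must be symmetric")
    if (any(abs(diag(latentCorr) - 1) > 1e-8))
        stop("latentCorr must have unit diagonal")
    C <- nearestPSDCorr(latentCorr)
    R <- ncol(C)
    withSeed(seed,
        MASS::mvrnorm(as.integer(nTimepoints), mu = rep(0, R), Sigma = C,
                      tol = 1e-6))
}
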