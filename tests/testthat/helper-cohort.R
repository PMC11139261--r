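# Shared fixtures, built in code.

suppressMessages(library(SummarizedExperiment))  # colData / metadata in tests

# Decade binning matching the generator presets' default group structure.
presetBinning <- function() {
    AgeBinning(c("18-30", "31-40", "41-50", "51-60", "61-70", "71-85"),
               c(18, 31, 41, 51, 61, 71),
               c(30, 40, 50, 60, 70, 85))
}

# A tiny hand-made cohort with known feature values.
tinyCohort <- function(features = NULL, age = c(25, 45, 75),
                       sex = c("M", "F", "F"), nRois = 3,
                       site = c("A", "A", "B"),
                       eyes = c("open", "closed", "open")) {
    if (is.null(features))
        features <- rbind(c(0.7, -0.65, 0.2),
                          c(0.5, 0.1, -0.3),
                          c(0.0, 0.0, 0.0))
    ConnectomeCohort(features, age = age, sex = sex, nRois = nRois,
                     site = site, eyes = eyes)
}

# Small fast generator config: two extreme groups only.
twoGroupConfig <- function(seed = 1L, ...) {
    cohortConfig(nRois = 10,
                 groupSpec = data.frame(ageLo = c(18, 71),
                                        ageHi = c(30, 80),
                                        nMale = c(2, 2),
                                        nFemale = c(2, 2)),
                 seed = seed, ...)
}
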