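# Shared fixture builders: tiny tables, manifests and sampler configs
# kept small enough for fast, deterministic tests.

makeRows <- function(n = 3, injuries = seq_len(n), aes = rep(1000L, n)) {
  data.frame(
    school_id = sprintf("school_%03d", seq_len(n)),
    division = "DI",
    academic_year = "2014/15",
    sport = "womens_soccer",
    event_type = "competition",
    diagnosis = "sprain",
    injuries = as.integer(injuries),
    athlete_exposures = as.integer(aes),
    stringsAsFactors = FALSE)
}

makeTable <- function(...) surveillanceTable(makeRows(...))

# single-stratum intercept-only table for conjugate-oracle fits
oneRowTable <- function(injuries = 84L, aes = 10000L) {
  surveillanceTable(data.frame(
    school_id = "school_001", division = "DI",
    academic_year = "2014/15", sport = "womens_soccer",
    event_type = "competition", diagnosis = "sprain",
    injuries = as.integer(injuries),
    athlete_exposures = as.integer(aes)))
}

interceptSpec <- function(priorIntercept = list(type = "cauchy")) {
  modelSpec("poisson", covariates = character(0),
            referenceLevels = character(0),
            priorIntercept = priorIntercept)
}

# a manifest with hand-picked parameters (bypasses defaultTruth)
makeTruth <- function(family = "poisson", gamma = log(0.001),
                      alphaEvent = numeric(), betaDivision = numeric(),
                      epsilonDiagnosis = numeric(),
                      kappaYear = numeric(), sigmaSchool = 0,
                      overdispersion = NA_real_,
                      zeroInflation = numeric(), seed = 1L) {
  new("TruthManifest", family = family, gamma = gamma,
      alphaEvent = alphaEvent, betaDivision = betaDivision,
      epsilonDiagnosis = epsilonDiagnosis, kappaYear = kappaYear,
      sigmaSchool = sigmaSchool, schoolEffects = numeric(),
      overdispersion = overdispersion, zeroInflation = zeroInflation,
      seed = as.integer(seed))
}

# fixed-AE structure with arbitrary shape (aeSdlog = 0 gives constant AEs)
makeStructure <- function(schoolsPerDivision = c(DI = 1L), years = "y01",
                          ae = 10000, aeSdlog = 0,
                          sport = "womens_soccer") {
  new("StructureConfig",
      schoolsPerDivision = stats::setNames(
        as.integer(schoolsPerDivision), names(schoolsPerDivision)),
      years = years,
      eventTypes = c("practice", "competition"),
      diagnoses = c("sprain", "strain", "contusion", "concussion"),
      sport = sport,
      aeMeanlog = c(practice = log(ae), competition = log(ae)),
      aeSdlog = aeSdlog)
}

quickMcmc <- function(seed = 1L, chains = 2L, iters = 200L)
  mcmcConfig(chains = chains, warmupIterations = iters,
             samplingIterations = iters, seed = seed)

# PosteriorDraws wrapper around a plain matrix of draws (for summary and
# diagnostic tests that need no sampler run)
fakeDraws <- function(draws_by_param, chains = 2L,
                      spec = interceptSpec()) {
  m <- as.matrix(draws_by_param)
  n <- nrow(m) %/% chains
  a <- array(m[seq_len(n * chains), , drop = FALSE],
             c(n, chains, ncol(m)),
             dimnames = list(NULL, NULL, colnames(m)))
  new("PosteriorDraws", draws = a, spec = spec,
      schoolLevels = character(), dataFingerprint = "fake",
      samplerInfo = list(seed = 0L, divergences = 0L))
}
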