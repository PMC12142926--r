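#' @import methods
NULL

SURV_COLUMNS <- c("school_id", "division", "academic_year", "sport",
                  "event_type", "diagnosis", "injuries", "athlete_exposures")

SURV_COVARIATES <- c("school_id", "division", "academic_year", "sport",
                     "event_type", "diagnosis")

STRATUM_KEY <- c("school_id", "academic_year", "sport", "event_type",
                 "diagnosis")

MODEL_FAMILIES <- c("poisson", "poisson_school", "nb_school", "zinb_school")

#' Stratified injury-surveillance table
#'
#' An ordered collection of surveillance strata, one row per combination of
#' school, division, academic year, sport, event type and diagnosis, holding
#' the injury count and the athlete-exposure (AE) denominator for that
#' stratum. Category level sets are declared explicitly (rather than
#' inferred from the data) so that strata with zero injuries remain
#' representable.
#'
#' @slot data A `data.frame` with columns `school_id`, `division`,
#'   `academic_year`, `sport`, `event_type`, `diagnosis`, `injuries`
#'   (non-negative integer) and `athlete_exposures` (positive integer).
#' @slot levelSets Named list of declared category levels for `division`,
#'   `academic_year`, `sport`, `event_type` and `diagnosis`. The first
#'   element of each is the conventional reference level.
#' @seealso [readSurveillanceCSV()], [validateTable()], [aggregateTable()]
#' @export
setClass("SurveillanceTable",
  representation(data = "data.frame", levelSets = "list"),
  validity = function(object) {
    msg <- character()
    missing_cols <- setdiff(SURV_COLUMNS, names(object@data))
    if (length(missing_cols))
      msg <- c(msg, paste0("missing columns: ",
                           paste(missing_cols, collapse = ", ")))
    if (!nrow(object@data))
      msg <- c(msg, "table is empty")
    needed <- setdiff(SURV_COVARIATES, "school_id")
    missing_ls <- setdiff(needed, names(object@levelSets))
    if (length(missing_ls))
      msg <- c(msg, paste0("missing level sets: ",
                           paste(missing_ls, collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

#' Ground truth used by the synthetic surveillance-data generator
#'
#' Records the generative family and every parameter used to simulate a
#' surveillance table, including the realized per-school effects, so that
#' parameter-recovery experiments can compare posterior summaries against
#' the values that actually generated the data.
#'
#' @slot family One of `"poisson"`, `"poisson_school"`, `"nb_school"`,
#'   `"zinb_school"`.
#' @slot gamma Log baseline injury rate per AE (reference cell).
#' @slot alphaEvent,betaDivision,epsilonDiagnosis,kappaYear Named numeric
#'   vectors of log rate-ratio effects for the non-reference levels of the
#'   event-type, division, diagnosis and academic-year covariates.
#' @slot sigmaSchool Standard deviation of school effects (>= 0).
#' @slot schoolEffects Named numeric vector of realized per-school effects
#'   zeta; filled in by [generateDataset()].
#' @slot overdispersion NB overdispersion kappa (> 0; `NA` for Poisson
#'   families).
#' @slot zeroInflation Named numeric vector of structural-zero
#'   probabilities theta per event type, each in `[0, 1]` (empty unless
#'   `family = "zinb_school"`).
#' @slot seed Integer seed the dataset was (or will be) generated from.
#' @export
setClass("TruthManifest",
  representation(family = "character", gamma = "numeric",
                 alphaEvent = "numeric", betaDivision = "numeric",
                 epsilonDiagnosis = "numeric", kappaYear = "numeric",
                 sigmaSchool = "numeric", schoolEffects = "numeric",
                 overdispersion = "numeric", zeroInflation = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@family %in% MODEL_FAMILIES)
      msg <- c(msg, paste0("unknown family '", object@family, "'"))
    if (object@sigmaSchool < 0) msg <- c(msg, "sigmaSchool must be >= 0")
    if (object@family %in% c("nb_school", "zinb_school") &&
        (!length(object@overdispersion) ||
         is.na(object@overdispersion) || object@overdispersion <= 0))
      msg <- c(msg, "overdispersion must be > 0 for NB families")
    if (object@family == "zinb_school" &&
        (!length(object@zeroInflation) ||
         any(object@zeroInflation < 0 | object@zeroInflation > 1)))
      msg <- c(msg, "zeroInflation must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Structural configuration of the synthetic generator
#'
#' Describes the shape of the simulated surveillance system: how many
#' schools report in each division, which academic years, event types and
#' diagnosis classes are covered, and the per-event-type log-normal law the
#' athlete-exposure denominators are drawn from.
#'
#' @slot schoolsPerDivision Named integer vector (names are divisions).
#' @slot years Character vector of academic-year labels.
#' @slot eventTypes,diagnoses Declared level sets (reference level first).
#' @slot sport Sport label stamped on every generated row.
#' @slot aeMeanlog Named numeric, per-event-type mean of log AE.
#' @slot aeSdlog Standard deviation of log AE (shared across event types).
#' @export
setClass("StructureConfig",
  representation(schoolsPerDivision = "integer", years = "character",
                 eventTypes = "character", diagnoses = "character",
                 sport = "character", aeMeanlog = "numeric",
                 aeSdlog = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(object@schoolsPerDivision < 1L))
      msg <- c(msg, "at least one school per included division")
    if (object@aeSdlog < 0) msg <- c(msg, "aeSdlog must be >= 0")
    if (!all(object@eventTypes %in% names(object@aeMeanlog)))
      msg <- c(msg, "aeMeanlog must name every event type")
    if (length(msg)) msg else TRUE
  })

#' Model specification for the count-regression families
#'
#' Names the likelihood family, the categorical covariates entering the
#' log-linear predictor, their reference levels (absorbed by the
#' intercept), and the prior scales. All fixed effects and the intercept
#' receive Cauchy(0, `priorScaleFixed`) priors; the school-effect scale
#' receives a half-Cauchy(0, `priorScaleSigma`) prior, as does the NB
#' overdispersion; zero-inflation probabilities are uniform on `[0, 1]`.
#' The intercept prior can be swapped for a Gamma prior on the baseline
#' rate `exp(gamma)` (`priorIntercept = list(type = "gamma", shape, rate)`),
#' which makes the intercept-only Poisson model conjugate and analytically
#' checkable.
#'
#' @slot family One of `"poisson"`, `"poisson_school"`, `"nb_school"`,
#'   `"zinb_school"`.
#' @slot covariates Ordered subset of `c("event_type", "division",
#'   "diagnosis", "academic_year")`.
#' @slot referenceLevels Named character, one reference level per covariate.
#' @slot priorScaleFixed,priorScaleSigma Positive Cauchy scales (default 10).
#' @slot priorIntercept List describing the intercept prior.
#' @export
setClass("ModelSpec",
  representation(family = "character", covariates = "character",
                 referenceLevels = "character",
                 priorScaleFixed = "numeric", priorScaleSigma = "numeric",
                 priorIntercept = "list"),
  validity = function(object) {
    msg <- character()
    if (!object@family %in% MODEL_FAMILIES)
      msg <- c(msg, paste0("unknown family '", object@family, "'"))
    bad <- setdiff(object@covariates,
                   c("event_type", "division", "diagnosis", "academic_year"))
    if (length(bad))
      msg <- c(msg, paste0("unsupported covariates: ",
                           paste(bad, collapse = ", ")))
    if (length(object@covariates) &&
        !all(object@covariates %in% names(object@referenceLevels)))
      msg <- c(msg, "every covariate needs a reference level")
    if (object@priorScaleFixed <= 0 || object@priorScaleSigma <= 0)
      msg <- c(msg, "prior scales must be > 0")
    if (!identical(object@priorIntercept$type, "cauchy") &&
        !identical(object@priorIntercept$type, "gamma"))
      msg <- c(msg, "priorIntercept$type must be 'cauchy' or 'gamma'")
    if (length(msg)) msg else TRUE
  })

#' Design matrix for the log-linear injury-rate predictor
#'
#' Reference-coded indicator columns for every non-reference covariate
#' level, aligned row-for-row with a [SurveillanceTable], plus the log-AE
#' offset, the per-row school index (for families with school effects) and
#' the per-row event-type index (for the zero-inflation component).
#'
#' @slot X Indicator matrix; column names follow the shared parameter
#'   naming convention (`alpha[competition]`, `beta[DII]`, ...).
#' @slot offset Numeric, `log(athlete_exposures)` per row.
#' @slot counts Integer injury counts per row.
#' @slot schoolIndex Integer index into `schoolLevels` per row.
#' @slot schoolLevels Character, the distinct schools (model order).
#' @slot eventIndex Integer index into `eventLevels` per row.
#' @slot eventLevels Character, the declared event-type levels.
#' @export
setClass("DesignMatrix",
  representation(X = "matrix", offset = "numeric", counts = "integer",
                 schoolIndex = "integer", schoolLevels = "character",
                 eventIndex = "integer", eventLevels = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@offset) != nrow(object@X) ||
        length(object@counts) != nrow(object@X))
      msg <- c(msg, "offset/counts must align with the design rows")
    if (length(object@X) && !all(object@X %in% c(0, 1)))
      msg <- c(msg, "indicator entries must be 0/1")
    if (any(!is.finite(object@offset)))
      msg <- c(msg, "offset must be finite")
    if (length(msg)) msg else TRUE
  })

#' Sampler configuration
#'
#' @slot chains Number of Markov chains (>= 2 so split R-hat is defined).
#' @slot warmupIterations,samplingIterations Iterations per chain.
#' @slot seed Integer seed; chain c is jittered deterministically from it.
#' @slot targetAcceptance Dual-averaging target acceptance statistic.
#' @slot maxTreedepth Maximum trajectory doubling depth.
#' @export
setClass("McmcConfig",
  representation(chains = "integer", warmupIterations = "integer",
                 samplingIterations = "integer", seed = "integer",
                 targetAcceptance = "numeric", maxTreedepth = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@chains < 2L) msg <- c(msg, "chains must be >= 2")
    if (object@warmupIterations < 1L || object@samplingIterations < 1L)
      msg <- c(msg, "iterations must be >= 1")
    if (object@targetAcceptance <= 0 || object@targetAcceptance >= 1)
      msg <- c(msg, "targetAcceptance must lie in (0, 1)")
    if (length(msg)) msg else TRUE
  })

#' Posterior draws from a fitted model
#'
#' Post-warmup MCMC draws indexed (iteration, chain, parameter), on the
#' constrained scale, with the fitted [ModelSpec], a fingerprint of the
#' data the model was fitted to, and sampler metadata (divergence counts,
#' adapted step sizes, seed).
#'
#' @slot draws 3-d array `iterations x chains x parameters`, parameter
#'   names following the shared convention (`gamma`, `alpha[competition]`,
#'   `zeta[school_017]`, `sigma_zeta`, `kappa_nb`, `theta[competition]`).
#' @slot spec The [ModelSpec] that was fitted.
#' @slot schoolLevels Schools backing the `zeta` parameters.
#' @slot dataFingerprint Character fingerprint of the fitted table.
#' @slot samplerInfo List: per-chain divergences, step sizes, seed.
#' @export
setClass("PosteriorDraws",
  representation(draws = "array", spec = "ModelSpec",
                 schoolLevels = "character", dataFingerprint = "character",
                 samplerInfo = "list"),
  validity = function(object) {
    if (length(dim(object@draws)) != 3L)
      return("draws must be a 3-d array (iteration, chain, parameter)")
    if (is.null(dimnames(object@draws)[[3]]))
      return("parameter dimension must be named")
    TRUE
  })

#' Convergence diagnostics report
#'
#' Per-parameter rank-normalized split R-hat and bulk effective sample
#' size, with pass flags against declared thresholds. Parameters are
#' ordered worst-first (largest R-hat).
#'
#' @slot table `data.frame` with columns `parameter`, `rhat`, `ess`,
#'   `degenerate`.
#' @slot passRhat,passEss Logical pass flags over all parameters.
#' @slot rhatThreshold,essThreshold Thresholds the flags were taken at.
#' @export
setClass("ConvergenceReport",
  representation(table = "data.frame", passRhat = "logical",
                 passEss = "logical", rhatThreshold = "numeric",
                 essThreshold = "numeric"))

#' Posterior predictive replicate datasets
#'
#' @slot counts Integer matrix `replicates x rows`, aligned to the
#'   observed table's rows; each replicate was generated from one distinct
#'   posterior draw.
#' @slot drawIndices Flattened draw index used for each replicate.
#' @slot seed Generating seed.
#' @export
setClass("PpcReplicates",
  representation(counts = "matrix", drawIndices = "integer",
                 seed = "integer"),
  validity = function(object) {
    if (!nrow(object@counts)) return("at least one replicate required")
    if (any(object@counts < 0)) return("replicate counts must be >= 0")
    TRUE
  })

#' Gamma prior for the conjugate rate model
#'
#' Rate parameterization: the prior mean rate is `shape / rate`, so the
#' conjugate update is additive in counts and exposures.
#'
#' @slot shape,rate Positive Gamma hyperparameters.
#' @export
setClass("GammaPrior",
  representation(shape = "numeric", rate = "numeric"),
  validity = function(object) {
    if (object@shape <= 0 || object@rate <= 0)
      return("shape and rate must be > 0")
    TRUE
  })

#' Gamma posterior for the conjugate rate model
#'
#' @slot shape,rate Posterior Gamma parameters (prior shape + injuries,
#'   prior rate + exposures).
#' @export
setClass("RatePosterior", contains = "GammaPrior")
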