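# Published season totals (2014/15-2018/19 collegiate soccer): injuries and
# athlete exposures by event type. Used only to put the generator's
# magnitudes on the scale of real surveillance data.
SPORT_TOTALS <- list(
  mens_soccer = list(competition = c(injuries = 1358, aes = 80453),
                     practice    = c(injuries = 1463, aes = 251225)),
  womens_soccer = list(competition = c(injuries = 1885, aes = 112245),
                       practice    = c(injuries = 2047, aes = 342085)))

# Posterior-mean fixed effects reported for the NB school-effects model,
# used as default generating values (log rate-ratio scale).
SPORT_EFFECTS <- list(
  mens_soccer = list(
    alphaEvent = c("competition" = 1.28),
    betaDivision = c("DII" = -0.18, "DIII" = -0.03),
    epsilonDiagnosis = c("strain" = -0.02, "contusion" = -0.23,
                         "concussion" = -1.41)),
  womens_soccer = list(
    alphaEvent = c("competition" = 1.33),
    betaDivision = c("DII" = 0.01, "DIII" = 0.09),
    epsilonDiagnosis = c("strain" = -0.07, "contusion" = -0.68,
                         "concussion" = -0.99)))

#' Default structural configuration of the synthetic generator
#'
#' Ten schools per division across five seasons, two event types and four
#' diagnosis classes (1,200 strata per sport). Athlete-exposure
#' denominators are drawn log-normally with an event-type-specific
#' location calibrated so that expected AE totals match the published
#' season totals for the sport (practice exposure roughly three times
#' competition exposure).
#'
#' @param sport `"mens_soccer"` or `"womens_soccer"`.
#' @param schoolsPerDivision Named integer vector of reporting schools.
#' @param years Academic-year labels.
#' @param aeSdlog Log-scale spread of per-stratum AEs.
#' @return A [StructureConfig].
#' @export
defaultStructure <- function(sport = "womens_soccer",
                             schoolsPerDivision = c(DI = 10L, DII = 10L,
                                                    DIII = 10L),
                             years = c("2014/15", "2015/16", "2016/17",
                                       "2017/18", "2018/19"),
                             aeSdlog = 0.5) {
  totals <- SPORT_TOTALS[[sport]]
  if (is.null(totals))
    stop("unknown sport '", sport, "'", call. = FALSE)
  ls <- defaultLevelSets(years = years)
  rows_per_event <- sum(schoolsPerDivision) * length(years) *
    length(ls$diagnosis)
  # E[lognormal] = exp(meanlog + sdlog^2/2); match expected AE totals
  aeMeanlog <- vapply(ls$event_type, function(ev)
    log(totals[[ev]][["aes"]] / rows_per_event) - aeSdlog^2 / 2,
    numeric(1))
  new("StructureConfig",
      schoolsPerDivision = stats::setNames(as.integer(schoolsPerDivision),
                                           names(schoolsPerDivision)),
      years = years, eventTypes = ls$event_type, diagnoses = ls$diagnosis,
      sport = sport,
      aeMeanlog = stats::setNames(aeMeanlog, ls$event_type),
      aeSdlog = aeSdlog)
}

setMethod("show", "StructureConfig", function(object) {
  cat("StructureConfig:", object@sport, "\n")
  cat("  schools per division:",
      paste(names(object@schoolsPerDivision), object@schoolsPerDivision,
            sep = "=", collapse = ", "), "\n")
  cat("  years:", length(object@years),
      " event types:", length(object@eventTypes),
      " diagnoses:", length(object@diagnoses), "\n")
})

# expected rate multiplier of a covariate: equally weighted mean of
# exp(effect) over levels (reference contributes exp(0) = 1)
meanMultiplier <- function(effects) mean(exp(c(0, effects)))

#' Calibrate the log baseline rate to published exposure totals
#'
#' Chooses gamma so that the generator's expected injury totals per event
#' type sit on the magnitude of the published totals: for each event type
#' the implied baseline log rate is computed from the published
#' injuries-per-AE rate, discounting the event effect, the average
#' division/diagnosis/year multipliers, the log-normal school-effect mean
#' `exp(sigma^2/2)` and (for zero-inflated families) the structural-zero
#' thinning `1 - theta`; the returned gamma is the average of the two
#' implied baselines, so each event total is matched up to the residual
#' disagreement between the published rate ratio and the event effect.
#'
#' @param truth A [TruthManifest] (its `gamma` is ignored).
#' @param sport Sport whose published totals are targeted.
#' @return The calibrated gamma (log rate per AE in the reference cell).
#' @export
calibrateGamma <- function(truth, sport) {
  totals <- SPORT_TOTALS[[sport]]
  if (is.null(totals)) stop("unknown sport '", sport, "'", call. = FALSE)
  adj <- meanMultiplier(truth@betaDivision) *
    meanMultiplier(truth@epsilonDiagnosis) *
    meanMultiplier(truth@kappaYear) *
    exp(truth@sigmaSchool^2 / 2)
  implied <- vapply(names(totals), function(ev) {
    rate <- totals[[ev]][["injuries"]] / totals[[ev]][["aes"]]
    a <- if (ev %in% names(truth@alphaEvent)) truth@alphaEvent[[ev]] else 0
    thin <- if (truth@family == "zinb_school" &&
                ev %in% names(truth@zeroInflation))
      1 - truth@zeroInflation[[ev]] else 1
    log(rate) - a - log(adj) - log(thin)
  }, numeric(1))
  mean(implied)
}

#' Default ground truth for the synthetic generator
#'
#' The event, division and diagnosis effects equal the posterior means
#' reported for the sport's NB school-effects model; year effects (not
#' reported) are small declared values; the school-effect scale,
#' overdispersion and zero-inflation defaults are declared desk-scale
#' choices. The baseline gamma is calibrated with [calibrateGamma()] so
#' generated totals are on the magnitude of the published season totals.
#'
#' @param sport `"mens_soccer"` or `"womens_soccer"`.
#' @param family Generative family (default `"nb_school"`).
#' @param sigmaSchool School-effect standard deviation.
#' @param overdispersion NB overdispersion kappa (> 0).
#' @param zeroInflation Named per-event-type structural-zero probabilities
#'   (used when `family = "zinb_school"`).
#' @param seed Integer seed recorded in the manifest.
#' @return A [TruthManifest] with empty `schoolEffects` (realized by
#'   [generateDataset()]).
#' @examples
#' defaultTruth("womens_soccer")@alphaEvent   # competition effect 1.33
#' @export
defaultTruth <- function(sport, family = "nb_school", sigmaSchool = 0.3,
                         overdispersion = 2,
                         zeroInflation = c(practice = 0.25,
                                           competition = 0.25),
                         seed = 20250101L) {
  eff <- SPORT_EFFECTS[[sport]]
  if (is.null(eff)) stop("unknown sport '", sport, "'", call. = FALSE)
  truth <- new("TruthManifest", family = family, gamma = 0,
               alphaEvent = eff$alphaEvent,
               betaDivision = eff$betaDivision,
               epsilonDiagnosis = eff$epsilonDiagnosis,
               kappaYear = c("2015/16" = 0.02, "2016/17" = -0.03,
                             "2017/18" = 0.04, "2018/19" = -0.02),
               sigmaSchool = sigmaSchool,
               schoolEffects = numeric(),
               overdispersion = if (family %in% c("nb_school",
                                                  "zinb_school"))
                 overdispersion else NA_real_,
               zeroInflation = if (family == "zinb_school")
                 zeroInflation else numeric(),
               seed = as.integer(seed))
  truth@gamma <- calibrateGamma(truth, sport)
  truth
}

setMethod("show", "TruthManifest", function(object) {
  cat("TruthManifest: family", object@family, "\n")
  cat("  gamma:", format(object@gamma, digits = 4),
      " sigma_school:", object@sigmaSchool, "\n")
  cat("  alpha:", paste(names(object@alphaEvent),
                        object@alphaEvent, sep = "=", collapse = ", "), "\n")
  if (length(object@schoolEffects))
    cat("  realized school effects for", length(object@schoolEffects),
        "schools\n")
})

# effect lookup for a covariate level (reference levels contribute 0)
effectAt <- function(effects, levels) {
  out <- rep(0, length(levels))
  hit <- levels %in% names(effects)
  out[hit] <- effects[levels[hit]]
  out
}

#' Generate a synthetic surveillance dataset with recorded ground truth
#'
#' Simulates one stratum row per (school, year, event type, diagnosis)
#' from the named generative family: athlete exposures are drawn
#' log-normally per event type, school effects once per school (shared
#' across all that school's rows), and counts from the family with mean
#' `AEs * exp(gamma + effects + zeta)`. For the zero-inflated family a
#' structural zero replaces the count with probability `theta[event]` at
#' the row level. Fully reproducible from the seed.
#'
#' @param truth A [TruthManifest].
#' @param structure A [StructureConfig].
#' @param seed Integer seed (default: the manifest's).
#' @return List with `table` (a [SurveillanceTable]) and `truth` (the
#'   manifest with realized `schoolEffects` and the seed used).
#' @export
generateDataset <- function(truth, structure, seed = truth@seed) {
  stopifnot(is(truth, "TruthManifest"), is(structure, "StructureConfig"))
  validObject(truth)
  if (truth@family %in% c("nb_school", "zinb_school") &&
      !is.finite(truth@overdispersion))
    stop("configuration error: overdispersion required for family ",
         truth@family, call. = FALSE)
  if (truth@family == "zinb_school" &&
      !all(structure@eventTypes %in% names(truth@zeroInflation)))
    stop("configuration error: zeroInflation must name every event type",
         call. = FALSE)
  divs <- names(structure@schoolsPerDivision)
  school_div <- rep(divs, structure@schoolsPerDivision)
  schools <- sprintf("school_%03d", seq_along(school_div))
  grid <- expand.grid(diagnosis = structure@diagnoses,
                      event_type = structure@eventTypes,
                      academic_year = structure@years,
                      school = seq_along(schools),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$school), , drop = FALSE]
  set.seed(as.integer(seed))
  zeta <- if (truth@family == "poisson") rep(0, length(schools))
          else stats::rnorm(length(schools), 0, truth@sigmaSchool)
  names(zeta) <- schools
  aes <- pmax(1, round(stats::rlnorm(
    nrow(grid), structure@aeMeanlog[grid$event_type], structure@aeSdlog)))
  eta <- truth@gamma +
    effectAt(truth@alphaEvent, grid$event_type) +
    effectAt(truth@betaDivision, school_div[grid$school]) +
    effectAt(truth@epsilonDiagnosis, grid$diagnosis) +
    effectAt(truth@kappaYear, grid$academic_year) +
    zeta[grid$school]
  mu <- aes * exp(eta)
  n <- nrow(grid)
  counts <- switch(truth@family,
    poisson = ,
    poisson_school = stats::rpois(n, mu),
    nb_school = stats::rnbinom(n, size = truth@overdispersion, mu = mu),
    zinb_school = {
      theta <- truth@zeroInflation[grid$event_type]
      z <- stats::rbinom(n, 1L, theta)
      x <- stats::rnbinom(n, size = truth@overdispersion, mu = mu)
      ifelse(z == 1L, 0L, x)
    })
  tab <- surveillanceTable(
    data.frame(school_id = schools[grid$school],
               division = school_div[grid$school],
               academic_year = grid$academic_year,
               sport = structure@sport,
               event_type = grid$event_type,
               diagnosis = grid$diagnosis,
               injuries = as.integer(counts),
               athlete_exposures = as.integer(aes),
               stringsAsFactors = FALSE),
    levelSets = defaultLevelSets(years = structure@years))
  truth@schoolEffects <- zeta
  truth@seed <- as.integer(seed)
  list(table = tab, truth = truth)
}

#' Ground-truth parameters as a named vector
#'
#' Flattens a [TruthManifest] to the shared parameter naming convention
#' (`gamma`, `alpha[competition]`, `beta[DII]`, `epsilon[concussion]`,
#' `kappa_year[2015/16]`, `sigma_zeta`, `kappa_nb`, `theta[practice]`,
#' `zeta[school_001]`, ...).
#'
#' @param truth A [TruthManifest].
#' @param includeSchools Include realized per-school effects.
#' @return Named numeric vector.
#' @export
truthParameters <- function(truth, includeSchools = FALSE) {
  nm <- function(prefix, v) stats::setNames(v, sprintf("%s[%s]", prefix,
                                                       names(v)))
  out <- c(gamma = truth@gamma,
           nm("alpha", truth@alphaEvent),
           nm("beta", truth@betaDivision),
           nm("epsilon", truth@epsilonDiagnosis),
           nm("kappa_year", truth@kappaYear))
  if (truth@family != "poisson")
    out <- c(out, sigma_zeta = truth@sigmaSchool)
  if (truth@family %in% c("nb_school", "zinb_school"))
    out <- c(out, kappa_nb = truth@overdispersion)
  if (truth@family == "zinb_school")
    out <- c(out, nm("theta", truth@zeroInflation))
  if (includeSchools && length(truth@schoolEffects))
    out <- c(out, nm("zeta", truth@schoolEffects))
  out
}

#' Parameter-recovery report against a posterior summary
#'
#' For every ground-truth parameter present in the summary table, reports
#' the posterior-mean bias, its z-score (bias over posterior SD) and
#' whether the truth is covered by the equal-tailed 95% credible interval.
#'
#' @param truth A [TruthManifest] with realized school effects.
#' @param summaries A summary `data.frame` from [summarizePosterior()]
#'   (columns `parameter`, `mean`, `sd`, `lower`, `upper` at the 95%
#'   level).
#' @param includeSchools Also score the per-school effects.
#' @return `data.frame` with columns `parameter`, `truth`, `bias`, `z`,
#'   `covered_by_95`.
#' @export
recoveryReport <- function(truth, summaries, includeSchools = FALSE) {
  tv <- truthParameters(truth, includeSchools = includeSchools)
  missing <- setdiff(names(tv), summaries$parameter)
  if (length(missing))
    stop("parameter(s) in truth but absent from summaries: ",
         paste(missing, collapse = ", "), call. = FALSE)
  s <- summaries[match(names(tv), summaries$parameter), , drop = FALSE]
  data.frame(parameter = names(tv), truth = unname(tv),
             bias = s$mean - unname(tv),
             z = ifelse(s$sd > 0, (s$mean - unname(tv)) / s$sd, 0),
             covered_by_95 = tv >= s$lower & tv <= s$upper,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Serialize a truth manifest to JSON
#'
#' @param truth A [TruthManifest].
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
writeTruthManifest <- function(truth, path) {
  jsonlite::write_json(
    list(family = truth@family, gamma = truth@gamma,
         alpha_event = as.list(truth@alphaEvent),
         beta_division = as.list(truth@betaDivision),
         epsilon_diagnosis = as.list(truth@epsilonDiagnosis),
         kappa_year = as.list(truth@kappaYear),
         sigma_school = truth@sigmaSchool,
         school_effects = as.list(truth@schoolEffects),
         overdispersion = truth@overdispersion,
         zero_inflation = as.list(truth@zeroInflation),
         seed = truth@seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
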