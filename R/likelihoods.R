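COVARIATE_PREFIX <- c(event_type = "alpha", division = "beta",
                      diagnosis = "epsilon", academic_year = "kappa_year")

#' Construct a model specification
#'
#' @param family One of `"poisson"`, `"poisson_school"`, `"nb_school"`,
#'   `"zinb_school"`.
#' @param covariates Ordered subset of `c("event_type", "division",
#'   "diagnosis", "academic_year")` entering the log-linear predictor.
#' @param referenceLevels Named character vector of reference levels; by
#'   default the first declared level of each covariate in `levelSets`
#'   (practice, DI, sprain, earliest season).
#' @param levelSets Level sets used to derive default reference levels.
#' @param priorScaleFixed Cauchy scale for the intercept and fixed
#'   effects (default 10, a weakly informative choice that admits a huge
#'   range of rate multipliers).
#' @param priorScaleSigma Half-Cauchy scale for the school-effect SD and
#'   the NB overdispersion.
#' @param priorIntercept `list(type = "cauchy")` (default, using
#'   `priorScaleFixed`) or `list(type = "gamma", shape =, rate =)` for a
#'   conjugate-matched Gamma prior on the baseline rate `exp(gamma)`.
#' @return A [ModelSpec].
#' @export
modelSpec <- function(family,
                      covariates = c("event_type", "division",
                                     "diagnosis", "academic_year"),
                      referenceLevels = NULL,
                      levelSets = defaultLevelSets(),
                      priorScaleFixed = 10, priorScaleSigma = 10,
                      priorIntercept = list(type = "cauchy")) {
  if (is.null(referenceLevels))
    referenceLevels <- vapply(covariates,
                              function(cv) levelSets[[cv]][1L], character(1))
  new("ModelSpec", family = family, covariates = covariates,
      referenceLevels = referenceLevels,
      priorScaleFixed = priorScaleFixed,
      priorScaleSigma = priorScaleSigma,
      priorIntercept = priorIntercept)
}

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec: family", object@family, "\n")
  if (length(object@covariates))
    cat("  covariates:",
        paste0(object@covariates, " (ref ",
               object@referenceLevels[object@covariates], ")",
               collapse = ", "), "\n")
  else cat("  intercept-only\n")
  cat("  priors: Cauchy(0,", object@priorScaleFixed,
      ") fixed effects; half-Cauchy(0,", object@priorScaleSigma,
      ") scales\n")
})

familyHasSchool <- function(family)
  family %in% c("poisson_school", "nb_school", "zinb_school")

#' Build the reference-coded design matrix
#'
#' One indicator column per non-reference covariate level, in covariate
#' declaration order then declared level order, with the intercept
#' absorbing the reference cell. The offset is the natural log of the
#' athlete exposures, and the per-row school and event-type indices
#' needed by the school-effect and zero-inflation components are
#' recorded.
#'
#' @param table A validated single-sport [SurveillanceTable].
#' @param spec A [ModelSpec].
#' @return A [DesignMatrix].
#' @export
buildDesign <- function(table, spec) {
  stopifnot(is(table, "SurveillanceTable"), is(spec, "ModelSpec"))
  d <- strataData(table)
  ls <- levelSets(table)
  cols <- list()
  for (cv in spec@covariates) {
    lv <- ls[[cv]]
    ref <- spec@referenceLevels[[cv]]
    if (!ref %in% lv)
      stop("reference level '", ref, "' not in declared levels of ", cv,
           call. = FALSE)
    bad <- which(!d[[cv]] %in% lv)
    if (length(bad))
      stop("row ", bad[1], ": level '", d[[cv]][bad[1]],
           "' of ", cv, " absent from the declared level set",
           call. = FALSE)
    for (l in setdiff(lv, ref))
      cols[[sprintf("%s[%s]", COVARIATE_PREFIX[[cv]], l)]] <-
        as.numeric(d[[cv]] == l)
  }
  X <- if (length(cols)) do.call(cbind, cols)
       else matrix(numeric(0), nrow(d), 0)
  schools <- sort(unique(d$school_id))
  new("DesignMatrix", X = X, offset = log(d$athlete_exposures),
      counts = as.integer(d$injuries),
      schoolIndex = match(d$school_id, schools), schoolLevels = schools,
      eventIndex = match(d$event_type, ls$event_type),
      eventLevels = ls$event_type)
}

#' Per-row log mean count under the log-linear model
#'
#' Evaluates `gamma + sum(effects) + zeta[school] + log(AEs)` per row —
#' the log of the expected injury count, i.e. log rate plus the exposure
#' offset. Effect parameters are matched to design columns by name; a
#' school effect is added whenever `zeta[...]` parameters are present.
#'
#' @param design A [DesignMatrix].
#' @param params Named numeric vector in the shared naming convention
#'   (`gamma`, `alpha[competition]`, ..., `zeta[school_001]`, ...).
#' @return Numeric vector of per-row log mean counts.
#' @export
linearPredictor <- function(design, params) {
  stopifnot(is(design, "DesignMatrix"))
  need <- colnames(design@X)
  missing <- setdiff(c("gamma", need), names(params))
  if (length(missing))
    stop("parameter(s) missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  eta <- params[["gamma"]] + design@offset
  if (length(need))
    eta <- eta + as.vector(design@X %*% params[need])
  zeta_names <- sprintf("zeta[%s]", design@schoolLevels)
  if (any(zeta_names %in% names(params))) {
    if (!all(zeta_names %in% names(params)))
      stop("school effects present but incomplete", call. = FALSE)
    eta <- eta + unname(params[zeta_names])[design@schoolIndex]
  }
  eta
}

#' Poisson log probability mass
#'
#' @param x Non-negative integer count(s).
#' @param mu Positive mean(s).
#' @return Log pmf, vectorized.
#' @export
poissonLogLik <- function(x, mu) {
  if (any(x < 0)) stop("x must be >= 0", call. = FALSE)
  if (any(mu <= 0)) stop("mu must be > 0", call. = FALSE)
  stats::dpois(x, mu, log = TRUE)
}

#' Negative binomial (NB2) log probability mass
#'
#' Mean `mu`, variance `mu + mu^2 / kappa`: the overdispersion `kappa`
#' inflates the variance above the Poisson, which is recovered as
#' `kappa -> Inf`.
#'
#' @param x Non-negative integer count(s).
#' @param mu Positive mean(s).
#' @param kappa Overdispersion (> 0).
#' @return Log pmf, vectorized.
#' @export
nbLogLik <- function(x, mu, kappa) {
  if (any(x < 0)) stop("x must be >= 0", call. = FALSE)
  if (any(mu <= 0)) stop("mu must be > 0", call. = FALSE)
  if (any(kappa <= 0)) stop("kappa must be > 0", call. = FALSE)
  stats::dnbinom(x, size = kappa, mu = mu, log = TRUE)
}

#' Zero-inflated negative binomial log probability mass
#'
#' A structural zero with probability `theta` mixed with an NB2 count:
#' `P(0) = theta + (1 - theta) NB(0)`, `P(x > 0) = (1 - theta) NB(x)`.
#'
#' @param x Non-negative integer count(s).
#' @param mu Positive NB mean(s).
#' @param kappa Overdispersion (> 0).
#' @param theta Structural-zero probability in `[0, 1]`.
#' @return Log pmf, vectorized.
#' @export
zinbLogLik <- function(x, mu, kappa, theta) {
  if (any(theta < 0 | theta > 1))
    stop("theta must lie in [0, 1]", call. = FALSE)
  nb <- nbLogLik(x, mu, kappa)
  n <- max(length(x), length(mu), length(kappa), length(theta))
  x <- rep_len(x, n); theta <- rep_len(theta, n)
  nb <- rep_len(nb, n)
  out <- numeric(n)
  zero <- x == 0L
  # log(theta + (1-theta) NB(0)) computed stably via log-sum-exp
  if (any(zero)) {
    lt <- ifelse(theta[zero] > 0, log(theta[zero]), -Inf)
    lnb <- log1p(-theta[zero]) + nb[zero]
    m <- pmax(lt, lnb)
    out[zero] <- m + log(exp(lt - m) + exp(lnb - m))
    out[zero][theta[zero] == 1] <- 0
  }
  out[!zero] <- log1p(-theta[!zero]) + nb[!zero]
  out
}

logCauchy <- function(x, scale) -log(pi * scale) - log1p((x / scale)^2)

#' Log prior density of a parameter vector
#'
#' The joint log prior on the constrained scale: Cauchy(0,
#' `priorScaleFixed`) on the intercept (unless a Gamma intercept prior is
#' declared) and every fixed effect; Normal(0, `sigma_zeta`) on each
#' school effect; half-Cauchy(0, `priorScaleSigma`) on `sigma_zeta` and
#' on the NB overdispersion `kappa_nb`; Uniform(0, 1) on each
#' zero-inflation probability `theta`. Returns `-Inf` outside the
#' support.
#'
#' @param params Named numeric vector (shared naming convention).
#' @param spec A [ModelSpec].
#' @return Scalar log density.
#' @export
logPrior <- function(params, spec) {
  stopifnot(is(spec, "ModelSpec"))
  nm <- names(params)
  lp <- 0
  g <- params[["gamma"]]
  if (identical(spec@priorIntercept$type, "gamma")) {
    a <- spec@priorIntercept$shape; r <- spec@priorIntercept$rate
    lp <- lp + stats::dgamma(exp(g), a, rate = r, log = TRUE) + g
  } else lp <- lp + logCauchy(g, spec@priorScaleFixed)
  fixed <- grepl("^(alpha|beta|epsilon|kappa_year)\\[", nm)
  lp <- lp + sum(logCauchy(params[fixed], spec@priorScaleFixed))
  zeta <- grepl("^zeta\\[", nm)
  if (any(zeta) || "sigma_zeta" %in% nm) {
    sigma <- params[["sigma_zeta"]]
    if (is.na(sigma) || sigma < 0) return(-Inf)
    lp <- lp + logCauchy(sigma, spec@priorScaleSigma) + log(2) +
      sum(stats::dnorm(params[zeta], 0, sigma, log = TRUE))
  }
  if ("kappa_nb" %in% nm) {
    k <- params[["kappa_nb"]]
    if (k <= 0) return(-Inf)
    lp <- lp + logCauchy(k, spec@priorScaleSigma) + log(2)
  }
  th <- grepl("^theta\\[", nm)
  if (any(th) && any(params[th] < 0 | params[th] > 1)) return(-Inf)
  unname(lp)
}

#' Pointwise log likelihood over posterior draws
#'
#' Entry (s, i) is the family log pmf of row i's observed count under
#' draw s, with school effects taken at their sampled values — the
#' matrix consumed by [psisLoo()].
#'
#' @param table The fitted [SurveillanceTable].
#' @param design The [DesignMatrix] from [buildDesign()] (rebuilt if
#'   `NULL`).
#' @param draws A [PosteriorDraws] fitted under `spec`.
#' @param spec The [ModelSpec]; defaults to the one stored in `draws`.
#' @return Numeric matrix `draws x rows`.
#' @export
pointwiseLogLik <- function(table, design = NULL, draws,
                            spec = fittedSpec(draws)) {
  stopifnot(is(draws, "PosteriorDraws"))
  if (!identical(spec@family, draws@spec@family))
    stop("family mismatch between spec and draws", call. = FALSE)
  if (is.null(design)) design <- buildDesign(table, spec)
  dm <- drawsMatrix(draws)
  x <- design@counts
  eff <- colnames(design@X)
  zeta_nm <- sprintf("zeta[%s]", design@schoolLevels)
  has_school <- familyHasSchool(spec@family) &&
    all(zeta_nm %in% colnames(dm))
  theta_nm <- sprintf("theta[%s]", design@eventLevels)
  out <- matrix(NA_real_, nrow(dm), length(x))
  for (s in seq_len(nrow(dm))) {
    q <- dm[s, ]
    eta <- q[["gamma"]] + design@offset
    if (length(eff)) eta <- eta + as.vector(design@X %*% q[eff])
    if (has_school) eta <- eta + unname(q[zeta_nm])[design@schoolIndex]
    mu <- exp(eta)
    out[s, ] <- switch(spec@family,
      poisson = ,
      poisson_school = poissonLogLik(x, mu),
      nb_school = nbLogLik(x, mu, q[["kappa_nb"]]),
      zinb_school = zinbLogLik(x, mu, q[["kappa_nb"]],
                               unname(q[theta_nm])[design@eventIndex]))
  }
  out
}
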