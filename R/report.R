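# Posterior summary tables, rate-ratio interpretation and the
# frequentist NB comparator.

# conventional row order: event, division, diagnosis, year contrasts,
# then intercept, scales and zero-inflation, then school effects
parameterOrder <- function(params) {
  rank <- function(p) {
    if (grepl("^alpha\\[", p)) 1
    else if (grepl("^beta\\[", p)) 2
    else if (grepl("^epsilon\\[", p)) 3
    else if (grepl("^kappa_year\\[", p)) 4
    else if (p == "gamma") 5
    else if (p == "sigma_zeta") 6
    else if (p == "kappa_nb") 7
    else if (grepl("^theta\\[", p)) 8
    else 9
  }
  params[order(vapply(params, rank, numeric(1)),
               match(params, params))]
}

contrastLabel <- function(param, spec) {
  m <- regmatches(param, regexec("^([a-z_]+)\\[(.+)\\]$", param))[[1]]
  if (length(m) != 3L) return(param)
  cov <- names(COVARIATE_PREFIX)[COVARIATE_PREFIX == m[2]]
  if (!length(cov) || !cov %in% names(spec@referenceLevels)) return(param)
  caps <- function(s) paste0(toupper(substring(s, 1, 1)), substring(s, 2))
  sprintf("%s (vs. %s)", caps(m[3]), caps(spec@referenceLevels[[cov]]))
}

#' Posterior summary table
#'
#' Mean, SD and equal-tailed credible bounds per parameter, ordered by
#' the conventional reporting layout (event, division, diagnosis and
#' year contrasts first, each labelled `"Competition (vs. Practice)"`
#' style, then intercept, scales and zero-inflation, then school
#' effects).
#'
#' @param draws A [PosteriorDraws].
#' @param level Credible level (default 0.95).
#' @param includeSchools Include the per-school effects (default TRUE).
#' @return `data.frame`: `parameter`, `label`, `mean`, `sd`, `lower`,
#'   `upper`.
#' @export
summarizePosterior <- function(draws, level = 0.95,
                               includeSchools = TRUE) {
  stopifnot(is(draws, "PosteriorDraws"))
  dm <- drawsMatrix(draws)
  params <- parameterOrder(colnames(dm))
  if (!includeSchools) params <- params[!grepl("^zeta\\[", params)]
  a <- (1 - level) / 2
  out <- data.frame(
    parameter = params,
    label = vapply(params, contrastLabel, character(1),
                   spec = draws@spec),
    mean = colMeans(dm[, params, drop = FALSE]),
    sd = apply(dm[, params, drop = FALSE], 2, stats::sd),
    lower = apply(dm[, params, drop = FALSE], 2, stats::quantile,
                  probs = a),
    upper = apply(dm[, params, drop = FALSE], 2, stats::quantile,
                  probs = 1 - a),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "level") <- level
  out
}

# round half away from zero, as in printed rate-ratio tables
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Exponentiate a log-scale summary into a rate ratio
#'
#' Componentwise exponential of a posterior mean and interval estimated
#' on the log rate scale, rounded half-up to one decimal by default: a
#' competition-vs-practice effect of 1.33 (1.23, 1.44) becomes a rate
#' ratio of 3.8 (3.4, 4.2) — the injury rate in competitions is 3.8
#' times the practice rate. Interval bounds are exponentiated directly
#' (no re-estimation on the ratio scale).
#'
#' @param logSummary Named numeric with elements `mean`, `lower`,
#'   `upper` (or a single number).
#' @param digits Decimal places of half-up rounding; `NA` skips
#'   rounding.
#' @return Named numeric: `ratio`, `lower`, `upper` (or a single ratio).
#' @examples
#' rateRatioTransform(c(mean = 1.33, lower = 1.23, upper = 1.44))
#' @export
rateRatioTransform <- function(logSummary, digits = 1) {
  out <- exp(unlist(logSummary))
  if (!is.na(digits)) out <- roundHalfUp(out, digits)
  if (all(c("mean", "lower", "upper") %in% names(out)))
    c(ratio = unname(out[["mean"]]), lower = unname(out[["lower"]]),
      upper = unname(out[["upper"]]))
  else out
}

#' Rate-ratio table from a posterior summary
#'
#' @param summary A summary `data.frame` from [summarizePosterior()].
#' @param digits Half-up rounding digits (default 1).
#' @return The summary restricted to fixed-effect contrasts with
#'   `rate_ratio`, `ratio_lower`, `ratio_upper` columns appended.
#' @export
rateRatioTable <- function(summary, digits = 1) {
  keep <- grepl("^(alpha|beta|epsilon|kappa_year)\\[", summary$parameter)
  out <- summary[keep, , drop = FALSE]
  rr <- t(apply(out[, c("mean", "lower", "upper")], 1, function(r)
    rateRatioTransform(c(mean = r[1], lower = r[2], upper = r[3]),
                       digits = digits)))
  out$rate_ratio <- rr[, 1]; out$ratio_lower <- rr[, 2]
  out$ratio_upper <- rr[, 3]
  rownames(out) <- NULL
  out
}

#' Frequentist negative binomial comparator
#'
#' Fits the same NB model in the frequentist framework — maximum
#' likelihood NB2 regression with a log-AE offset and a school random
#' intercept (Laplace approximation, via glmmTMB) — and reports Wald 95%
#' intervals per fixed effect, mapped to the shared parameter naming
#' convention. With weakly informative priors and dense data the
#' Bayesian and frequentist estimates coincide closely.
#'
#' @param table A validated single-sport [SurveillanceTable].
#' @param spec A [ModelSpec] with `family = "nb_school"`.
#' @param level Confidence level (default 0.95).
#' @return List of class `frequentistFit`: `estimates` (`data.frame`
#'   with `parameter`, `estimate`, `lower`, `upper`), `sigma_school`,
#'   `overdispersion`, `converged`, `method`.
#' @export
fitFrequentistNB <- function(table, spec, level = 0.95) {
  stopifnot(is(table, "SurveillanceTable"), is(spec, "ModelSpec"))
  if (spec@family != "nb_school")
    stop("the frequentist comparator is defined for family 'nb_school'",
         call. = FALSE)
  assertSingleSport(table)
  d <- strataData(table)
  ls <- levelSets(table)
  for (cv in spec@covariates)
    d[[cv]] <- stats::relevel(factor(d[[cv]], levels = ls[[cv]]),
                              ref = spec@referenceLevels[[cv]])
  rhs <- if (length(spec@covariates))
    paste(spec@covariates, collapse = " + ") else "1"
  form <- stats::as.formula(paste(
    "injuries ~", rhs,
    "+ (1 | school_id) + offset(log(athlete_exposures))"))
  fit <- glmmTMB::glmmTMB(form, data = d, family = glmmTMB::nbinom2())
  converged <- isTRUE(fit$fit$convergence == 0) &&
    !isTRUE(fit$sdr$pdHess == FALSE)
  if (!converged)
    warning("frequentist NB fit did not converge cleanly", call. = FALSE)
  co <- summary(fit)$coefficients$cond
  z <- stats::qnorm(1 - (1 - level) / 2)
  # map "event_typecompetition" -> "alpha[competition]"
  mapName <- function(nm) {
    if (nm == "(Intercept)") return("gamma")
    for (cv in spec@covariates)
      if (startsWith(nm, cv))
        return(sprintf("%s[%s]", COVARIATE_PREFIX[[cv]],
                       substring(nm, nchar(cv) + 1L)))
    nm
  }
  est <- data.frame(
    parameter = vapply(rownames(co), mapName, character(1)),
    estimate = co[, "Estimate"],
    lower = co[, "Estimate"] - z * co[, "Std. Error"],
    upper = co[, "Estimate"] + z * co[, "Std. Error"],
    row.names = NULL, stringsAsFactors = FALSE)
  est <- est[match(parameterOrder(est$parameter), est$parameter), ]
  rownames(est) <- NULL
  structure(list(estimates = est,
                 sigma_school = sqrt(unname(
                   glmmTMB::VarCorr(fit)$cond$school_id[1, 1])),
                 overdispersion = glmmTMB::sigma(fit),
                 converged = converged,
                 method = "glmmTMB nbinom2, Laplace approximation"),
            class = "frequentistFit")
}

#' @export
print.frequentistFit <- function(x, ...) {
  cat("Frequentist NB comparator (", x$method, ")\n", sep = "")
  cat("  converged:", x$converged,
      " sigma_school:", format(x$sigma_school, digits = 3),
      " overdispersion:", format(x$overdispersion, digits = 3), "\n")
  print(x$estimates, digits = 3)
  invisible(x)
}
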