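# Posterior predictive replicate generation and the four-part check
# suite: maxima exceedance, zero proportions, actual-vs-predicted rates,
# randomized PIT calibration.

# evenly thinned flat draw indices (chain-major flattening)
thinDrawIndices <- function(nDraws, nReplicates) {
  unique(round(seq(1, nDraws, length.out = nReplicates)))
}

drawMu <- function(q, design) {
  eta <- q[["gamma"]] + design@offset
  eff <- colnames(design@X)
  if (length(eff)) eta <- eta + as.vector(design@X %*% q[eff])
  zeta_nm <- sprintf("zeta[%s]", design@schoolLevels)
  if (all(zeta_nm %in% names(q)))
    eta <- eta + unname(q[zeta_nm])[design@schoolIndex]
  exp(eta)
}

#' Generate posterior predictive replicate datasets
#'
#' Each replicate is a full simulated count dataset aligned to the
#' observed rows: one distinct posterior draw (thinned evenly across
#' chains) supplies the parameters, and counts are simulated from the
#' fitted family with the observed athlete exposures as offsets.
#'
#' @param draws A [PosteriorDraws].
#' @param table The observed [SurveillanceTable] the model was fitted to.
#' @param spec The [ModelSpec]; defaults to the fitted one.
#' @param nReplicates Number of replicates (default 1000 or the number
#'   of posterior draws, whichever is smaller).
#' @param seed Integer seed for the count simulation.
#' @return A [PpcReplicates].
#' @export
generateReplicates <- function(draws, table, spec = fittedSpec(draws),
                               nReplicates = NULL, seed = 1L) {
  stopifnot(is(draws, "PosteriorDraws"))
  dm <- drawsMatrix(draws)
  if (is.null(nReplicates)) nReplicates <- min(1000L, nrow(dm))
  if (nReplicates > nrow(dm))
    stop("nReplicates (", nReplicates, ") exceeds available draws (",
         nrow(dm), ")", call. = FALSE)
  design <- buildDesign(table, spec)
  idx <- thinDrawIndices(nrow(dm), nReplicates)
  theta_nm <- sprintf("theta[%s]", design@eventLevels)
  set.seed(as.integer(seed))
  n <- length(design@counts)
  counts <- matrix(0L, length(idx), n)
  for (r in seq_along(idx)) {
    q <- dm[idx[r], ]
    mu <- drawMu(q, design)
    counts[r, ] <- switch(spec@family,
      poisson = ,
      poisson_school = stats::rpois(n, mu),
      nb_school = stats::rnbinom(n, size = q[["kappa_nb"]], mu = mu),
      zinb_school = {
        th <- unname(q[theta_nm])[design@eventIndex]
        z <- stats::rbinom(n, 1L, th)
        ifelse(z == 1L, 0L,
               stats::rnbinom(n, size = q[["kappa_nb"]], mu = mu))
      })
  }
  new("PpcReplicates", counts = counts, drawIndices = as.integer(idx),
      seed = as.integer(seed))
}

setMethod("show", "PpcReplicates", function(object) {
  cat("PpcReplicates:", nrow(object@counts), "replicates x",
      ncol(object@counts), "rows (seed", object@seed, ")\n")
})

groupIndex <- function(table, grouping) {
  d <- strataData(table)
  bad <- setdiff(grouping, names(d))
  if (length(bad))
    stop("unknown grouping column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  interaction(d[grouping], drop = TRUE, sep = " / ", lex.order = TRUE)
}

#' Maxima-exceedance posterior predictive check
#'
#' Per group, the percentage of replicate datasets whose within-group
#' maximum count strictly exceeds the observed within-group maximum.
#' Percentages near zero across groups indicate the model cannot produce
#' extremes as large as those observed (the characteristic failure of an
#' equidispersed Poisson fit to overdispersed surveillance counts); ties
#' count as non-exceedance.
#'
#' @param table Observed [SurveillanceTable].
#' @param reps A [PpcReplicates] aligned to `table`.
#' @param grouping Covariate columns defining the groups (default
#'   division by event type, points per diagnosis within sport).
#' @return `data.frame`: `group`, `observed_max`, `exceedance_pct`.
#' @export
maximaCheck <- function(table, reps,
                        grouping = c("division", "event_type",
                                     "diagnosis")) {
  stopifnot(is(reps, "PpcReplicates"))
  g <- groupIndex(table, grouping)
  x <- strataData(table)$injuries
  out <- lapply(levels(g), function(lv) {
    sel <- which(g == lv)
    if (!length(sel)) return(NULL)
    obs_max <- max(x[sel])
    rep_max <- apply(reps@counts[, sel, drop = FALSE], 1, max)
    data.frame(group = lv, observed_max = obs_max,
               exceedance_pct = 100 * mean(rep_max > obs_max),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Zero-proportion posterior predictive check
#'
#' Per group, the observed percentage of zero-count strata against the
#' equal-tailed credible interval of the same percentage in the
#' replicate datasets, with an inside/outside flag.
#'
#' @param table Observed [SurveillanceTable].
#' @param reps A [PpcReplicates].
#' @param grouping Covariate columns defining the groups.
#' @param intervalLevel Credible level of the replicate interval
#'   (default 0.95).
#' @return `data.frame`: `group`, `observed_zero_pct`, `lower`, `upper`,
#'   `inside`.
#' @export
zeroProportionCheck <- function(table, reps,
                                grouping = c("division", "event_type"),
                                intervalLevel = 0.95) {
  stopifnot(is(reps, "PpcReplicates"))
  g <- groupIndex(table, grouping)
  x <- strataData(table)$injuries
  a <- (1 - intervalLevel) / 2
  out <- lapply(levels(g), function(lv) {
    sel <- which(g == lv)
    if (!length(sel)) return(NULL)
    obs <- 100 * mean(x[sel] == 0L)
    rep_zero <- 100 * rowMeans(reps@counts[, sel, drop = FALSE] == 0L)
    qs <- unname(stats::quantile(rep_zero, c(a, 1 - a), type = 7))
    data.frame(group = lv, observed_zero_pct = obs, lower = qs[1],
               upper = qs[2], inside = obs >= qs[1] & obs <= qs[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Actual versus posterior-predicted injury rates
#'
#' Per observed row, the posterior predictive median rate and
#' equal-tailed credible interval (replicate count over AEs, per
#' `rateScale` AEs), together with the ordinary-least-squares regression
#' of the predictive medians on the actual rates — slope near 1 and
#' intercept near 0 indicate calibrated predictions. Intervals on the
#' actual rates are Jeffreys Gamma intervals on the observed count (a
#' reporting convention of this package; the observed rate itself
#' carries no posterior).
#'
#' @param table Observed [SurveillanceTable].
#' @param reps A [PpcReplicates].
#' @param rateScale Rate standardization (default per 10,000 AEs).
#' @param intervalLevel Credible level for the error bars (default 0.90).
#' @return List with `rows` (per-row `data.frame`) and `regression`
#'   (`slope`, `intercept`).
#' @export
actualVsPredicted <- function(table, reps, rateScale = 10000,
                              intervalLevel = 0.90) {
  stopifnot(is(reps, "PpcReplicates"))
  d <- strataData(table)
  a <- (1 - intervalLevel) / 2
  rates <- sweep(reps@counts, 2, d$athlete_exposures, "/") * rateScale
  qs <- apply(rates, 2, stats::quantile, probs = c(a, 0.5, 1 - a))
  actual <- computeRawRate(d$injuries, d$athlete_exposures, rateScale)
  act_lo <- stats::qgamma(a, d$injuries + 0.5) /
    d$athlete_exposures * rateScale
  act_hi <- stats::qgamma(1 - a, d$injuries + 0.5) /
    d$athlete_exposures * rateScale
  rows <- data.frame(actual_rate = actual, actual_lower = act_lo,
                     actual_upper = act_hi, predicted_median = qs[2, ],
                     predicted_lower = qs[1, ], predicted_upper = qs[3, ])
  fit <- stats::lm(predicted_median ~ actual_rate, data = rows)
  list(rows = rows,
       regression = c(slope = unname(stats::coef(fit)[2]),
                      intercept = unname(stats::coef(fit)[1])))
}

familyCdf <- function(x, mu, family, kappa = NULL, theta = NULL) {
  base <- switch(family,
    poisson = ,
    poisson_school = stats::ppois(x, mu),
    nb_school = stats::pnbinom(x, size = kappa, mu = mu),
    zinb_school = theta + (1 - theta) *
      stats::pnbinom(x, size = kappa, mu = mu))
  ifelse(x < 0, 0, base)
}

#' Randomized PIT calibration check
#'
#' Probability integral transform for discrete counts: the predictive
#' CDF, averaged over (thinned) posterior draws, is evaluated at the
#' observed count and at the count minus one, and the PIT value is drawn
#' uniformly between the two — under a correctly specified model the PIT
#' values are uniform on (0, 1). Reports per-observation PIT values, the
#' Kolmogorov-Smirnov distance from uniformity, and a pointwise 95%
#' envelope of the uniform eCDF obtained by simulation at matching
#' sample size.
#'
#' @param table Observed [SurveillanceTable].
#' @param draws A [PosteriorDraws].
#' @param spec The [ModelSpec]; defaults to the fitted one.
#' @param seed Seed for the PIT randomization and envelope simulation.
#' @param nDraws Number of thinned draws the CDF is averaged over
#'   (default 500).
#' @param nEnvelope Uniform simulations for the envelope (default 1000).
#' @return List with `pit` (per-row values), `ks` (KS distance from
#'   uniform), `ecdf` (`data.frame`: `u`, `ecdf`, `lower`, `upper`) and
#'   `inside_envelope` (fraction of grid points inside).
#' @export
pitCheck <- function(table, draws, spec = fittedSpec(draws), seed = 1L,
                     nDraws = 500L, nEnvelope = 1000L) {
  stopifnot(is(draws, "PosteriorDraws"))
  design <- buildDesign(table, spec)
  dm <- drawsMatrix(draws)
  idx <- thinDrawIndices(nrow(dm), min(nDraws, nrow(dm)))
  x <- design@counts
  theta_nm <- sprintf("theta[%s]", design@eventLevels)
  Fx <- numeric(length(x)); Fxm1 <- numeric(length(x))
  for (s in idx) {
    q <- dm[s, ]
    mu <- drawMu(q, design)
    kappa <- if ("kappa_nb" %in% names(q)) q[["kappa_nb"]] else NULL
    theta <- if (spec@family == "zinb_school")
      unname(q[theta_nm])[design@eventIndex] else NULL
    Fx <- Fx + familyCdf(x, mu, spec@family, kappa, theta)
    Fxm1 <- Fxm1 + familyCdf(x - 1L, mu, spec@family, kappa, theta)
  }
  Fx <- Fx / length(idx); Fxm1 <- Fxm1 / length(idx)
  set.seed(as.integer(seed))
  pit <- stats::runif(length(x), Fxm1, Fx)
  ks <- suppressWarnings(stats::ks.test(pit, "punif"))$statistic
  grid <- seq(0, 1, length.out = 101)
  emp <- stats::ecdf(pit)(grid)
  sims <- matrix(stats::runif(nEnvelope * length(x)), nEnvelope)
  sim_ecdf <- apply(sims, 1, function(u) stats::ecdf(u)(grid))
  env <- apply(sim_ecdf, 1, stats::quantile, probs = c(0.025, 0.975))
  inside <- emp >= env[1, ] & emp <= env[2, ]
  list(pit = pit, ks = unname(ks),
       ecdf = data.frame(u = grid, ecdf = emp, lower = env[1, ],
                         upper = env[2, ]),
       inside_envelope = mean(inside))
}
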