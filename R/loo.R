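# Pareto-smoothed importance-sampling leave-one-out cross-validation.

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# profile-likelihood Bayesian estimate of the generalized Pareto shape
# (Zhang & Stephens 2009), with the weak prior pull toward k = 1/2 used
# for stabilizing small tails
gpdFit <- function(y) {
  y <- sort(y)
  n <- length(y)
  m <- 30L + floor(sqrt(n))
  quartile <- y[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / y[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) / (3 * quartile)
  profll <- vapply(theta, function(th) {
    k <- -mean(log1p(-th * y))
    n * (log(th / k) + k - 1)
  }, numeric(1))
  w <- exp(profll - logSumExp(profll))
  th_hat <- sum(theta * w)
  k <- -mean(log1p(-th_hat * y))
  sigma <- k / th_hat
  k <- (n * k + 5) / (n + 10)   # prior regularization toward 0.5
  c(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

# smooth the largest importance log-weights of one observation
psisSmooth <- function(lw) {
  S <- length(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5L) return(list(lw = lw, k = NA_real_))
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1):S]
  cutoff <- lw[ord[S - M]]
  exc <- exp(lw[tail_ids]) - exp(cutoff)
  if (all(exc <= 0) || length(unique(exc)) < 2L)
    return(list(lw = lw, k = NA_real_))
  fit <- gpdFit(exc)
  smoothed <- log(qgpd((seq_len(M) - 0.5) / M, fit[["k"]],
                       fit[["sigma"]]) + exp(cutoff))
  lw[tail_ids[order(exc)]] <- pmin(sort(smoothed), max(lw))
  list(lw = lw, k = fit[["k"]])
}

#' PSIS-LOO expected log pointwise predictive density
#'
#' Approximates exact leave-one-out cross-validation from a single
#' posterior sample: per observation, importance ratios proportional to
#' the inverse pointwise likelihood are tail-smoothed by a generalized
#' Pareto fit, and the pointwise ELPD is the smoothed-weighted average
#' of the predictive density. Observations whose Pareto shape diagnostic
#' exceeds 0.7 are flagged as unreliable (for small data, exact refits
#' are the documented fallback).
#'
#' @param logLik Numeric matrix, posterior draws by observations, of
#'   pointwise log likelihoods (e.g. from [pointwiseLogLik()]).
#' @param label Model label carried into comparison tables.
#' @return List of class `looResult`: `label`, `elpd`, `elpd_se`,
#'   `pointwise`, `pareto_k`, `n_flagged`.
#' @export
psisLoo <- function(logLik, label = "model") {
  logLik <- as.matrix(logLik)
  if (any(!is.finite(logLik))) {
    bad <- which(apply(logLik, 2, function(c) any(!is.finite(c))))
    stop("non-finite log likelihood for observation(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  S <- nrow(logLik); n <- ncol(logLik)
  if (S < 100)
    warning("only ", S, " draws; PSIS-LOO is unreliable below ~100",
            call. = FALSE)
  pointwise <- numeric(n)
  k <- numeric(n)
  for (i in seq_len(n)) {
    ll <- logLik[, i]
    lw <- -ll
    lw <- lw - max(lw)
    sm <- psisSmooth(lw)
    pointwise[i] <- logSumExp(sm$lw + ll) - logSumExp(sm$lw)
    k[i] <- sm$k
  }
  structure(list(label = label, elpd = sum(pointwise),
                 elpd_se = stats::sd(pointwise) * sqrt(n),
                 pointwise = pointwise, pareto_k = k,
                 n_flagged = sum(!is.na(k) & k > 0.7)),
            class = "looResult")
}

#' @export
print.looResult <- function(x, ...) {
  cat(sprintf("PSIS-LOO [%s]: elpd %.1f (se %.1f), %d observation(s)",
              x$label, x$elpd, x$elpd_se, length(x$pointwise)))
  if (x$n_flagged > 0)
    cat(sprintf("; %d with Pareto k > 0.7", x$n_flagged))
  cat("\n")
  invisible(x)
}

#' Rank models by out-of-sample predictive accuracy
#'
#' Orders [psisLoo()] results by ELPD (higher, i.e. closer to zero, is
#' better) and reports each model's ELPD difference from the top model
#' with the standard error of the pointwise differences — the scale on
#' which "within 2 SE" comparability is judged. All results must cover
#' the same observations in the same order.
#'
#' @param loos List of `looResult` objects.
#' @return `data.frame` ranked by ELPD: `model`, `elpd`, `elpd_se`,
#'   `elpd_diff`, `diff_se`, `n_flagged`.
#' @export
compareModels <- function(loos) {
  if (inherits(loos, "looResult")) loos <- list(loos)
  ns <- vapply(loos, function(l) length(l$pointwise), integer(1))
  if (length(unique(ns)) != 1L)
    stop("models were evaluated on different observation sets",
         call. = FALSE)
  elpd <- vapply(loos, `[[`, numeric(1), "elpd")
  ord <- order(elpd, decreasing = TRUE)
  best <- loos[[ord[1]]]
  rows <- lapply(ord, function(i) {
    l <- loos[[i]]
    dif <- l$pointwise - best$pointwise
    data.frame(model = l$label, elpd = l$elpd, elpd_se = l$elpd_se,
               elpd_diff = sum(dif),
               diff_se = stats::sd(dif) * sqrt(length(dif)),
               n_flagged = l$n_flagged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exact leave-one-out ELPD by refitting (oracle for small data)
#'
#' Refits the model once per held-out observation and evaluates the
#' log posterior predictive density of the held-out count by averaging
#' its likelihood over the refitted draws. Computationally exact but
#' only feasible for small tables; used to validate [psisLoo()].
#'
#' @param table A small [SurveillanceTable].
#' @param spec A [ModelSpec].
#' @param mcmc A [McmcConfig].
#' @return List: `elpd`, `pointwise`.
#' @export
exactLooRefit <- function(table, spec, mcmc) {
  d <- strataData(table)
  n <- nrow(d)
  pointwise <- numeric(n)
  for (i in seq_len(n)) {
    train <- surveillanceTable(d[-i, , drop = FALSE],
                               levelSets = levelSets(table))
    fit <- fitModel(train, spec, mcmc)
    held <- surveillanceTable(d[i, , drop = FALSE],
                              levelSets = levelSets(table))
    ll <- pointwiseLogLik(held, draws = fit, spec = spec)
    pointwise[i] <- logSumExp(ll[, 1]) - log(nrow(ll))
  }
  list(elpd = sum(pointwise), pointwise = pointwise)
}
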