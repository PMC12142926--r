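# Rank-normalized split R-hat and bulk effective sample size, computed
# from an iterations x chains matrix of draws for one parameter.

splitChains <- function(x) {
  n <- nrow(x)
  h <- floor(n / 2)
  cbind(x[seq_len(h), , drop = FALSE],
        x[(n - h + 1):n, , drop = FALSE])
}

# fractional-offset normal scores of the pooled draws
rankNormalize <- function(x) {
  r <- rank(x, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
  matrix(z, nrow(x), ncol(x))
}

isConstant <- function(x, tol = 1e-12) {
  diff(range(x)) <= tol * max(1, abs(mean(x)))
}

rhatBasic <- function(x) {
  n <- nrow(x); m <- ncol(x)
  cm <- colMeans(x)
  W <- mean(apply(x, 2, stats::var))
  B <- n * stats::var(cm)
  varplus <- (n - 1) / n * W + B / n
  if (W <= 0) return(NA_real_)
  sqrt(varplus / W)
}

#' Rank-normalized split R-hat for one parameter
#'
#' Chains are split in half, pooled draws are replaced by normal scores
#' of their ranks, and the classical between/within variance-ratio
#' diagnostic is taken as the larger of the bulk value and the value on
#' folded (median-absolute) draws, so both location and scale
#' disagreements between chains are detected. Values near 1 indicate
#' convergence. Constant chains return exactly 1 (degenerate case).
#'
#' @param x Numeric matrix, iterations by chains (>= 2 chains, >= 4
#'   iterations).
#' @return Scalar R-hat.
#' @export
computeRhat <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("R-hat requires at least 2 chains",
                         call. = FALSE)
  if (nrow(x) < 4L) stop("R-hat requires at least 4 draws per chain",
                         call. = FALSE)
  if (isConstant(x)) return(1)
  s <- splitChains(x)
  bulk <- rhatBasic(rankNormalize(s))
  folded <- rhatBasic(rankNormalize(abs(s - stats::median(s))))
  max(bulk, folded, na.rm = TRUE)
}

# Geyer initial-monotone-positive-sequence ESS of split, rank-normalized
# chains
essCore <- function(x) {
  n <- nrow(x); m <- ncol(x)
  chain_var <- apply(x, 2, stats::var)
  W <- mean(chain_var)
  varplus <- (n - 1) / n * W + n * stats::var(colMeans(x)) / n
  # per-chain autocovariances via FFT
  acov <- vapply(seq_len(m), function(j) {
    v <- x[, j] - mean(x[, j])
    nfft <- stats::nextn(2 * n)
    f <- stats::fft(c(v, rep(0, nfft - n)))
    ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / nfft
    ac / ac[1] * chain_var[j] * (n - 1) / n
  }, numeric(n))
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / varplus
  # Geyer: initial positive monotone sequence of lag pairs
  # (rho_0 + rho_1), (rho_2 + rho_3), ...
  maxlag <- n - 4
  pairs <- numeric(0)
  t <- 0
  while (t + 2 <= maxlag) {
    pr <- rho[t + 1] + rho[t + 2]
    if (!is.finite(pr) || pr < 0) break
    pairs <- c(pairs, pr)
    t <- t + 2
  }
  if (!length(pairs)) pairs <- max(rho[1], 0)
  tau <- max(-rho[1] + 2 * sum(cummin(pairs)), 1 / (n * m))
  n * m / tau
}

#' Bulk effective sample size for one parameter
#'
#' Split chains are rank-normalized and the effective sample size is
#' estimated from the chain-combined autocorrelation sequence using the
#' initial monotone positive-pair truncation. Constant chains are
#' degenerate and report 0.
#'
#' @param x Numeric matrix, iterations by chains.
#' @return Scalar ESS estimate.
#' @export
computeESS <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("ESS requires at least 2 chains", call. = FALSE)
  if (nrow(x) < 4L) stop("ESS requires at least 4 draws per chain",
                         call. = FALSE)
  if (isConstant(x)) return(0)
  z <- rankNormalize(splitChains(x))
  essCore(z)
}

#' Convergence report for a fitted model
#'
#' Applies [computeRhat()] and [computeESS()] to every parameter and
#' compares them to the conventional thresholds: convergence is flagged
#' only if R-hat is at most `rhatThreshold` (default 1.01) and ESS at
#' least `essThreshold` (default 400) for all parameters. Parameters are
#' listed worst-first.
#'
#' @param draws A [PosteriorDraws].
#' @param rhatThreshold,essThreshold Pass thresholds.
#' @return A [ConvergenceReport].
#' @export
checkConvergence <- function(draws, rhatThreshold = 1.01,
                             essThreshold = 400) {
  stopifnot(is(draws, "PosteriorDraws"))
  a <- drawsArray(draws)
  params <- dimnames(a)[[3]]
  if (!length(params)) stop("no parameters in draws", call. = FALSE)
  tab <- data.frame(
    parameter = params,
    rhat = vapply(params, function(p) computeRhat(a[, , p]), numeric(1)),
    ess = vapply(params, function(p) computeESS(a[, , p]), numeric(1)),
    degenerate = vapply(params, function(p) isConstant(a[, , p]),
                        logical(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  tab <- tab[order(-tab$rhat, tab$ess), , drop = FALSE]
  rownames(tab) <- NULL
  new("ConvergenceReport", table = tab,
      passRhat = all(tab$rhat <= rhatThreshold),
      passEss = all(tab$ess >= essThreshold),
      rhatThreshold = rhatThreshold, essThreshold = essThreshold)
}

#' @describeIn checkConvergence Accessor for the per-parameter table.
#' @param report A [ConvergenceReport].
#' @export
convergenceTable <- function(report) report@table

#' @describeIn checkConvergence TRUE iff both pass flags hold.
#' @export
convergencePassed <- function(report) report@passRhat && report@passEss

setMethod("show", "ConvergenceReport", function(object) {
  t <- object@table
  cat("ConvergenceReport over", nrow(t), "parameters\n")
  cat(sprintf("  max R-hat %.4f (threshold %.2f): %s\n", max(t$rhat),
              object@rhatThreshold,
              if (object@passRhat) "PASS" else "FAIL"))
  cat(sprintf("  min ESS %.0f (threshold %.0f): %s\n", min(t$ess),
              object@essThreshold,
              if (object@passEss) "PASS" else "FAIL"))
  worst <- utils::head(t, 3)
  cat("  worst parameters:",
      paste(sprintf("%s (rhat %.3f, ess %.0f)", worst$parameter,
                    worst$rhat, worst$ess), collapse = "; "), "\n")
})

#' Convergence report as JSON
#'
#' @param report A [ConvergenceReport].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeConvergenceReport <- function(report, path) {
  jsonlite::write_json(
    list(pass_rhat = report@passRhat, pass_ess = report@passEss,
         rhat_threshold = report@rhatThreshold,
         ess_threshold = report@essThreshold,
         parameters = report@table),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
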