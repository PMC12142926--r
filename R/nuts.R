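# Adaptive Hamiltonian sampler (dynamic no-U-turn trajectories, dual-
# averaging step size, windowed diagonal mass adaptation). The backend
# contract is a log joint density with gradients on the unconstrained
# scale; the compiled kernels in src/ provide it for the four families.

#' Construct a sampler configuration
#'
#' @param chains Number of chains (>= 2; default 4).
#' @param warmupIterations,samplingIterations Iterations per chain
#'   (default 1000 each).
#' @param seed Integer seed; each chain's RNG stream is derived from it.
#' @param targetAcceptance Dual-averaging target (default 0.9).
#' @param maxTreedepth Maximum trajectory doubling depth (default 10).
#' @return A [McmcConfig].
#' @export
mcmcConfig <- function(chains = 4L, warmupIterations = 1000L,
                       samplingIterations = 1000L, seed = 1L,
                       targetAcceptance = 0.9, maxTreedepth = 10L) {
  new("McmcConfig", chains = as.integer(chains),
      warmupIterations = as.integer(warmupIterations),
      samplingIterations = as.integer(samplingIterations),
      seed = as.integer(seed), targetAcceptance = targetAcceptance,
      maxTreedepth = as.integer(maxTreedepth))
}

setMethod("show", "McmcConfig", function(object) {
  cat("McmcConfig:", object@chains, "chains x", object@warmupIterations,
      "warmup +", object@samplingIterations, "sampling iterations, seed",
      object@seed, "\n")
})

# unconstrained-scale model bound to a design: log density + gradient
# callback, parameter naming and the constraining transform
modelEnvironment <- function(design, spec) {
  family_code <- match(spec@family, MODEL_FAMILIES) - 1L
  p <- ncol(design@X)
  S <- length(design@schoolLevels)
  E <- length(design@eventLevels)
  names_con <- c("gamma", colnames(design@X))
  if (family_code >= 1L)
    names_con <- c(names_con, sprintf("zeta[%s]", design@schoolLevels),
                   "sigma_zeta")
  if (family_code >= 2L) names_con <- c(names_con, "kappa_nb")
  if (family_code == 3L)
    names_con <- c(names_con, sprintf("theta[%s]", design@eventLevels))
  d <- length(names_con)
  ip <- spec@priorIntercept
  ip_type <- if (identical(ip$type, "gamma")) 1L else 0L
  ip_shape <- if (ip_type) ip$shape else 0
  ip_rate <- if (ip_type) ip$rate else 0
  lpGrad <- function(q)
    lpGradCpp(q, design@counts, design@X, design@offset,
              design@schoolIndex, S, design@eventIndex, E, family_code,
              spec@priorScaleFixed, spec@priorScaleSigma,
              ip_type, ip_shape, ip_rate)
  constrain <- function(q) {
    out <- q
    i <- 1L + p
    if (family_code >= 1L) {
      i <- i + S + 1L
      out[i] <- exp(q[i])            # sigma_zeta
    }
    if (family_code >= 2L) {
      i <- i + 1L
      out[i] <- exp(q[i])            # kappa_nb
    }
    if (family_code == 3L)
      out[(i + 1L):(i + E)] <- stats::plogis(q[(i + 1L):(i + E)])
    stats::setNames(out, names_con)
  }
  list(lpGrad = lpGrad, dim = d, names = names_con, constrain = constrain)
}

kinetic <- function(p, invM) 0.5 * sum(p * p * invM)

leapfrog <- function(q, p, grad, eps, lpGrad, invM) {
  p <- p + 0.5 * eps * grad
  q <- q + eps * invM * p
  st <- lpGrad(q)
  p <- p + 0.5 * eps * st$grad
  list(q = q, p = p, grad = st$grad, lp = st$lp)
}

findStepsize <- function(q0, st0, lpGrad, invM) {
  eps <- 1
  d <- length(q0)
  p0 <- stats::rnorm(d) / sqrt(invM)
  H0 <- st0$lp - kinetic(p0, invM)
  s <- leapfrog(q0, p0, st0$grad, eps, lpGrad, invM)
  H1 <- s$lp - kinetic(s$p, invM)
  if (!is.finite(H1)) {
    while (!is.finite(H1) && eps > 1e-10) {
      eps <- eps / 2
      s <- leapfrog(q0, p0, st0$grad, eps, lpGrad, invM)
      H1 <- s$lp - kinetic(s$p, invM)
    }
  }
  a <- if (is.finite(H1) && H1 - H0 > log(0.5)) 1 else -1
  while (eps > 1e-10 && eps < 1e7) {
    s <- leapfrog(q0, p0, st0$grad, eps, lpGrad, invM)
    H1 <- s$lp - kinetic(s$p, invM)
    dH <- if (is.finite(H1)) H1 - H0 else -Inf
    if (a == 1 && dH <= log(0.5)) break
    if (a == -1 && dH >= log(0.5)) break
    eps <- eps * 2^a
  }
  eps
}

# recursive trajectory doubling (slice formulation); divergence at
# energy error > 1000
buildTree <- function(st, logu, dir, depth, eps, H0, lpGrad, invM,
                      env) {
  if (depth == 0L) {
    s1 <- leapfrog(st$q, st$p, st$grad, dir * eps, lpGrad, invM)
    H <- if (is.finite(s1$lp)) s1$lp - kinetic(s1$p, invM) else -Inf
    n1 <- as.integer(is.finite(H) && logu <= H)
    div <- !is.finite(H) || logu > H + 1000
    if (div) env$divergent <- TRUE
    env$alpha <- env$alpha + min(1, if (is.finite(H)) exp(H - H0) else 0)
    env$nalpha <- env$nalpha + 1L
    return(list(minus = s1, plus = s1, prop = s1, n = n1,
                stop = div))
  }
  t1 <- buildTree(st, logu, dir, depth - 1L, eps, H0, lpGrad, invM, env)
  if (t1$stop) return(t1)
  inner <- if (dir == -1) t1$minus else t1$plus
  t2 <- buildTree(inner, logu, dir, depth - 1L, eps, H0, lpGrad, invM,
                  env)
  minus <- if (dir == -1) t2$minus else t1$minus
  plus <- if (dir == -1) t1$plus else t2$plus
  prop <- t1$prop
  ntot <- t1$n + t2$n
  if (t2$n > 0L && stats::runif(1) < t2$n / max(1L, ntot))
    prop <- t2$prop
  dq <- plus$q - minus$q
  uturn <- sum(dq * invM * minus$p) < 0 || sum(dq * invM * plus$p) < 0
  list(minus = minus, plus = plus, prop = prop, n = ntot,
       stop = t2$stop || uturn)
}

nutsTransition <- function(st, eps, maxDepth, lpGrad, invM, env) {
  d <- length(st$q)
  p0 <- stats::rnorm(d) / sqrt(invM)
  H0 <- st$lp - kinetic(p0, invM)
  logu <- H0 - stats::rexp(1)
  st$p <- p0
  minus <- st; plus <- st
  prop <- st
  n <- 1L
  depth <- 0L
  env$alpha <- 0; env$nalpha <- 0L
  env$divergent <- FALSE
  repeat {
    dir <- if (stats::runif(1) < 0.5) -1 else 1
    t <- if (dir == -1)
      buildTree(minus, logu, dir, depth, eps, H0, lpGrad, invM, env)
    else
      buildTree(plus, logu, dir, depth, eps, H0, lpGrad, invM, env)
    if (dir == -1) minus <- t$minus else plus <- t$plus
    if (!t$stop && t$n > 0L && stats::runif(1) < min(1, t$n / n))
      prop <- t$prop
    n <- n + t$n
    if (t$stop) break
    dq <- plus$q - minus$q
    if (sum(dq * invM * minus$p) < 0 || sum(dq * invM * plus$p) < 0)
      break
    depth <- depth + 1L
    if (depth >= maxDepth) break
  }
  prop$treedepth <- depth
  prop
}

# adaptation windows: step-size-only initial buffer, doubling
# mass-estimation windows, step-size-only terminal buffer
adaptationWindows <- function(W) {
  if (W < 150L) {
    init <- max(1L, floor(0.15 * W))
    term <- max(1L, floor(0.1 * W))
    return(list(init = init, ends = max(init + 1L, W - term)))
  }
  init <- 75L; term <- 50L; w <- 25L
  ends <- integer(0)
  pos <- init
  while (pos < W - term) {
    end <- if (pos + 2L * w >= W - term) W - term else pos + w
    ends <- c(ends, end)
    pos <- end
    w <- 2L * w
  }
  list(init = init, ends = ends)
}

nutsChain <- function(lpGrad, q0, warmup, sampling, targetAccept,
                      maxDepth, seed) {
  set.seed(seed)
  d <- length(q0)
  invM <- rep(1, d)
  st <- lpGrad(q0)
  if (!is.finite(st$lp))
    stop("non-finite joint density at the initial values", call. = FALSE)
  st <- list(q = q0, p = numeric(d), grad = st$grad, lp = st$lp)
  eps <- findStepsize(q0, st, lpGrad, invM)
  # dual averaging state
  mu <- log(10 * eps); logeps <- log(eps); logepsbar <- 0; Hbar <- 0
  gamma_da <- 0.05; t0 <- 10; kappa_da <- 0.75; da_iter <- 0L
  env <- new.env(parent = emptyenv())
  win <- adaptationWindows(warmup)
  win_buf <- NULL
  divergences <- 0L
  draws <- matrix(NA_real_, sampling, d)
  treedepths <- integer(sampling)
  for (i in seq_len(warmup + sampling)) {
    inWarmup <- i <= warmup
    st <- nutsTransition(st, exp(if (inWarmup) logeps else logepsbar),
                         maxDepth, lpGrad, invM, env)
    if (env$divergent && !inWarmup) divergences <- divergences + 1L
    if (inWarmup) {
      da_iter <- da_iter + 1L
      a <- if (env$nalpha > 0L) env$alpha / env$nalpha else 0
      Hbar <- (1 - 1 / (da_iter + t0)) * Hbar +
        (targetAccept - a) / (da_iter + t0)
      logeps <- mu - sqrt(da_iter) / gamma_da * Hbar
      w <- da_iter^(-kappa_da)
      logepsbar <- w * logeps + (1 - w) * logepsbar
      if (i > win$init) win_buf <- rbind(win_buf, st$q)
      if (i %in% win$ends && !is.null(win_buf) && nrow(win_buf) > 4L) {
        v <- apply(win_buf, 2, stats::var)
        nw <- nrow(win_buf)
        invM <- nw / (nw + 5) * v + 1e-3 * (5 / (nw + 5))
        win_buf <- NULL
        # re-initialize step-size adaptation under the new metric
        eps <- findStepsize(st$q, st, lpGrad, invM)
        mu <- log(10 * eps); logeps <- log(eps)
        logepsbar <- 0; Hbar <- 0; da_iter <- 0L
      }
    } else {
      j <- i - warmup
      draws[j, ] <- st$q
      treedepths[j] <- st$treedepth
    }
  }
  list(draws = draws, stepsize = exp(logepsbar),
       divergences = divergences, treedepths = treedepths)
}

dataFingerprint <- function(table) {
  d <- strataData(table)
  sprintf("n=%d;inj=%d;ae=%d;sports=%s", nrow(d), sum(d$injuries),
          sum(d$athlete_exposures),
          paste(sort(unique(d$sport)), collapse = "+"))
}

#' Fit a count-regression model by adaptive Hamiltonian MCMC
#'
#' Samples the posterior of the specified family on its unconstrained
#' scale with dynamic no-U-turn trajectories, dual-averaging step-size
#' adaptation and windowed diagonal mass-matrix estimation during warmup.
#' Chains are initialized in a small ball around zero, jittered per chain
#' from the seed; identical inputs and configuration reproduce identical
#' draws. The zero-inflation indicator of the ZINB family is marginalized
#' analytically, keeping the parameter space continuous.
#'
#' @param table A validated single-sport [SurveillanceTable].
#' @param spec A [ModelSpec].
#' @param mcmc A [McmcConfig].
#' @return A [PosteriorDraws] with post-warmup draws on the constrained
#'   scale.
#' @examples
#' \donttest{
#' sim <- generateDataset(defaultTruth("womens_soccer"),
#'                        defaultStructure("womens_soccer"))
#' fit <- fitModel(sim$table, modelSpec("nb_school"),
#'                 mcmcConfig(chains = 2, warmupIterations = 200,
#'                            samplingIterations = 200))
#' checkConvergence(fit)
#' }
#' @export
fitModel <- function(table, spec, mcmc = mcmcConfig()) {
  stopifnot(is(table, "SurveillanceTable"), is(spec, "ModelSpec"),
            is(mcmc, "McmcConfig"))
  validObject(spec); validObject(mcmc)
  assertSingleSport(table)
  report <- validateTable(table)
  if (nrow(report))
    stop("table fails validation; see validateTable()", call. = FALSE)
  design <- buildDesign(table, spec)
  env <- modelEnvironment(design, spec)
  draws <- array(NA_real_,
                 c(mcmc@samplingIterations, mcmc@chains, env$dim),
                 dimnames = list(NULL, NULL, env$names))
  stepsizes <- numeric(mcmc@chains)
  divergences <- integer(mcmc@chains)
  for (ch in seq_len(mcmc@chains)) {
    chain_seed <- (mcmc@seed + ch * 7919L) %% 2147483647L
    set.seed(chain_seed)
    q0 <- stats::runif(env$dim, -1, 1) * 0.25
    res <- tryCatch(
      nutsChain(env$lpGrad, q0, mcmc@warmupIterations,
                mcmc@samplingIterations, mcmc@targetAcceptance,
                mcmc@maxTreedepth, chain_seed),
      error = function(e)
        stop("sampler failure in chain ", ch, " (family ", spec@family,
             ", ", env$dim, " parameters): ", conditionMessage(e),
             call. = FALSE))
    for (i in seq_len(mcmc@samplingIterations))
      draws[i, ch, ] <- env$constrain(res$draws[i, ])
    stepsizes[ch] <- res$stepsize
    divergences[ch] <- res$divergences
  }
  new("PosteriorDraws", draws = draws, spec = spec,
      schoolLevels = design@schoolLevels,
      dataFingerprint = dataFingerprint(table),
      samplerInfo = list(seed = mcmc@seed, stepsizes = stepsizes,
                         divergences = divergences,
                         warmup = mcmc@warmupIterations))
}

#' @describeIn drawsMatrix Flatten posterior draws chain-major.
#' @export
setMethod("drawsMatrix", "PosteriorDraws", function(x) {
  dm <- dim(x@draws)
  out <- matrix(aperm(x@draws, c(1, 2, 3)), dm[1] * dm[2], dm[3])
  colnames(out) <- dimnames(x@draws)[[3]]
  out
})

#' @describeIn drawsArray The (iteration, chain, parameter) array.
#' @export
setMethod("drawsArray", "PosteriorDraws", function(x) x@draws)

#' @describeIn parameterNames Parameter names of the draws.
#' @export
setMethod("parameterNames", "PosteriorDraws",
          function(x) dimnames(x@draws)[[3]])

#' @describeIn fittedSpec Specification a posterior was fitted under.
#' @export
setMethod("fittedSpec", "PosteriorDraws", function(x) x@spec)

setMethod("show", "PosteriorDraws", function(object) {
  dm <- dim(object@draws)
  cat("PosteriorDraws:", object@spec@family, "family,", dm[3],
      "parameters\n")
  cat(" ", dm[1], "post-warmup iterations x", dm[2], "chains; seed",
      object@samplerInfo$seed, "\n")
  div <- sum(object@samplerInfo$divergences)
  if (div > 0) cat("  WARNING:", div, "divergent transitions\n")
})
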