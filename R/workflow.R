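# End-to-end orchestration: describe -> specify -> fit -> diagnose ->
# posterior predictive checks -> cross-family LOO comparison ->
# summaries and interpretation.

#' Run the full Bayesian injury-rate workflow from a config file
#'
#' Executes the standard analysis sequence on a surveillance table:
#' descriptive rate summaries; per requested family, model fit,
#' convergence gate (downstream stages for a non-converged model run
#' only with `allow_nonconverged: true`), posterior predictive checks
#' and figures; PSIS-LOO comparison across families; posterior summary,
#' rate-ratio table and (for the NB family) the frequentist comparator.
#' Every artifact is written under `outDir` and every stage is logged
#' with its seed.
#'
#' Config keys (YAML or an equivalent named list): either `data` (path
#' to a surveillance CSV) or `simulate` (`sport`, optional `family`,
#' `seed`, `schools_per_division`); `models` (families to fit); `mcmc`
#' (`chains`, `warmup`, `sampling`, `seed`); `ppc` (`replicates`);
#' `rate_scale`; `frequentist`; `allow_nonconverged`.
#'
#' @param config Path to a YAML config file, or a named list.
#' @param outDir Output directory (created if absent).
#' @return Invisibly, a list with the fitted objects, check results,
#'   comparison table and file manifest.
#' @export
runWorkflow <- function(config, outDir = "injurybayes_run") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outDir, "run.log")
  logline <- function(level, ...) {
    msg <- sprintf("[%s] %s %s", level,
                   format(Sys.time(), "%H:%M:%S"), paste0(...))
    cat(msg, "\n", file = logfile, append = TRUE)
    message(msg)
  }
  mcmc_cfg <- config$mcmc %||% list()
  mcmc <- mcmcConfig(chains = mcmc_cfg$chains %||% 4L,
                     warmupIterations = mcmc_cfg$warmup %||% 1000L,
                     samplingIterations = mcmc_cfg$sampling %||% 1000L,
                     seed = mcmc_cfg$seed %||% 1L)
  logline("INFO", "workflow start; mcmc seed ", mcmc@seed)

  # data: simulate with recorded truth, or load
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim_cfg <- config$simulate
    sport <- sim_cfg$sport %||% "womens_soccer"
    truth0 <- defaultTruth(sport, family = sim_cfg$family %||% "nb_school",
                           seed = sim_cfg$seed %||% mcmc@seed)
    structure <- defaultStructure(
      sport,
      schoolsPerDivision = unlist(sim_cfg$schools_per_division) %||%
        c(DI = 10L, DII = 10L, DIII = 10L))
    sim <- generateDataset(truth0, structure)
    table <- sim$table; truth <- sim$truth
    writeSurveillanceCSV(table, file.path(outDir, "surveillance.csv"))
    writeTruthManifest(truth, file.path(outDir, "truth_manifest.json"))
    logline("INFO", "simulated ", nStrata(table), " strata (seed ",
            truth@seed, ")")
  } else if (!is.null(config$data)) {
    table <- readSurveillanceCSV(config$data)
    logline("INFO", "loaded ", nStrata(table), " strata from ",
            config$data)
  } else stop("config must provide 'data' or 'simulate'", call. = FALSE)

  rate_scale <- config$rate_scale %||% 10000
  desc <- strataData(aggregateTable(table, c("sport", "event_type",
                                             "diagnosis")))
  desc$rate <- computeRawRate(desc$injuries, desc$athlete_exposures,
                              rate_scale)
  utils::write.csv(desc, file.path(outDir, "descriptive_rates.csv"),
                   row.names = FALSE)

  families <- unlist(config$models) %||% MODEL_FAMILIES
  ppc_reps <- (config$ppc %||% list())$replicates %||%
    min(500L, mcmc@chains * mcmc@samplingIterations)
  allow_fail <- isTRUE(config$allow_nonconverged)

  fits <- list(); loos <- list()
  ppc <- list(maxima = NULL, zeros = NULL, avp = NULL, pit = NULL)
  for (fam in families) {
    spec <- modelSpec(fam, levelSets = levelSets(table))
    logline("INFO", "fitting ", fam)
    fit <- fitModel(table, spec, mcmc)
    fits[[fam]] <- fit
    conv <- checkConvergence(fit)
    writeConvergenceReport(conv, file.path(outDir,
                                           paste0("convergence_", fam,
                                                  ".json")))
    if (!convergencePassed(conv)) {
      logline("WARN", fam, " failed the convergence gate (max rhat ",
              format(max(convergenceTable(conv)$rhat), digits = 4),
              ", min ess ",
              format(min(convergenceTable(conv)$ess), digits = 4), ")")
      if (!allow_fail) {
        logline("WARN", "skipping downstream stages for ", fam,
                " (set allow_nonconverged: true to override)")
        next
      }
    }
    reps <- generateReplicates(fit, table, nReplicates = ppc_reps,
                               seed = mcmc@seed)
    mx <- maximaCheck(table, reps); mx$model <- fam
    zz <- zeroProportionCheck(table, reps); zz$model <- fam
    av <- actualVsPredicted(table, reps, rateScale = rate_scale)
    avr <- av$rows; avr$model <- fam
    pt <- pitCheck(table, fit, seed = mcmc@seed)
    pte <- pt$ecdf; pte$model <- fam
    ppc$maxima <- rbind(ppc$maxima, mx)
    ppc$zeros <- rbind(ppc$zeros, zz)
    ppc$avp <- rbind(ppc$avp, avr)
    ppc$pit <- rbind(ppc$pit, pte)
    logline("INFO", fam, " PPC: avp slope ",
            format(av$regression[["slope"]], digits = 3), ", PIT KS ",
            format(pt$ks, digits = 3))
    ll <- pointwiseLogLik(table, draws = fit)
    loos[[fam]] <- psisLoo(ll, label = fam)
  }

  if (!is.null(ppc$maxima)) {
    utils::write.csv(ppc$maxima, file.path(outDir, "ppc_maxima.csv"),
                     row.names = FALSE)
    utils::write.csv(ppc$zeros, file.path(outDir, "ppc_zeros.csv"),
                     row.names = FALSE)
    grDevices::pdf(file.path(outDir, "ppc_figures.pdf"), width = 9,
                   height = 6)
    print(plotMaximaCheck(ppc$maxima))
    print(plotZeroCheck(ppc$zeros))
    print(plotActualVsPredicted(ppc$avp))
    print(plotPitCheck(ppc$pit))
    grDevices::dev.off()
  }

  comparison <- NULL
  if (length(loos)) {
    comparison <- compareModels(loos)
    utils::write.csv(comparison, file.path(outDir, "loo_comparison.csv"),
                     row.names = FALSE)
    logline("INFO", "LOO ranking: ",
            paste(comparison$model, collapse = " > "))
  }

  final_fam <- if ("nb_school" %in% names(fits)) "nb_school"
               else names(fits)[1]
  summary_tab <- NULL
  if (length(fits)) {
    summary_tab <- summarizePosterior(fits[[final_fam]],
                                      includeSchools = FALSE)
    utils::write.csv(summary_tab,
                     file.path(outDir, "posterior_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(rateRatioTable(summary_tab),
                     file.path(outDir, "rate_ratios.csv"),
                     row.names = FALSE)
  }
  freq <- NULL
  if (isTRUE(config$frequentist %||% TRUE) && "nb_school" %in% families) {
    freq <- fitFrequentistNB(table, modelSpec("nb_school",
                                              levelSets = levelSets(table)))
    utils::write.csv(freq$estimates,
                     file.path(outDir, "frequentist_nb.csv"),
                     row.names = FALSE)
    logline("INFO", "frequentist comparator converged: ", freq$converged)
  }
  logline("INFO", "workflow complete")
  invisible(list(table = table, truth = truth, fits = fits, ppc = ppc,
                 comparison = comparison, summary = summary_tab,
                 frequentist = freq, outDir = outDir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
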