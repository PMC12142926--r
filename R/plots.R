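# ggplot2 figure builders for the check suite; each takes the tidy
# output of the corresponding check (with a `model` column when faceted
# across model families) and returns a ggplot object.

#' @import ggplot2
NULL

#' Plot prior and posterior densities of the conjugate rate model
#'
#' Two panels: the Gamma prior densities, and the corresponding
#' Gamma-Poisson posterior densities after the shared conjugate update —
#' with dense data the posteriors overlap even when the priors differ
#' widely.
#'
#' @param priors Named list of [GammaPrior] objects.
#' @param injuries,exposures Observed data for the update.
#' @param scale Rate standardization for the x axis (default per 10,000
#'   AEs).
#' @return A ggplot object.
#' @export
plotPriorSensitivity <- function(priors, injuries, exposures,
                                 scale = 10000) {
  if (is.null(names(priors)))
    names(priors) <- paste("prior", seq_along(priors))
  posts <- lapply(priors, gammaPoissonPosterior, injuries = injuries,
                  exposures = exposures)
  hi <- max(vapply(posts, function(p)
    stats::qgamma(0.999, p@shape, rate = p@rate), numeric(1)))
  grid <- seq(0, hi * 1.5, length.out = 400)
  dens <- function(obj, panel, nm)
    data.frame(rate = grid * scale,
               density = stats::dgamma(grid, obj@shape, rate = obj@rate),
               panel = panel, prior = nm)
  df <- rbind(
    do.call(rbind, Map(dens, priors, "prior", names(priors))),
    do.call(rbind, Map(dens, posts, "posterior", names(priors))))
  df$panel <- factor(df$panel, levels = c("prior", "posterior"))
  ggplot(df, aes(x = .data$rate, y = .data$density,
                 colour = .data$prior)) +
    geom_line() +
    facet_wrap(~panel, ncol = 1, scales = "free_y") +
    labs(x = sprintf("injury rate per %s AEs",
                     format(scale, big.mark = ",")),
         y = "density") +
    theme_minimal()
}

#' Plot the maxima-exceedance check across models
#' @param df Row-bound [maximaCheck()] outputs with a `model` column.
#' @return A ggplot object.
#' @export
plotMaximaCheck <- function(df) {
  ggplot(df, aes(x = .data$group, y = .data$exceedance_pct)) +
    geom_point() +
    facet_wrap(~model) +
    labs(x = NULL, y = "% of replicates exceeding observed maximum") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Plot the zero-proportion check across models
#' @param df Row-bound [zeroProportionCheck()] outputs with a `model`
#'   column.
#' @return A ggplot object.
#' @export
plotZeroCheck <- function(df) {
  ggplot(df, aes(x = .data$group)) +
    geom_linerange(aes(ymin = .data$lower, ymax = .data$upper),
                   colour = "grey60", linewidth = 1.2) +
    geom_point(aes(y = .data$observed_zero_pct)) +
    facet_wrap(~model) +
    labs(x = NULL, y = "% zero-injury strata (dot observed, bar 95% CrI)") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Plot actual versus posterior-predicted rates across models
#' @param df Row-bound `rows` from [actualVsPredicted()] with a `model`
#'   column.
#' @return A ggplot object.
#' @export
plotActualVsPredicted <- function(df) {
  ggplot(df, aes(x = .data$actual_rate, y = .data$predicted_median)) +
    geom_errorbar(aes(ymin = .data$predicted_lower,
                      ymax = .data$predicted_upper),
                  colour = "grey70", width = 0) +
    geom_errorbarh(aes(xmin = .data$actual_lower,
                       xmax = .data$actual_upper),
                   colour = "grey70", height = 0) +
    geom_point(size = 0.8) +
    geom_abline(linetype = "dashed") +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                linewidth = 0.5, colour = "black") +
    facet_wrap(~model) +
    labs(x = "actual injury rate", y = "posterior predictive rate") +
    theme_minimal()
}

#' Plot the PIT eCDF calibration check across models
#' @param df Row-bound `ecdf` data from [pitCheck()] with a `model`
#'   column.
#' @return A ggplot object.
#' @export
plotPitCheck <- function(df) {
  ggplot(df, aes(x = .data$u)) +
    geom_ribbon(aes(ymin = .data$lower, ymax = .data$upper),
                fill = "grey80") +
    geom_line(aes(y = .data$ecdf)) +
    geom_abline(linetype = "dashed") +
    facet_wrap(~model) +
    labs(x = "uniform eCDF", y = "PIT eCDF") +
    theme_minimal()
}
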