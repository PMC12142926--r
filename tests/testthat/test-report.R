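test_that("posterior summaries report means and equal-tailed quantiles", {
  # constant draws collapse to a point
  pd <- fakeDraws(matrix(2.5, 400, 1, dimnames = list(NULL, "gamma")))
  s <- summarizePosterior(pd)
  expect_equal(s$mean, 2.5)
  expect_equal(s$lower, 2.5)
  expect_equal(s$upper, 2.5)

  # large standard-normal sample: 95% bounds near +-1.96
  set.seed(2)
  pd2 <- fakeDraws(matrix(rnorm(100000), ncol = 1,
                          dimnames = list(NULL, "gamma")), chains = 4L)
  s2 <- summarizePosterior(pd2)
  expect_lt(abs(s2$lower + 1.96), 0.02)
  expect_lt(abs(s2$upper - 1.96), 0.02)
})

test_that("summary rows follow the conventional contrast order and labels", {
  params <- c("gamma", "zeta[school_001]", "kappa_nb", "sigma_zeta",
              "epsilon[concussion]", "beta[DII]", "alpha[competition]")
  m <- matrix(rnorm(400 * 7), 400, dimnames = list(NULL, params))
  pd <- fakeDraws(m, spec = modelSpec("nb_school"))
  s <- summarizePosterior(pd)
  expect_equal(s$parameter[1:3],
               c("alpha[competition]", "beta[DII]",
                 "epsilon[concussion]"))
  expect_equal(s$label[1], "Competition (vs. Practice)")
  expect_equal(s$label[2], "DII (vs. DI)")
  expect_equal(s$label[3], "Concussion (vs. Sprain)")
  expect_true(which(s$parameter == "zeta[school_001]") > 5)
  s_noschool <- summarizePosterior(pd, includeSchools = FALSE)
  expect_false(any(grepl("^zeta", s_noschool$parameter)))
})

test_that("rate ratios reproduce the printed headline values", {
  rr <- rateRatioTransform(c(mean = 1.33, lower = 1.23, upper = 1.44))
  expect_equal(unname(rr), c(3.8, 3.4, 4.2))
  expect_equal(unname(rateRatioTransform(0)), 1.0)
  # exponentiated bounds are exp of the log bounds, no re-estimation
  rr_raw <- rateRatioTransform(c(mean = 1.33, lower = 1.23,
                                 upper = 1.44), digits = NA)
  expect_equal(unname(rr_raw), exp(c(1.33, 1.23, 1.44)))
  # half-up rounding at the boundary
  expect_equal(unname(rateRatioTransform(log(1.25))), 1.3)
})

test_that("frequentist comparator recovers the truth on dense synthetic data", {
  truth <- defaultTruth("womens_soccer", sigmaSchool = 0.2)
  sim <- generateDataset(truth, defaultStructure("womens_soccer"),
                         seed = 60L)
  fit <- fitFrequentistNB(sim$table, modelSpec("nb_school"))
  expect_true(fit$converged)
  tv <- truthParameters(sim$truth)
  est <- fit$estimates
  fx <- est[grepl("^(alpha|beta|epsilon|kappa_year)\\[",
                  est$parameter), ]
  se <- (fx$upper - fx$lower) / (2 * qnorm(0.975))
  expect_true(all(abs(fx$estimate - tv[fx$parameter]) < 2.5 * se))
  expect_gt(fit$overdispersion, 0)
  expect_error(fitFrequentistNB(sim$table, modelSpec("poisson")),
               "nb_school")
})

test_that("intercept-only ML rate equals the raw pooled rate on Poisson-like data", {
  truth <- makeTruth(family = "poisson_school", gamma = log(0.004),
                     sigmaSchool = 0.01)
  st <- makeStructure(c(DI = 10L), years = sprintf("y%d", 1:5),
                      ae = 5000)
  sim <- generateDataset(truth, st, seed = 61L)
  spec <- modelSpec("nb_school", covariates = character(0),
                    referenceLevels = character(0))
  fit <- fitFrequentistNB(sim$table, spec)
  pooled <- totalInjuries(sim$table) / totalExposures(sim$table)
  est <- exp(fit$estimates$estimate[fit$estimates$parameter == "gamma"])
  expect_lt(abs(est / pooled - 1), 0.02)
})
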