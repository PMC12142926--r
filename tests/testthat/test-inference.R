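test_that("repeated fits with the same configuration are identical", {
  tab <- oneRowTable(12L, 2000L)
  mc <- quickMcmc(seed = 33L, iters = 60L)
  f1 <- fitModel(tab, interceptSpec(), mc)
  f2 <- fitModel(tab, interceptSpec(), mc)
  expect_identical(drawsArray(f1), drawsArray(f2))
  f3 <- fitModel(tab, interceptSpec(), quickMcmc(seed = 34L, iters = 60L))
  expect_false(identical(drawsArray(f1), drawsArray(f3)))
})

test_that("the MCMC posterior reproduces the conjugate closed form", {
  # Gamma(1,1) prior on exp(gamma) with a Poisson likelihood on
  # (84 injuries, 10,000 AEs) has the exact posterior Gamma(85, 10001)
  tab <- oneRowTable(84L, 10000L)
  spec <- interceptSpec(list(type = "gamma", shape = 1, rate = 1))
  means <- sapply(1:3, function(s) {
    fit <- fitModel(tab, spec, mcmcConfig(chains = 2,
                                          warmupIterations = 300,
                                          samplingIterations = 300,
                                          seed = 100L + s))
    rate <- exp(drawsMatrix(fit)[, "gamma"])
    ess <- computeESS(matrix(rate, ncol = 2))
    c(mean(rate), sd(rate) / sqrt(max(ess, 10)))
  })
  exact <- 85 / 10001
  expect_true(all(abs(means[1, ] - exact) < 3 * means[2, ]))
  # posterior SD also matches the Gamma closed form loosely
  expect_lt(abs(mean(means[1, ]) / exact - 1), 0.02)
})

test_that("constrained parameters respect their supports in every draw", {
  sim <- generateDataset(defaultTruth("womens_soccer",
                                      family = "zinb_school"),
                         makeStructure(c(DI = 3L), years = c("y1", "y2"),
                                       ae = 3000),
                         seed = 14L)
  spec <- modelSpec("zinb_school",
                    levelSets = defaultLevelSets(years = c("y1", "y2")))
  fit <- fitModel(sim$table, spec, quickMcmc(seed = 3L, iters = 80L))
  dm <- drawsMatrix(fit)
  expect_true(all(dm[, "sigma_zeta"] > 0))
  expect_true(all(dm[, "kappa_nb"] > 0))
  expect_true(all(dm[, "theta[practice]"] >= 0 &
                    dm[, "theta[practice]"] <= 1))
  expect_setequal(
    grep("^zeta\\[", colnames(dm), value = TRUE),
    sprintf("zeta[school_%03d]", 1:3))
  # warmup is excluded from the returned draws
  expect_equal(dim(drawsArray(fit))[1], 80L)
})

test_that("fitting rejects invalid input instead of sampling it", {
  d <- rbind(makeRows(1), makeRows(1))
  d$sport <- c("mens_soccer", "womens_soccer")
  d$school_id <- c("a", "b")
  expect_error(fitModel(surveillanceTable(d), modelSpec("poisson"),
                        quickMcmc()), "separately")
  bad <- makeRows(2); bad$injuries[1] <- -4L
  expect_error(fitModel(surveillanceTable(bad, validate = FALSE),
                        modelSpec("poisson"), quickMcmc()),
               "validation")
  expect_error(mcmcConfig(chains = 1), "chains")
})
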