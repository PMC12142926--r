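test_that("generation is deterministic in the seed", {
  truth <- defaultTruth("womens_soccer")
  st <- defaultStructure("womens_soccer",
                         schoolsPerDivision = c(DI = 2L, DII = 2L))
  a <- generateDataset(truth, st, seed = 5L)
  b <- generateDataset(truth, st, seed = 5L)
  expect_identical(strataData(a$table), strataData(b$table))
  expect_identical(a$truth@schoolEffects, b$truth@schoolEffects)
  c <- generateDataset(truth, st, seed = 6L)
  expect_false(identical(strataData(a$table), strataData(c$table)))
})

test_that("a null Poisson truth reproduces its analytic mean count", {
  # all effects zero, gamma = log(0.001), AE = 10,000 per row:
  # mean count is 10 per row
  truth <- makeTruth(family = "poisson", gamma = log(0.001))
  st <- makeStructure(schoolsPerDivision = c(DI = 100L),
                      years = sprintf("y%02d", 1:8), ae = 10000)
  sim <- generateDataset(truth, st, seed = 31L)
  x <- strataData(sim$table)$injuries
  se <- sd(x) / sqrt(length(x))
  expect_gt(length(x), 6000)
  expect_lt(abs(mean(x) - 10), 3 * se)
})

test_that("degenerate zero inflation produces an all-zero table", {
  truth <- makeTruth(family = "zinb_school", gamma = log(0.001),
                     sigmaSchool = 0.2, overdispersion = 1,
                     zeroInflation = c(practice = 1, competition = 1))
  sim <- generateDataset(truth, makeStructure(c(DI = 3L)), seed = 2L)
  expect_true(all(strataData(sim$table)$injuries == 0L))
})

test_that("NB counts are overdispersed with variance near mu + mu^2/kappa", {
  # one school, sigma 0, constant AEs: every row shares one NB law, and
  # 50 'years' x 8 cells give 400 iid draws per run
  kappa <- 2
  truth <- makeTruth(family = "nb_school", gamma = log(0.001),
                     sigmaSchool = 0, overdispersion = kappa)
  st <- makeStructure(c(DI = 1L), years = sprintf("y%02d", 1:50),
                      ae = 5000)
  x <- unlist(lapply(1:8, function(s)
    strataData(generateDataset(truth, st, seed = s)$table)$injuries))
  mu <- 5000 * 0.001
  expected_var <- mu + mu^2 / kappa
  expect_gt(var(x), mu * 1.5)            # clearly above Poisson
  expect_lt(abs(var(x) / expected_var - 1), 0.15)
  expect_lt(abs(mean(x) / mu - 1), 0.05)
})

test_that("zero inflation only adds zeros relative to the NB family", {
  base <- makeTruth(family = "nb_school", gamma = log(0.0008),
                    sigmaSchool = 0.3, overdispersion = 1)
  zi <- makeTruth(family = "zinb_school", gamma = log(0.0008),
                  sigmaSchool = 0.3, overdispersion = 1,
                  zeroInflation = c(practice = 0.3, competition = 0.3))
  st <- makeStructure(c(DI = 10L), years = sprintf("y%02d", 1:10),
                      ae = 2000)
  z_nb <- mean(strataData(generateDataset(base, st, 3L)$table)$injuries == 0)
  z_zi <- mean(strataData(generateDataset(zi, st, 3L)$table)$injuries == 0)
  expect_gt(z_zi, z_nb)
})

test_that("school multipliers obey the log-normal mean identity", {
  sigma <- 0.4
  truth <- makeTruth(family = "nb_school", gamma = log(0.001),
                     sigmaSchool = sigma, overdispersion = 2)
  st <- makeStructure(c(DI = 3000L))
  sim <- generateDataset(truth, st, seed = 9L)
  z <- sim$truth@schoolEffects
  expect_length(z, 3000L)
  expect_lt(abs(mean(exp(z)) / exp(sigma^2 / 2) - 1), 0.03)
})

test_that("default truths carry the reported posterior-mean effects", {
  w <- defaultTruth("womens_soccer")
  expect_equal(unname(w@alphaEvent["competition"]), 1.33)
  expect_equal(unname(w@epsilonDiagnosis["concussion"]), -0.99)
  m <- defaultTruth("mens_soccer")
  expect_equal(unname(m@alphaEvent["competition"]), 1.28)
  expect_equal(unname(m@epsilonDiagnosis["contusion"]), -0.23)
  # reference levels carry no named effect: implicit zero in the
  # parameter vector
  tv <- truthParameters(w)
  expect_false(any(grepl("practice|\\[DI\\]|sprain|2014/15", names(tv))))
  expect_error(defaultTruth("badminton"), "unknown sport")
})

test_that("recovery reports score bias, z and interval coverage", {
  truth <- defaultTruth("womens_soccer")
  tv <- truthParameters(truth)
  summaries <- data.frame(parameter = names(tv), mean = unname(tv),
                          sd = rep(0.1, length(tv)),
                          lower = unname(tv) - 0.2,
                          upper = unname(tv) + 0.2,
                          stringsAsFactors = FALSE)
  rec <- recoveryReport(truth, summaries)
  expect_equal(rec$bias, rep(0, nrow(rec)))
  expect_equal(rec$z, rep(0, nrow(rec)))
  expect_true(all(rec$covered_by_95))

  summaries$lower[1] <- tv[1] + 0.01   # truth now outside
  rec2 <- recoveryReport(truth, summaries)
  expect_false(rec2$covered_by_95[1])

  expect_error(recoveryReport(truth, summaries[-2, ]),
               "absent from summaries")
})
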