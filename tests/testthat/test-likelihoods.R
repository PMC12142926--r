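test_that("reference coding produces one indicator per non-reference level", {
  d <- makeRows(2)
  d$event_type <- c("practice", "competition")
  d$division <- c("DI", "DII")
  tab <- surveillanceTable(d)
  spec <- modelSpec("poisson")
  des <- buildDesign(tab, spec)
  expect_equal(colnames(des@X),
               c("alpha[competition]", "beta[DII]", "beta[DIII]",
                 "epsilon[strain]", "epsilon[contusion]",
                 "epsilon[concussion]", "kappa_year[2015/16]",
                 "kappa_year[2016/17]", "kappa_year[2017/18]",
                 "kappa_year[2018/19]"))
  expect_equal(des@X[, "alpha[competition]"], c(0, 1))
  expect_equal(des@X[, "beta[DII]"], c(0, 1))

  # offset is log AEs; AE = 1 gives offset 0
  d$athlete_exposures <- c(1L, 100L)
  des2 <- buildDesign(surveillanceTable(d), spec)
  expect_equal(des2@offset, c(0, log(100)))

  # undeclared level is rejected with the offending row
  ls <- defaultLevelSets()
  ls$division <- c("DI", "DII")
  d2 <- makeRows(1); d2$division <- "DIII"
  expect_error(buildDesign(surveillanceTable(d2, levelSets = ls,
                                             validate = FALSE), spec),
               "row 1")
})

test_that("the linear predictor is additive with an exposure offset", {
  d <- makeRows(2, injuries = c(1L, 1L), aes = c(400L, 400L))
  d$event_type <- c("practice", "competition")
  tab <- surveillanceTable(d)
  des <- buildDesign(tab, modelSpec("poisson"))
  par <- c(gamma = -5, setNames(rep(0, ncol(des@X)), colnames(des@X)))

  # all effects zero: mean count AE * exp(gamma)
  expect_equal(exp(linearPredictor(des, par)),
               rep(400 * exp(-5), 2))

  # a competition effect of 1.33 multiplies the rate by exp(1.33) ~ 3.8
  par["alpha[competition]"] <- 1.33
  eta <- linearPredictor(des, par)
  expect_equal(exp(eta[2] - eta[1]), exp(1.33))
  expect_equal(round(exp(1.33), 1), 3.8)

  # doubling AEs doubles the mean count
  d2 <- d; d2$athlete_exposures <- d2$athlete_exposures * 2L
  des2 <- buildDesign(surveillanceTable(d2), modelSpec("poisson"))
  expect_equal(exp(linearPredictor(des2, par)),
               2 * exp(linearPredictor(des, par)))

  expect_error(linearPredictor(des, c(gamma = -5)), "missing")
})

test_that("count log pmfs match their closed forms and normalize", {
  expect_equal(poissonLogLik(0, 2), -2)
  expect_equal(poissonLogLik(3, 3), log(27 * exp(-3) / 6))
  expect_error(poissonLogLik(-1, 2), ">= 0")

  # NB at zero: kappa * (log kappa - log(kappa + mu))
  expect_equal(nbLogLik(0, 3, 1.7), 1.7 * (log(1.7) - log(1.7 + 3)))
  expect_error(nbLogLik(1, 3, 0), "> 0")

  # Poisson limit of the NB
  x <- 0:15
  expect_lt(max(abs(nbLogLik(x, 4.2, 1e6) - poissonLogLik(x, 4.2))),
            1e-3)

  # ZINB zero mass: theta + (1 - theta) * (kappa/(kappa+mu))^kappa
  expect_equal(exp(zinbLogLik(0, 5, 2, 0.3)), 0.3 + 0.7 * (2 / 7)^2)
  # theta = 0 reduces to the NB; theta = 1 is the point mass at zero
  expect_equal(zinbLogLik(0:9, 5, 2, 0), nbLogLik(0:9, 5, 2))
  expect_equal(zinbLogLik(0, 5, 2, 1), 0)
  expect_equal(zinbLogLik(3, 5, 2, 1), -Inf)
  expect_error(zinbLogLik(0, 5, 2, 1.2), "\\[0, 1\\]")

  # normalization across families at randomly drawn valid parameters
  set.seed(42)
  for (i in 1:5) {
    mu <- runif(1, 0.2, 8); kap <- runif(1, 0.3, 5)
    th <- runif(1)
    xs <- 0:400
    expect_equal(sum(exp(poissonLogLik(xs, mu))), 1, tolerance = 1e-8)
    expect_equal(sum(exp(nbLogLik(xs, mu, kap))), 1, tolerance = 1e-8)
    expect_equal(sum(exp(zinbLogLik(xs, mu, kap, th))), 1,
                 tolerance = 1e-8)
  }
})

test_that("zero probabilities are stochastically ordered across families", {
  set.seed(7)
  for (i in 1:10) {
    mu <- runif(1, 0.5, 6); kap <- runif(1, 0.2, 4)
    th <- runif(1, 0.05, 0.95)
    p_pois <- exp(poissonLogLik(0, mu))
    p_nb <- exp(nbLogLik(0, mu, kap))
    p_zinb <- exp(zinbLogLik(0, mu, kap, th))
    expect_gt(p_zinb, p_nb)
    expect_gt(p_nb, p_pois)
  }
})

test_that("the log prior matches the declared densities", {
  spec <- modelSpec("nb_school")
  # every fixed effect at its mode contributes log(1/(10 pi))
  p0 <- c(gamma = 0, "alpha[competition]" = 0, sigma_zeta = 1,
          kappa_nb = 1)
  p1 <- p0; p1["alpha[competition]"] <- 10
  # moving an effect one Cauchy scale unit halves its density
  expect_equal(logPrior(p1, spec) - logPrior(p0, spec), log(1 / 2))

  base <- logPrior(c(gamma = 0, sigma_zeta = 1, kappa_nb = 1), spec)
  expect_equal(logPrior(p0, spec) - base, log(1 / (10 * pi)))

  # support constraints
  expect_equal(logPrior(c(gamma = 0, sigma_zeta = -0.1, kappa_nb = 1),
                        spec), -Inf)
  expect_equal(logPrior(c(gamma = 0, sigma_zeta = 1, kappa_nb = -2),
                        spec), -Inf)
  expect_equal(logPrior(c(gamma = 0, sigma_zeta = 1, kappa_nb = 1,
                          "theta[practice]" = 1.4),
                        modelSpec("zinb_school")), -Inf)

  # gamma intercept prior integrates the conjugate-matched density
  gspec <- interceptSpec(list(type = "gamma", shape = 2, rate = 100))
  g <- -3
  expect_equal(logPrior(c(gamma = g), gspec),
               dgamma(exp(g), 2, rate = 100, log = TRUE) + g)
})

test_that("pointwise log likelihood agrees with direct evaluation", {
  sim <- generateDataset(defaultTruth("womens_soccer",
                                      family = "zinb_school"),
                         makeStructure(c(DI = 2L, DII = 2L),
                                       years = c("y01", "y02"),
                                       ae = 2000),
                         seed = 4L)
  # a single hand-built draw: pointwise rows equal direct loglik calls
  spec <- modelSpec("zinb_school",
                    levelSets = defaultLevelSets(years = c("y01", "y02")))
  des <- buildDesign(sim$table, spec)
  params <- c(gamma = -6.5, setNames(rep(0.1, ncol(des@X)),
                                     colnames(des@X)),
              setNames(rep(0.05, length(des@schoolLevels)),
                       sprintf("zeta[%s]", des@schoolLevels)),
              sigma_zeta = 0.3, kappa_nb = 1.5,
              "theta[practice]" = 0.2, "theta[competition]" = 0.1)
  pd <- fakeDraws(matrix(rep(params, each = 4), 4,
                         dimnames = list(NULL, names(params))),
                  chains = 2L, spec = spec)
  ll <- pointwiseLogLik(sim$table, des, pd, spec)
  mu <- exp(linearPredictor(des, params))
  direct <- zinbLogLik(des@counts, mu, 1.5,
                       c(0.2, 0.1)[des@eventIndex])
  expect_equal(unname(ll[1, ]), direct)
  expect_equal(unname(ll[4, ]), direct)
  # additivity: row sum is the joint conditional log likelihood
  expect_equal(sum(ll[1, ]), sum(direct))
  expect_true(all(is.finite(ll)))
  expect_error(pointwiseLogLik(sim$table, des, pd,
                               modelSpec("nb_school")),
               "family mismatch")
})
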