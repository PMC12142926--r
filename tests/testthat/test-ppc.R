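makeReps <- function(counts, seed = 1L) {
  new("PpcReplicates", counts = counts,
      drawIndices = seq_len(nrow(counts)), seed = as.integer(seed))
}

test_that("replicate generation is deterministic and draw-aligned", {
  sim <- generateDataset(defaultTruth("womens_soccer"),
                         makeStructure(c(DI = 2L), years = c("y1", "y2"),
                                       ae = 3000),
                         seed = 6L)
  spec <- modelSpec("nb_school",
                    levelSets = defaultLevelSets(years = c("y1", "y2")))
  fit <- fitModel(sim$table, spec, quickMcmc(seed = 8L, iters = 100L))
  r1 <- generateReplicates(fit, sim$table, nReplicates = 50, seed = 9L)
  r2 <- generateReplicates(fit, sim$table, nReplicates = 50, seed = 9L)
  expect_identical(r1@counts, r2@counts)
  expect_equal(ncol(r1@counts), nStrata(sim$table))
  expect_error(generateReplicates(fit, sim$table, nReplicates = 10000),
               "exceeds")
})

test_that("Poisson replicate means track the generating draw means", {
  tab <- makeTable(n = 4, injuries = c(2L, 5L, 1L, 7L),
                   aes = rep(1000L, 4))
  spec <- interceptSpec()
  mu <- 1000 * exp(-5.2)
  pd <- fakeDraws(matrix(-5.2, 400, 1,
                         dimnames = list(NULL, "gamma")),
                  chains = 2L, spec = spec)
  reps <- generateReplicates(pd, tab, nReplicates = 400, seed = 2L)
  means <- colMeans(reps@counts)
  se <- sqrt(mu / 400)
  expect_true(all(abs(means - mu) < 4 * se))
})

test_that("degenerate ZINB draws yield all-zero replicates", {
  sim <- generateDataset(defaultTruth("womens_soccer",
                                      family = "zinb_school"),
                         makeStructure(c(DI = 2L), ae = 2000), seed = 3L)
  spec <- modelSpec("zinb_school",
                    levelSets = defaultLevelSets(years = "y01"))
  des <- buildDesign(sim$table, spec)
  params <- c(gamma = -6, setNames(rep(0, ncol(des@X)),
                                   colnames(des@X)),
              setNames(rep(0, 2), sprintf("zeta[%s]",
                                          des@schoolLevels)),
              sigma_zeta = 0.3, kappa_nb = 1,
              "theta[practice]" = 1, "theta[competition]" = 1)
  pd <- fakeDraws(matrix(rep(params, each = 8), 8,
                         dimnames = list(NULL, names(params))),
                  chains = 2L, spec = spec)
  reps <- generateReplicates(pd, sim$table, nReplicates = 8, seed = 1L)
  expect_true(all(reps@counts == 0L))
})

test_that("maxima exceedance uses a strict inequality", {
  tab <- makeTable(n = 2, injuries = c(5L, 3L))
  # observed group max 5; replicate maxima 3, 6, 7, 5 -> 50%
  reps <- makeReps(rbind(c(3L, 1L), c(6L, 0L), c(7L, 2L), c(5L, 5L)))
  out <- maximaCheck(tab, reps, grouping = "division")
  expect_equal(out$observed_max, 5)
  expect_equal(out$exceedance_pct, 50)
  # replicates identical to the observed data: 0% everywhere
  obs <- matrix(rep(c(5L, 3L), each = 4), 4)
  expect_equal(maximaCheck(tab, makeReps(obs),
                           grouping = "division")$exceedance_pct, 0)
  # row order within groups does not matter
  perm <- makeReps(rbind(c(1L, 3L), c(0L, 6L), c(2L, 7L), c(5L, 5L)))
  swapped <- maximaCheck(tab, perm, grouping = "division")
  expect_equal(swapped$exceedance_pct, 50)
})

test_that("zero-proportion check flags observed values outside the interval", {
  tab <- makeTable(n = 10, injuries = c(rep(0L, 3), rep(2L, 7)))
  # every replicate has no zeros: the 30% observed is outside
  reps <- makeReps(matrix(1L, 20, 10))
  out <- zeroProportionCheck(tab, reps, grouping = "division")
  expect_equal(out$observed_zero_pct, 30)
  expect_false(out$inside)
  # replicates identical to observed: degenerate interval, inside
  obs <- matrix(rep(strataData(tab)$injuries, each = 20), 20)
  out2 <- zeroProportionCheck(tab, makeReps(obs), grouping = "division")
  expect_equal(out2$lower, 30)
  expect_equal(out2$upper, 30)
  expect_true(out2$inside)
})

test_that("actual-vs-predicted regression recovers forced slopes", {
  tab <- makeTable(n = 3, injuries = c(2L, 4L, 8L),
                   aes = rep(1000L, 3))
  # replicates identical to observed: slope 1, intercept 0
  obs <- matrix(rep(strataData(tab)$injuries, each = 9), 9)
  out <- actualVsPredicted(tab, makeReps(obs))
  expect_equal(unname(out$regression["slope"]), 1, tolerance = 1e-10)
  expect_equal(unname(out$regression["intercept"]), 0,
               tolerance = 1e-10)
  # medians at exactly twice the actual counts: slope 2
  out2 <- actualVsPredicted(tab, makeReps(2L * obs))
  expect_equal(unname(out2$regression["slope"]), 2, tolerance = 1e-10)
  expect_equal(unname(out2$regression["intercept"]), 0,
               tolerance = 1e-8)
})

test_that("PIT values are near-uniform under a correctly specified model", {
  # a correctly specified Poisson fit: KS distance below the 5% critical
  # value in most seeds
  truth <- makeTruth(family = "poisson", gamma = log(0.002))
  st <- makeStructure(c(DI = 4L), years = sprintf("y%d", 1:5), ae = 2000)
  hits <- 0L
  for (s in 1:3) {
    sim <- generateDataset(truth, st, seed = 50L + s)
    spec <- modelSpec("poisson",
                      levelSets = defaultLevelSets(
                        years = sprintf("y%d", 1:5)))
    fit <- fitModel(sim$table, spec, quickMcmc(seed = s, iters = 150L))
    pt <- pitCheck(sim$table, fit, seed = s)
    crit <- 1.358 / sqrt(nStrata(sim$table))
    if (pt$ks < crit) hits <- hits + 1L
    expect_true(all(pt$pit >= 0 & pt$pit <= 1))
  }
  expect_gte(hits, 2L)
})
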