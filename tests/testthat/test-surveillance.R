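test_that("CSV round trip preserves a valid table exactly", {
  tab <- makeTable(n = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  writeSurveillanceCSV(tab, path)
  back <- readSurveillanceCSV(path)
  expect_identical(strataData(back), strataData(tab))
  # second round trip is also exact
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeSurveillanceCSV(back, path2)
  expect_identical(strataData(readSurveillanceCSV(path2)),
                   strataData(tab))
})

test_that("CSV reader tolerates thousands separators and flags bad rows", {
  d <- makeRows(2)
  path <- withr::local_tempfile(fileext = ".csv")
  d$injuries <- c("1,358", "2")
  d$athlete_exposures <- c("80,453", "1000")
  write.csv(d, path, row.names = FALSE)
  tab <- readSurveillanceCSV(path)
  expect_equal(strataData(tab)$injuries, c(1358L, 2L))
  expect_equal(strataData(tab)$athlete_exposures[1], 80453L)

  d$injuries <- c("3", "-1")
  write.csv(d, path, row.names = FALSE)
  expect_error(readSurveillanceCSV(path), "row 2")

  d$injuries <- c("3", "abc")
  write.csv(d, path, row.names = FALSE)
  expect_error(readSurveillanceCSV(path), "row\\(s\\) 2")

  write.csv(d[, -1], path, row.names = FALSE)
  expect_error(readSurveillanceCSV(path), "missing column")
})

test_that("validateTable reports each invariant violation with its row", {
  expect_equal(nrow(validateTable(makeTable(3))), 0L)

  d <- makeRows(3)
  d$injuries[2] <- -1L
  bad <- surveillanceTable(d, validate = FALSE)
  rep <- validateTable(bad)
  expect_equal(rep$row, 2L)
  expect_equal(rep$rule, "injuries_nonnegative")

  d <- makeRows(3)
  d$athlete_exposures[3] <- 0L
  rep <- validateTable(surveillanceTable(d, validate = FALSE))
  expect_true(any(rep$rule == "exposures_positive" & rep$row == 3L))

  d <- makeRows(3)
  d$division[1] <- "DIV"
  rep <- validateTable(surveillanceTable(d, validate = FALSE))
  expect_true(any(rep$rule == "level_declared:division" & rep$row == 1L))

  d <- makeRows(3)
  d$school_id[2] <- d$school_id[1]
  rep <- validateTable(surveillanceTable(d, validate = FALSE))
  expect_setequal(rep$row[rep$rule == "stratum_unique"], c(1L, 2L))
})

test_that("aggregation sums counts, is associative and identity-stable", {
  d <- rbind(makeRows(1, injuries = 3L, aes = 100L),
             makeRows(1, injuries = 4L, aes = 200L))
  d$diagnosis <- c("sprain", "strain")
  tab <- surveillanceTable(d)
  agg <- aggregateTable(tab, c("school_id", "division", "academic_year",
                               "sport", "event_type"))
  expect_equal(nrow(strataData(agg)), 1L)
  expect_equal(strataData(agg)$injuries, 7L)
  expect_equal(strataData(agg)$athlete_exposures, 300L)

  # full covariate set returns the rows unchanged
  full <- aggregateTable(tab, c("school_id", "division", "academic_year",
                                "sport", "event_type", "diagnosis"))
  expect_equal(strataData(full), strataData(tab))

  # associativity: by A then B subset of A == by B directly
  sim <- generateDataset(defaultTruth("mens_soccer"),
                         defaultStructure("mens_soccer",
                           schoolsPerDivision = c(DI = 2L, DII = 2L)),
                         seed = 8L)
  a_then_b <- aggregateTable(
    aggregateTable(sim$table, c("sport", "event_type", "diagnosis")),
    c("sport", "event_type"))
  b_direct <- aggregateTable(sim$table, c("sport", "event_type"))
  expect_equal(strataData(a_then_b), strataData(b_direct))

  expect_error(aggregateTable(tab, character()), "at least one")
})

test_that("men's-soccer-scale synthetic totals sit on the published magnitudes", {
  sim <- generateDataset(defaultTruth("mens_soccer"),
                         defaultStructure("mens_soccer"), seed = 12L)
  tot <- strataData(aggregateTable(sim$table, c("sport", "event_type")))
  comp <- tot[tot$event_type == "competition", ]
  # AE totals are matched in expectation; injuries to the same order
  expect_lt(abs(comp$athlete_exposures / 80453 - 1), 0.10)
  expect_lt(abs(comp$injuries / 1358 - 1), 0.35)
  prac <- tot[tot$event_type == "practice", ]
  expect_lt(abs(prac$athlete_exposures / 251225 - 1), 0.10)
  expect_lt(abs(prac$injuries / 1463 - 1), 0.35)
})

test_that("raw rates follow the ratio definition at any scale", {
  expect_equal(computeRawRate(84, 10000, 10000), 84)
  expect_equal(round(computeRawRate(1358, 80453, 10000), 1), 168.8)
  expect_equal(computeRawRate(0, 5000, 1000), 0)
  # inverse identity within float tolerance
  r <- computeRawRate(17, 4321, 1000)
  expect_equal(r * (4321 / 1000), 17, tolerance = 1e-12)
  expect_error(computeRawRate(5, 0), "exposures")
  expect_error(computeRawRate(5, 100, -1), "scale")
})
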