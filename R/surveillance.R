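#' Default category level sets for collegiate surveillance tables
#'
#' Reference levels come first: Division I, the earliest season, practice
#' events and sprain diagnoses, matching the contrasts conventionally
#' reported for collegiate injury-rate models ("Competition (vs.
#' Practice)", "Division II (vs. Division I)", ...).
#'
#' @param years Academic-year labels (default the 2014/15-2018/19 seasons).
#' @param sports Sport labels.
#' @return Named list of character level sets.
#' @export
defaultLevelSets <- function(years = c("2014/15", "2015/16", "2016/17",
                                       "2017/18", "2018/19"),
                             sports = c("mens_soccer", "womens_soccer")) {
  list(division = c("DI", "DII", "DIII"),
       academic_year = years,
       sport = sports,
       event_type = c("practice", "competition"),
       diagnosis = c("sprain", "strain", "contusion", "concussion"))
}

#' Construct a surveillance table
#'
#' @param data `data.frame` with the canonical eight columns (`school_id`,
#'   `division`, `academic_year`, `sport`, `event_type`, `diagnosis`,
#'   `injuries`, `athlete_exposures`).
#' @param levelSets Declared category levels, as from [defaultLevelSets()].
#' @param validate If `TRUE` (default), reject data violating any stratum
#'   invariant; with `FALSE` an invalid table can be built for inspection
#'   with [validateTable()].
#' @return A [SurveillanceTable].
#' @examples
#' tab <- surveillanceTable(data.frame(
#'   school_id = "school_01", division = "DI", academic_year = "2014/15",
#'   sport = "womens_soccer", event_type = "competition",
#'   diagnosis = "sprain", injuries = 3L, athlete_exposures = 150L))
#' computeRawRate(totalInjuries(tab), totalExposures(tab))
#' @export
surveillanceTable <- function(data, levelSets = defaultLevelSets(),
                              validate = TRUE) {
  data <- as.data.frame(data)[, intersect(SURV_COLUMNS, names(data)),
                              drop = FALSE]
  for (col in setdiff(SURV_COLUMNS, c("injuries", "athlete_exposures")))
    if (col %in% names(data)) data[[col]] <- as.character(data[[col]])
  for (col in c("injuries", "athlete_exposures"))
    if (col %in% names(data)) data[[col]] <- as.integer(data[[col]])
  rownames(data) <- NULL
  obj <- new("SurveillanceTable", data = data, levelSets = levelSets)
  if (validate) {
    report <- validateTable(obj)
    if (nrow(report))
      stop("invalid surveillance table:\n",
           paste0("  row ", report$row, " [", report$rule, "]: ",
                  report$message, collapse = "\n"), call. = FALSE)
  }
  obj
}

#' @describeIn strataData Rows of a surveillance table.
#' @export
setMethod("strataData", "SurveillanceTable", function(x) x@data)

#' @describeIn levelSets Declared levels of a surveillance table.
#' @export
setMethod("levelSets", "SurveillanceTable", function(x) x@levelSets)

#' @describeIn nStrata Row count of a surveillance table.
#' @export
setMethod("nStrata", "SurveillanceTable", function(x) nrow(x@data))

setMethod("show", "SurveillanceTable", function(object) {
  d <- object@data
  cat("SurveillanceTable with", nrow(d), "strata\n")
  cat("  sports:", paste(unique(d$sport), collapse = ", "), "\n")
  cat("  injuries:", sum(d$injuries), " athlete exposures:",
      sum(d$athlete_exposures), "\n")
  cat("  raw rate:", format(computeRawRate(sum(d$injuries),
                                           sum(d$athlete_exposures)),
                            digits = 4), "per 10,000 AEs\n")
})

# counts may carry thousands separators ("1,358") in delimited files
parseCount <- function(x) {
  x <- gsub("[, ]", "", trimws(as.character(x)))
  suppressWarnings(out <- as.numeric(x))
  out[!grepl("^-?[0-9]+$", x)] <- NA_real_
  out
}

#' Read a surveillance table from CSV
#'
#' Expects a UTF-8 CSV with a header naming the eight canonical columns.
#' Count columns are parsed as integers; thousands separators are
#' tolerated. Rows violating stratum invariants (negative injuries,
#' non-positive exposures, undeclared category levels, duplicated stratum
#' keys) are rejected with row-addressed errors.
#'
#' @param path Path to the CSV file.
#' @param levelSets Declared category levels the file is validated against.
#' @return A validated [SurveillanceTable]; row order is preserved.
#' @export
readSurveillanceCSV <- function(path, levelSets = defaultLevelSets()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = TRUE, strip.white = TRUE)
  missing_cols <- setdiff(SURV_COLUMNS, names(raw))
  if (length(missing_cols))
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  raw <- raw[, SURV_COLUMNS]
  for (col in c("injuries", "athlete_exposures")) {
    parsed <- parseCount(raw[[col]])
    bad <- which(is.na(parsed))
    if (length(bad))
      stop("parse error in column '", col, "', row(s) ",
           paste(bad, collapse = ", "), ": cannot parse '",
           raw[[col]][bad[1]], "' as a count", call. = FALSE)
    raw[[col]] <- as.integer(parsed)
  }
  surveillanceTable(raw, levelSets = levelSets)
}

#' Write a surveillance table to CSV
#'
#' Inverse of [readSurveillanceCSV()]: writing and re-reading a valid
#' table is an exact round trip.
#'
#' @param table A [SurveillanceTable].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSurveillanceCSV <- function(table, path) {
  stopifnot(is(table, "SurveillanceTable"))
  utils::write.csv(strataData(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a surveillance table
#'
#' Checks every stratum invariant and reports violations without raising:
#' non-negative injuries, strictly positive athlete exposures, category
#' values drawn from the declared level sets, and uniqueness of the
#' (school, year, sport, event type, diagnosis) stratum key.
#'
#' @param table A [SurveillanceTable] (possibly built with
#'   `validate = FALSE`).
#' @return A `data.frame` with columns `row`, `rule`, `message`; zero rows
#'   iff all invariants hold. Serialize with [jsonlite::toJSON()] for a
#'   machine-readable report.
#' @export
validateTable <- function(table) {
  stopifnot(is(table, "SurveillanceTable"))
  d <- strataData(table)
  ls <- levelSets(table)
  viol <- list()
  add <- function(rows, rule, message) {
    if (length(rows))
      viol[[length(viol) + 1L]] <<- data.frame(
        row = as.integer(rows), rule = rule, message = message,
        stringsAsFactors = FALSE)
  }
  add(which(is.na(d$injuries) | d$injuries < 0L), "injuries_nonnegative",
      "injuries must be a non-negative integer")
  add(which(is.na(d$athlete_exposures) | d$athlete_exposures < 1L),
      "exposures_positive", "athlete_exposures must be >= 1")
  for (cov in intersect(names(ls), names(d))) {
    bad <- which(!d[[cov]] %in% ls[[cov]])
    if (length(bad))
      add(bad, paste0("level_declared:", cov),
          paste0("undeclared ", cov, " level '", d[[cov]][bad[1]], "'"))
  }
  key <- do.call(paste, c(d[STRATUM_KEY], sep = "\r"))
  add(which(duplicated(key) | duplicated(key, fromLast = TRUE)),
      "stratum_unique",
      "duplicated (school, year, sport, event_type, diagnosis) stratum")
  if (length(viol)) do.call(rbind, viol)
  else data.frame(row = integer(), rule = character(),
                  message = character(), stringsAsFactors = FALSE)
}

#' Aggregate a surveillance table over a subset of covariates
#'
#' Sums injuries and athlete exposures within groups defined by `by`;
#' covariates not in `by` are collapsed to the sentinel level `"(all)"`
#' (added to the returned table's level sets) so the result remains a
#' valid [SurveillanceTable]. Aggregation is associative: aggregating by
#' `A` then by `B` (a subset of `A`) equals aggregating by `B` directly.
#'
#' @param table A [SurveillanceTable].
#' @param by Non-empty character subset of the six covariate columns; to
#'   take sport totals use `by = "sport"`.
#' @return Aggregated [SurveillanceTable], groups in first-appearance
#'   order.
#' @export
aggregateTable <- function(table, by) {
  stopifnot(is(table, "SurveillanceTable"))
  if (!length(by))
    stop("'by' must name at least one covariate (use by = \"sport\" for ",
         "sport totals)", call. = FALSE)
  bad <- setdiff(by, SURV_COVARIATES)
  if (length(bad))
    stop("unknown covariate(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  d <- strataData(table)
  collapsed <- setdiff(SURV_COVARIATES, by)
  for (col in collapsed) d[[col]] <- "(all)"
  key <- do.call(paste, c(d[SURV_COVARIATES], sep = "\r"))
  idx <- !duplicated(key)
  out <- d[idx, SURV_COVARIATES, drop = FALSE]
  out$injuries <- as.integer(rowsum(d$injuries, key)[unique(key), 1L])
  out$athlete_exposures <-
    as.integer(rowsum(d$athlete_exposures, key)[unique(key), 1L])
  ls <- levelSets(table)
  for (col in intersect(collapsed, names(ls)))
    ls[[col]] <- unique(c(ls[[col]], "(all)"))
  surveillanceTable(out, levelSets = ls)
}

#' Raw injury rate per `scale` athlete exposures
#'
#' The raw surveillance rate: total injuries divided by total athlete
#' exposures, standardized per `scale` AEs (10,000 by default).
#'
#' @param injuries Non-negative injury count.
#' @param athleteExposures Positive AE denominator.
#' @param scale Standardization constant (> 0).
#' @return `injuries / athleteExposures * scale`.
#' @examples
#' computeRawRate(84, 10000)          # 84 per 10,000 AEs
#' computeRawRate(1358, 80453)        # men's soccer competition
#' @export
computeRawRate <- function(injuries, athleteExposures, scale = 10000) {
  if (any(athleteExposures < 1))
    stop("rate undefined: athlete_exposures must be >= 1", call. = FALSE)
  if (any(scale <= 0)) stop("scale must be > 0", call. = FALSE)
  if (any(injuries < 0)) stop("injuries must be >= 0", call. = FALSE)
  injuries / athleteExposures * scale
}

#' Total injuries in a table
#' @param table A [SurveillanceTable].
#' @return Integer sum of injuries.
#' @export
totalInjuries <- function(table) sum(strataData(table)$injuries)

#' Total athlete exposures in a table
#' @param table A [SurveillanceTable].
#' @return Integer sum of athlete exposures.
#' @export
totalExposures <- function(table) sum(strataData(table)$athlete_exposures)

# fitting requires a single-sport table (sports are modelled separately)
assertSingleSport <- function(table) {
  sports <- unique(strataData(table)$sport)
  if (length(sports) != 1L)
    stop("table mixes sports (", paste(sports, collapse = ", "),
         "); analyze sports separately", call. = FALSE)
  invisible(sports)
}
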