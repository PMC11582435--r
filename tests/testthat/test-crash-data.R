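toy_schema <- function() {
  crash_schema(covariates = c("a1", "a2", "b"),
               exclusive_blocks = list(pair = c("a1", "a2")),
               exhaustive = "pair")
}

toy_csv <- function(path, rows) {
  writeLines(c("severity,a1,a2,b", rows), path)
}

test_that("reading a valid delimited file yields a validated dataset", {
  f <- withr::local_tempfile(fileext = ".csv")
  toy_csv(f, c("MI,1,0,0", "SI,0,1,1", "FI,1,0,1",
               "MI,0,1,0", "SI,1,0,0", "FI,0,1,1"))
  ds <- read_crash_data(f, toy_schema())
  expect_s3_class(ds, "crash_dataset")
  expect_equal(n_records(ds), 6)
  expect_equal(as.character(ds$data$severity),
               c("MI", "SI", "FI", "MI", "SI", "FI"))
})

test_that("integer severity coding 1/2/3 maps onto MI/SI/FI", {
  f <- withr::local_tempfile(fileext = ".csv")
  toy_csv(f, c("1,1,0,0", "2,0,1,1", "3,1,0,1"))
  sch <- crash_schema(c("a1", "a2", "b"),
                      exclusive_blocks = list(pair = c("a1", "a2")),
                      exhaustive = "pair", severity_coding = "integer")
  ds <- read_crash_data(f, sch)
  expect_equal(as.character(ds$data$severity), c("MI", "SI", "FI"))
})

test_that("invalid rows are rejected with row-indexed diagnostics", {
  f <- withr::local_tempfile(fileext = ".csv")
  toy_csv(f, c("MI,1,0,0", "SI,0,1,2"))
  expect_error(read_crash_data(f, toy_schema()), "row 2.*'b'")
  # exclusive-block violation
  toy_csv(f, c("MI,1,1,0"))
  expect_error(read_crash_data(f, toy_schema()), "exclusive block 'pair'")
  # exhaustive block with no indicator set
  toy_csv(f, c("MI,0,0,0"))
  expect_error(read_crash_data(f, toy_schema()), "exactly one indicator")
  # missing severity column
  writeLines(c("a1,a2,b", "1,0,0"), f)
  expect_error(read_crash_data(f, toy_schema()), "severity")
})

test_that("write/read round trip reproduces the table", {
  df <- data.frame(severity = c("MI", "SI", "FI", "SI"),
                   a1 = c(1, 0, 1, 0), a2 = c(0, 1, 0, 1),
                   b = c(0, 1, 1, 0))
  ds <- crash_dataset(df, toy_schema(), label = "toy")
  f <- withr::local_tempfile(fileext = ".csv")
  write_crash_data(ds, f)
  back <- read_crash_data(f, toy_schema(), label = "toy")
  expect_equal(back$data[names(ds$data)], ds$data)
})

test_that("season assignment follows the May 1 - Nov 30 rainy window", {
  expect_equal(assign_season(as.Date("2015-05-01")), "rainy")
  expect_equal(assign_season(as.Date("2015-11-30")), "rainy")
  expect_equal(assign_season(as.Date("2015-12-01")), "dry")
  expect_equal(assign_season(as.Date("2016-04-30")), "dry")
  expect_error(assign_season("not-a-date"))
})

test_that("a non-leap year has exactly 214 rainy days", {
  days <- seq(as.Date("2015-01-01"), as.Date("2015-12-31"), by = "day")
  s <- assign_season(days)
  expect_equal(sum(s == "rainy"), 214)
  expect_equal(sum(s == "dry"), 365 - 214)
})

test_that("contingency tables count severities by season and respect margins", {
  sch <- toy_schema()
  mk <- function(sev) {
    crash_dataset(data.frame(severity = sev,
                             a1 = 1, a2 = 0, b = 0), sch)
  }
  rainy <- mk(c("MI", "MI", "SI", "FI"))
  dry <- mk(c("SI", "FI", "FI"))
  tab <- build_contingency(list(rainy = rainy, dry = dry))
  expect_equal(unclass(tab),
               matrix(c(2L, 0L, 1L, 1L, 1L, 2L), 2,
                      dimnames = list(c("rainy", "dry"), severity_levels())))
  expect_equal(rowSums(tab), c(rainy = 4, dry = 3))
  # single record
  tab1 <- build_contingency(list(rainy = mk("FI")))
  expect_equal(sum(tab1), 1)
  expect_equal(unname(tab1[1, "FI"]), 1)
  # order invariance
  perm <- mk(c("FI", "SI", "MI", "MI"))
  expect_equal(unclass(build_contingency(list(rainy = perm, dry = dry))),
               unclass(tab))
  expect_error(build_contingency(list()), "empty")
})

test_that("records with missing covariates are dropped with a message", {
  f <- withr::local_tempfile(fileext = ".csv")
  toy_csv(f, c("MI,1,0,0", "SI,0,1,NA", "FI,1,0,1"))
  expect_message(ds <- read_crash_data(f, toy_schema()), "dropping 1")
  expect_equal(n_records(ds), 2)
})

test_that("season labels inconsistent with dates are rejected", {
  df <- data.frame(severity = "MI", a1 = 1, a2 = 0, b = 0,
                   date = as.Date("2015-06-15"), season = "dry")
  expect_error(crash_dataset(df, toy_schema()), "inconsistent")
  df$season <- "rainy"
  ds <- crash_dataset(df, toy_schema())
  expect_equal(ds$data$year, 2015L)
})
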