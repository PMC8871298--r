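test_that("device JSON round-trip preserves records at full precision", {
  co <- tiny_cohort(seed = 3)
  m <- co$measurements[[1L]]
  f <- withr::local_tempfile(fileext = ".json")
  write_measurement(m, f)
  m2 <- read_measurement(f)
  expect_identical(m2$measurement_id, m$measurement_id)
  expect_identical(m2$class_label, m$class_label)
  expect_identical(names(m2$sensors), names(m$sensors))
  for (sid in names(m$sensors)) {
    expect_identical(m2$sensors[[sid]]$baseline, m$sensors[[sid]]$baseline)
    expect_identical(m2$sensors[[sid]]$breath, m$sensors[[sid]]$breath)
    expect_identical(m2$sensors[[sid]]$family, m$sensors[[sid]]$family)
  }
  # second round trip is bit-stable
  f2 <- withr::local_tempfile(fileext = ".json")
  write_measurement(m2, f2)
  expect_identical(readLines(f2, warn = FALSE), readLines(f, warn = FALSE))
})

test_that("unicode measurement ids survive the round trip", {
  tr <- raw_sensor_trace("GNP01", "GNP", baseline = c(1, 2, 3),
                         breath = c(4, 5, 6))
  m <- breath_measurement("méasure-α", list(tr),
                          class_label = "control")
  f <- withr::local_tempfile(fileext = ".json")
  write_measurement(m, f)
  expect_identical(read_measurement(f)$measurement_id, "méasure-α")
})

test_that("schema violations raise errors naming the offending part", {
  f <- withr::local_tempfile(fileext = ".json")
  rec <- list(schema_version = "1.0", measurement_id = "m1", label = "cancer",
              metadata = list(),
              sensors = list(list(sensor_id = "GNP01", family = "GNP",
                                  sampling_interval_s = 1,
                                  baseline = c(1, 2, 3))))
  jsonlite::write_json(rec, f, auto_unbox = TRUE)
  expect_error(read_measurement(f), "breath.*GNP01|GNP01.*breath")

  rec$sensors[[1L]]$breath <- list(1, "oops", 3)
  jsonlite::write_json(rec, f, auto_unbox = TRUE)
  expect_error(read_measurement(f), "index 2")

  rec2 <- list(schema_version = "1.0", label = "cancer",
               sensors = rec$sensors)
  jsonlite::write_json(rec2, f, auto_unbox = TRUE)
  expect_error(read_measurement(f), "measurement_id")

  m <- breath_measurement("m1", list(raw_sensor_trace("S1", "GNP", 1:3, 1:3)))
  m$sensors <- list()
  expect_error(write_measurement(m, f), "empty sensors")
})

test_that("screening excludes measurements with missing or empty traces", {
  co <- tiny_cohort(n_cancer = 10, n_control = 10, seed = 5)
  # remove one sensor from 3 measurements, empty a trace in a 4th
  for (i in 1:3) co$measurements[[i]]$sensors[["GNP01"]] <- NULL
  co$measurements[[4L]]$sensors[["MOXA01"]]$breath <- numeric(0)
  co2 <- suppressMessages(screen_cohort(co))
  excluded <- Filter(function(m) m$excluded, co2$measurements)
  expect_length(excluded, 4L)
  expect_setequal(
    vapply(excluded, function(m) m$exclusion_reason, character(1)),
    c(rep("missing_sensor:GNP01", 3), "missing_sensor:MOXA01"))
  expect_length(kept_measurements(co2), 16L)

  # idempotent
  co3 <- suppressMessages(screen_cohort(co2))
  expect_identical(co3, co2)

  # clean cohort untouched
  clean <- tiny_cohort(seed = 6)
  expect_identical(kept_measurements(suppressMessages(screen_cohort(clean))),
                   clean$measurements)
})

test_that("a screened 139-measurement cohort with 12 faulty records keeps 127", {
  co <- tiny_cohort(n_cancer = 54, n_control = 85, n_sensors = 3, T = 30,
                    seed = 11)
  drop <- sample(seq_along(co$measurements), 12L)
  for (i in drop) co$measurements[[i]]$sensors[[1L]] <- NULL
  co2 <- suppressMessages(screen_cohort(co))
  expect_length(kept_measurements(co2), 127L)
})

test_that("exclusion is blind to class labels", {
  co <- tiny_cohort(n_cancer = 12, n_control = 12, seed = 7)
  drop <- c(2L, 9L, 17L) # arbitrary positions regardless of class
  for (i in drop) co$measurements[[i]]$sensors[[1L]] <- NULL
  co2 <- suppressMessages(screen_cohort(co))
  excl_ids <- names(Filter(function(m) m$excluded, co2$measurements))
  expect_identical(sort(excl_ids),
                   sort(names(co$measurements)[drop]))
  # all measurements excluded -> error
  co3 <- tiny_cohort(n_cancer = 2, n_control = 2, seed = 8)
  required <- names(co3$measurements[[1L]]$sensors)
  for (i in seq_along(co3$measurements))
    co3$measurements[[i]]$sensors[[1L]] <- NULL
  expect_error(suppressMessages(screen_cohort(co3, required)), "empty cohort")
})

test_that("cohorts read back from disk with a sample sheet", {
  co <- tiny_cohort(n_cancer = 4, n_control = 4, seed = 9)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  co2 <- read_cohort(dir, sample_sheet = file.path(dir, "sample_sheet.csv"))
  expect_identical(sort(names(co2$measurements)), sort(names(co$measurements)))
  expect_identical(cohort_labels(co2)[names(cohort_labels(co))],
                   cohort_labels(co))
  # manifest route
  co3 <- read_cohort(file.path(dir, "manifest.json"))
  expect_length(co3$measurements, length(co$measurements))
})
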