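test_that("read_universe inverts write_universe, byte-stably", {
  out <- simulate_universe(J = 3, counties_per_state = c(2, 5), seed = 3)
  uc <- apply_censoring(out$universe)
  d1 <- withr::local_tempdir()
  write_universe(uc, d1)
  u2 <- read_universe(d1)
  expect_equal(uc, u2, ignore_attr = TRUE)

  # writer output is byte-stable under a read/write cycle
  d2 <- withr::local_tempdir()
  write_universe(u2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d2, f)), readLines(file.path(d1, f)),
                     label = paste("file", f))
  }
})

test_that("censored and suppressed cells serialize as flags with empty values", {
  out <- simulate_universe(J = 3, counties_per_state = 6, seed = 11)
  uc <- apply_censoring(out$universe)
  # the seed gives at least one suppressed / censored cell of each kind
  expect_gt(sum(uc$mortality$suppressed), 0)
  expect_gt(sum(uc$fair_poor_health$censored), 0)
  d <- withr::local_tempdir()
  write_universe(uc, d)
  mort <- readr::read_csv(file.path(d, "mortality.csv"),
                          show_col_types = FALSE)
  expect_true(all(is.na(mort$deaths[mort$suppressed])))
  u2 <- read_universe(d)
  expect_true(all(is.na(u2$mortality$deaths[u2$mortality$suppressed])))
  # suppressed low-birth-weight cells: events absent after the round trip
  if (any(uc$low_birth_weight$suppressed)) {
    expect_true(all(is.na(
      u2$low_birth_weight$events[u2$low_birth_weight$suppressed])))
  }
})

test_that("validation rejects invariant violations with county-addressable messages", {
  out <- simulate_universe(J = 2, counties_per_state = 3, seed = 5)
  u <- out$universe

  bad <- u
  bad$mortality$deaths[4] <- bad$mortality$population[4] + 10L
  expect_error(validate_universe(bad), "exceeding population.*j=")

  bad <- u
  bad$low_birth_weight$events[1] <- bad$low_birth_weight$births[1] + 1L
  expect_error(validate_universe(bad), "low_birth_weight.*j=1, k=1")

  bad <- u
  bad$mortality$suppressed[2] <- TRUE  # flag set but count still present
  expect_error(validate_universe(bad), "suppressed")

  bad <- u
  bad$fair_poor_health$ci_low[2] <- bad$fair_poor_health$prevalence[2] + 0.01
  expect_error(validate_universe(bad), "fair_poor_health")

  # single state is rejected (state variance unidentifiable downstream)
  solo <- u
  for (nm in c("geography", "demographics", "mortality", "low_birth_weight",
               "fair_poor_health", "poor_physical_days", "poor_mental_days"))
    solo[[nm]] <- dplyr::filter(solo[[nm]], state_index == 1)
  solo$geography <- countyrank:::canonical_geography(solo$geography)
  expect_error(validate_universe(solo), "two states")
})

test_that("an empty county list cannot be written", {
  out <- simulate_universe(J = 2, counties_per_state = 2, seed = 5)
  u <- out$universe
  for (nm in setdiff(names(u), "measures")) u[[nm]] <- u[[nm]][0, ]
  expect_error(write_universe(u, withr::local_tempdir()), "empty")
})

test_that("malformed rows are reported with file and location", {
  out <- simulate_universe(J = 2, counties_per_state = 3, seed = 5)
  d <- withr::local_tempdir()
  write_universe(out$universe, d)
  path <- file.path(d, "low_birth_weight.csv")
  lines <- readLines(path)
  lines[3] <- sub("^(S[0-9]+,[^,]+,)[0-9]+", "\\1not_a_number", lines[3])
  writeLines(lines, path)
  expect_error(read_universe(d), "low_birth_weight.csv")
})

test_that("measure weights are the published composite scheme", {
  cfg <- measure_config()
  expect_setequal(cfg$weight, c(0.50, 0.10, 0.10, 0.10, 0.20))
  expect_equal(sum(cfg$weight), 1)
  expect_equal(cfg$weight[cfg$measure == "premature_mortality"], 0.5)
  bad <- cfg
  bad$weight[1] <- 0.4
  expect_error(countyrank:::validate_measure_config(bad), "sum to 1")
})
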