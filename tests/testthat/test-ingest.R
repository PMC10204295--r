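test_that("hourly reader splits stations and preserves missingness", {
  tmp <- tempfile(fileext = ".csv")
  write_hourly_fixture(tmp, list(A = rep(50, 48), B = rep(60, 48)))
  sl <- read_station_hourly(tmp)
  expect_length(sl, 2)
  expect_equal(vapply(sl, function(s) length(s$values), integer(1)),
               c(48L, 48L))
  # empty file with header
  tmp2 <- tempfile(fileext = ".csv")
  writeLines("station,lon,lat,timestamp,ozone_ugm3", tmp2)
  expect_length(read_station_hourly(tmp2), 0)
  # a non-numeric cell becomes missing, length unchanged
  v <- as.character(rep(40, 24))
  v[5] <- "bad"
  tmp3 <- tempfile(fileext = ".csv")
  write_hourly_fixture(tmp3, list(A = v))
  expect_warning(s3 <- read_station_hourly(tmp3), "non-numeric")
  expect_length(s3[[1]]$values, 24)
  expect_true(is.na(s3[[1]]$values[5]))
})

test_that("hourly reader names a missing required column", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(c("station,lon,lat,timestamp", "A,114,22.5,2013-01-01 00:00:00"),
             tmp)
  expect_error(read_station_hourly(tmp), "ozone_ugm3")
})

test_that("daily QC applies the completeness rule and the arithmetic mean", {
  tmp <- tempfile(fileext = ".csv")
  write_hourly_fixture(tmp, list(A = c(rep(40, 12), rep(100, 12))))
  d <- daily_mean_qc(read_station_hourly(tmp)[[1]])
  expect_true(d$valid[1])
  expect_equal(d$value[1], 70)
  # 10 of 24 hours at min_completeness 0.75 -> invalid
  v <- c(rep(55, 10), rep(NA, 14))
  tmp2 <- tempfile(fileext = ".csv")
  write_hourly_fixture(tmp2, list(A = v))
  d2 <- daily_mean_qc(read_station_hourly(tmp2)[[1]], min_completeness = 0.75)
  expect_false(d2$valid[1])
  expect_true(is.na(d2$value[1]))
})

test_that("daily QC is invariant to the order of hourly rows", {
  set.seed(7)
  v <- runif(72, 20, 120)
  tmp <- tempfile(fileext = ".csv")
  write_hourly_fixture(tmp, list(A = v))
  base <- daily_mean_qc(read_station_hourly(tmp)[[1]])
  df <- read.csv(tmp, stringsAsFactors = FALSE)
  df <- df[sample(nrow(df)), ]
  tmp2 <- tempfile(fileext = ".csv")
  write.csv(df, tmp2, row.names = FALSE)
  expect_equal(daily_mean_qc(read_station_hourly(tmp2)[[1]]), base)
})

test_that("citywide pooling averages valid stations per day", {
  d1 <- daily_series(as.Date("2013-01-01") + 0:2, c(60, 60, 60))
  d2 <- daily_series(as.Date("2013-01-01") + 0:2, c(80, 80, NA),
                     valid = c(TRUE, TRUE, FALSE))
  d3 <- daily_series(as.Date("2013-01-01") + 0:2, c(100, NA, 100),
                     valid = c(TRUE, FALSE, TRUE))
  expect_equal(pool_citywide(list(d1))$value, d1$value)
  expect_equal(pool_citywide(list(d1, d2))$value[1], 70)
  p <- pool_citywide(list(d1, d2, d3))
  expect_equal(p$value, c(80, 70, 80))
  expect_true(all(p$valid))
})

test_that("nearest-station assignment uses great-circle distance", {
  h <- data.frame(id = "h1", lon = 114.0, lat = 22.5)
  s <- data.frame(id = c("sA", "sB"), lon = c(114.0, 114.5),
                  lat = c(22.6, 22.5))
  # independent haversine check on the 6371 km sphere
  hav <- function(lon1, lat1, lon2, lat2) {
    to <- pi / 180
    a <- sin((lat2 - lat1) * to / 2)^2 +
      cos(lat1 * to) * cos(lat2 * to) * sin((lon2 - lon1) * to / 2)^2
    2 * 6371 * asin(sqrt(a))
  }
  expect_lt(hav(114, 22.5, 114, 22.6), hav(114, 22.5, 114.5, 22.5))
  expect_equal(unname(assign_nearest_station(h, s)), "sA")
  # coincident hospital-station pair and single-station degenerate cases
  expect_equal(unname(assign_nearest_station(
    data.frame(id = "h2", lon = 114.5, lat = 22.5), s)), "sB")
  expect_equal(unname(assign_nearest_station(h, s[1, , drop = FALSE])), "sA")
  expect_error(assign_nearest_station(
    data.frame(id = "h", lon = 200, lat = 22), s), "invalid coordinates")
})

test_that("nearest-station ties break lexicographically by station id", {
  h <- data.frame(id = "h1", lon = 114, lat = 22.5)
  # exact tie: two stations at the same coordinates
  s <- data.frame(id = c("sZ", "sA"), lon = 114.1, lat = 22.5)
  expect_equal(unname(assign_nearest_station(h, s)), "sA")
})

test_that("ICD-10 roots partition exhaustively into the four categories", {
  expect_equal(classify_icd10("J06.9"), "AURD")
  expect_equal(classify_icd10(c("J21", "J45")), c("ALRD", "OTHER_RESP"))
  expect_equal(classify_icd10("K52"), "NON_RESP")
  # every J00-J99 root lands in exactly one respiratory category
  roots <- sprintf("J%02d", 0:99)
  cls <- classify_icd10(roots)
  expect_equal(sum(cls == "AURD"), 7)
  expect_equal(sum(cls == "ALRD"), 3)
  expect_equal(sum(cls == "OTHER_RESP"), 90)
  expect_false(any(cls == "NON_RESP"))
  expect_error(classify_icd10("6J0"), "malformed")
})

test_that("aggregation builds zero-filled strata that nest correctly", {
  rng <- as.Date(c("2013-01-01", "2013-01-10"))
  empty <- aggregate_daily_counts(
    data.frame(date = as.Date(character(0)), gender = character(0),
               age = integer(0), icd10 = character(0)), rng)
  expect_equal(sum(get_stratum(empty)$count), 0)
  one <- data.frame(date = as.Date("2013-01-03"), gender = "male",
                    age = 5, icd10 = "J03")
  st <- aggregate_daily_counts(one, rng)
  for (key in list(c("AURD", "male", "0-14"), c("AURD", "all", "all"),
                   c("TOTAL_RESP", "male", "all"),
                   c("TOTAL_RESP", "all", "all"))) {
    s <- get_stratum(st, key[1], key[2], key[3])
    expect_equal(s$count[s$date == as.Date("2013-01-03")], 1L)
    expect_equal(sum(s$count), 1L)
  }
  expect_equal(sum(get_stratum(st, "ALRD", "all", "all")$count), 0L)
  expect_error(aggregate_daily_counts(
    data.frame(date = as.Date("2014-01-01"), gender = "male", age = 3,
               icd10 = "J03"), rng), "outside date_range")
})

test_that("synthetic records round-trip through aggregation exactly", {
  ex <- simulate_exposure(400, seed = 31)
  cnt <- simulate_counts(ex, health_sim_config(365, alpha = log(25),
                                               beta1 = 0, seed = 32))
  rec <- disaggregate_records(cnt, seed = 33,
                              icd_pool = c("J03", "J06.9", "J20", "J21",
                                           "J45", "J96"))
  st <- aggregate_daily_counts(rec, range(cnt$date))
  expect_identical(get_stratum(st)$count, cnt$count)
  # partition invariants on every date, all categories
  for (category in c("TOTAL_RESP", "AURD", "ALRD")) {
    all_s <- get_stratum(st, category, "all", "all")$count
    male <- get_stratum(st, category, "male", "all")$count
    female <- get_stratum(st, category, "female", "all")$count
    expect_identical(male + female, all_s)
    ages <- get_stratum(st, category, "all", "0-14")$count +
      get_stratum(st, category, "all", "15-64")$count +
      get_stratum(st, category, "all", "65+")$count
    expect_identical(ages, all_s)
  }
})

test_that("daily-series CSV dialect round-trips through disk", {
  d <- simulate_exposure(40, seed = 2)
  d$valid[5] <- FALSE
  d$value[5] <- NA
  tmp <- tempfile(fileext = ".csv")
  write_daily_series(daily_series(d$date, d$value, d$valid), tmp)
  back <- read_daily_series(tmp)
  expect_equal(back$value, d$value)
  expect_equal(back$valid, d$valid)
})
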