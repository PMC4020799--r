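fix_row <- function(ts, class, bird = "b1", lon = 0, lat = 0) {
  data.frame(bird_id = bird, timestamp = as.POSIXct(ts, tz = "UTC"),
             lon = lon, lat = lat, location_class = class)
}

test_that("best-per-duty-cycle selection keeps the most accurate fix", {
  # one cycle with classes {0, 3}: the class-3 fix is kept
  fx <- rbind(fix_row("2008-01-05 02:00:00", 0, lon = 1),
              fix_row("2008-01-05 03:30:00", 3, lon = 2))
  dp <- select_daily_positions(fx)
  expect_equal(nrow(dp), 1L)
  expect_equal(dp$location_class, 3L)
  expect_equal(dp$lon, 2)
  expect_equal(dp$date, as.Date("2008-01-05"))

  # a single fix is its own daily position
  expect_equal(nrow(select_daily_positions(fix_row("2008-01-05 02:00:00", 1))),
               1L)

  # tie on class: the earlier fix wins
  fx2 <- rbind(fix_row("2008-01-05 03:00:00", 2, lon = 9),
               fix_row("2008-01-05 02:00:00", 2, lon = 7))
  expect_equal(select_daily_positions(fx2)$lon, 7)

  # empty input is an empty result, not an error
  expect_equal(nrow(select_daily_positions(fx[0, ])), 0L)
})

test_that("duty cycles are cut at the 01:00 GMT switch-on", {
  # 00:30 belongs to the previous day's cycle; 01:30 starts a new one
  fx <- rbind(fix_row("2008-01-06 00:30:00", 1),
              fix_row("2008-01-06 01:30:00", 0))
  dp <- select_daily_positions(fx)
  expect_equal(nrow(dp), 2L)
  expect_equal(dp$date, as.Date(c("2008-01-05", "2008-01-06")))
})

test_that("separate birds and cycles are kept apart", {
  fx <- rbind(fix_row("2008-01-05 02:00:00", 0, bird = "a"),
              fix_row("2008-01-05 02:00:00", 3, bird = "b"),
              fix_row("2008-01-06 02:00:00", 1, bird = "a"))
  dp <- select_daily_positions(fx)
  expect_equal(nrow(dp), 3L)
  # output size never exceeds the number of distinct (bird, cycle) pairs
  set.seed(1)
  fx2 <- data.frame(
    bird_id = sample(letters[1:3], 50, TRUE),
    timestamp = as.POSIXct("2008-01-01", tz = "UTC") +
      runif(50, 0, 10 * 86400),
    lon = runif(50), lat = runif(50),
    location_class = sample(0:3, 50, TRUE))
  dp2 <- select_daily_positions(fx2)
  cyc <- as.Date(fx2$timestamp - 3600, tz = "UTC")
  expect_lte(nrow(dp2), nrow(unique(data.frame(fx2$bird_id, cyc))))
})

test_that("great-circle distance matches the haversine closed form", {
  expect_equal(great_circle_km(12, -34, 12, -34), 0)
  expect_equal(great_circle_km(0, 0, 0, 1), 111.19, tolerance = 1e-4)
  expect_equal(great_circle_km(0, 0, 180, 0), 20015.1, tolerance = 1e-5)
  # symmetry and non-negativity on random pairs
  set.seed(2)
  a <- cbind(runif(20, -180, 180), runif(20, -89, 89))
  b <- cbind(runif(20, -180, 180), runif(20, -89, 89))
  d1 <- great_circle_km(a[, 1], a[, 2], b[, 1], b[, 2])
  d2 <- great_circle_km(b[, 1], b[, 2], a[, 1], a[, 2])
  expect_equal(d1, d2)
  expect_true(all(d1 >= 0))
  expect_error(great_circle_km(0, 95, 0, 0), "latitude")
})

test_that("migration summary implements the published parameter definitions", {
  # two positions: one segment, so min covered = mean = max daily
  daily <- data.frame(bird_id = "b", date = as.Date("2008-01-01") + 0:1,
                      lon = c(0, 1), lat = c(0, 0))
  ms <- migration_summary(daily, 0, 0, "2007-12-11")
  seg <- great_circle_km(0, 0, 1, 0)
  expect_equal(ms$min_distance_covered_km, seg)
  expect_equal(ms$mean_daily_km, seg)
  expect_equal(ms$max_daily_km, seg)
  expect_equal(ms$duration_days, as.integer(as.Date("2008-01-02") -
                                              as.Date("2007-12-11")))

  # stationary at the colony: all distances are zero
  still <- data.frame(bird_id = "b", date = as.Date("2008-01-01") + 0:4,
                      lon = 3, lat = -50)
  ms2 <- migration_summary(still, 3, -50, "2007-12-31")
  expect_equal(ms2$max_distance_colony_km, 0)
  expect_equal(ms2$min_distance_covered_km, 0)

  # deployment 11 Dec 2007, last transmission 28 Aug 2008 -> 261 days
  one <- data.frame(bird_id = "b", date = as.Date("2008-08-28"),
                    lon = 0, lat = 0)
  expect_equal(migration_summary(one, 0, 0, "2007-12-11")$duration_days, 261L)

  expect_error(migration_summary(daily[0, ], 0, 0, "2007-12-11"),
               "no daily positions")
})

test_that("minimum distance covered obeys the triangle inequality", {
  set.seed(3)
  lon <- cumsum(rnorm(30, 0, 0.5)); lat <- cumsum(rnorm(30, 0, 0.5)) - 50
  path_len <- function(lon, lat) {
    n <- length(lon)
    sum(great_circle_km(lon[-n], lat[-n], lon[-1], lat[-1]))
  }
  # monotone non-decreasing as positions are appended
  lens <- vapply(2:30, function(k) path_len(lon[1:k], lat[1:k]), numeric(1))
  expect_true(all(diff(lens) >= 0))
  # removing any interior position never increases the total
  full <- path_len(lon, lat)
  for (k in 2:29)
    expect_lte(path_len(lon[-k], lat[-k]), full + 1e-9)
})

test_that("cohort statistics use the n-1 sd and report sums", {
  s <- data.frame(bird_id = c("a", "b", "c"), colony = c("X", "X", "Y"),
                  duration_days = c(50, 50, 50),
                  max_distance_colony_km = c(10, 20, 30),
                  min_distance_covered_km = c(100, 200, 300),
                  mean_daily_km = c(5, 10, 15), max_daily_km = c(9, 9, 9))
  cs <- cohort_stats(s)
  all_row <- cs[cs$group == "all", ]
  expect_equal(all_row$mean_duration_days, 50)
  expect_equal(all_row$sd_duration_days, 0)
  expect_equal(all_row$total_duration_days, 150)
  expect_equal(all_row$sd_max_distance_colony_km, sd(c(10, 20, 30)))
  # a single-bird colony has no sd, reported as NA (not 0)
  y_row <- cs[cs$group == "Y", ]
  expect_equal(y_row$n_birds, 1L)
  expect_true(is.na(y_row$sd_duration_days))
})

test_that("fix CSV round-trips and normalizes coordinates", {
  fx <- rbind(fix_row("2008-01-05 02:00:00", 2, lon = 185, lat = 10),
              fix_row("2008-01-06 02:00:00", 3, lon = -170, lat = -10))
  f <- tempfile(fileext = ".csv")
  write_argos_csv(fx, f)
  back <- read_argos_csv(f)
  expect_equal(back$lon, c(-175, -170))   # normalized to (-180, 180]
  expect_equal(back$timestamp, fx$timestamp)
  bad <- fx; bad$location_class[1] <- 9
  f2 <- tempfile(fileext = ".csv")
  write_argos_csv(bad, f2)
  expect_error(read_argos_csv(f2), "location_class")
})
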