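#' Read an Argos fix table from CSV
#'
#' Expected columns: `bird_id`, `timestamp` (ISO-8601, UTC), `lon`, `lat`,
#' `location_class` (0-3). Longitudes are normalized to `(-180, 180]`;
#' invalid latitudes or classes are an error.
#'
#' @param file Path to the CSV file.
#' @return Data frame of fixes with `timestamp` as POSIXct (UTC).
#' @export
read_argos_csv <- function(file) {
  x <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("bird_id", "timestamp", "lon", "lat", "location_class")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  x$timestamp <- as.POSIXct(x$timestamp, tz = "UTC",
                            tryFormats = c("%Y-%m-%dT%H:%M:%OSZ",
                                           "%Y-%m-%dT%H:%M:%OS",
                                           "%Y-%m-%d %H:%M:%OS",
                                           "%Y-%m-%d"))
  validate_fixes(x)
}

#' Write an Argos fix table to CSV
#' @param fixes Fix data frame.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_argos_csv <- function(fixes, file) {
  fixes$timestamp <- format(fixes$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(fixes, file, row.names = FALSE)
  invisible(file)
}

validate_fixes <- function(fixes) {
  if (any(is.na(fixes$timestamp))) stop("unparseable timestamps")
  if (any(fixes$lat < -90 | fixes$lat > 90)) stop("latitude outside [-90, 90]")
  if (!all(fixes$location_class %in% 0:3))
    stop("location_class must be one of 0, 1, 2, 3")
  # normalize lon to (-180, 180]
  lon <- fixes$lon %% 360
  lon[lon > 180] <- lon[lon > 180] - 360
  fixes$lon <- lon
  fixes
}

#' Filter fixes to best-per-duty-cycle daily positions
#'
#' Keeps, for each bird and transmitter duty cycle, only the most accurate
#' fix (highest location class; ties broken by earliest timestamp). A duty
#' cycle is the 24 h window opening when the transmitter switches on
#' (01:00 GMT by default), so the retained fix is the "daily position".
#'
#' @param fixes Fix data frame (`bird_id`, `timestamp`, `lon`, `lat`,
#'   `location_class`).
#' @param cycle_start_hour UTC hour at which a duty cycle begins (default 1).
#' @return Data frame of daily positions: `bird_id`, `date` (cycle day),
#'   `lon`, `lat`, `location_class`. Empty input gives an empty result.
#' @export
select_daily_positions <- function(fixes, cycle_start_hour = 1) {
  empty <- data.frame(bird_id = character(), date = as.Date(character()),
                      lon = numeric(), lat = numeric(),
                      location_class = integer())
  if (is.null(fixes) || nrow(fixes) == 0) return(empty)
  fixes <- validate_fixes(fixes)
  cycle <- as.Date(fixes$timestamp - cycle_start_hour * 3600, tz = "UTC")
  ord <- order(fixes$bird_id, cycle, -fixes$location_class, fixes$timestamp)
  f <- fixes[ord, ]; cy <- cycle[ord]
  keep <- !duplicated(data.frame(f$bird_id, cy))
  out <- data.frame(bird_id = f$bird_id[keep], date = cy[keep],
                    lon = f$lon[keep], lat = f$lat[keep],
                    location_class = as.integer(f$location_class[keep]))
  rownames(out) <- NULL
  out[order(out$bird_id, out$date), ]
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km, adequate far below the
#' >1 km Argos positional error.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in degrees (vectorized).
#' @return Distance(s) in km.
#' @examples
#' great_circle_km(0, 0, 0, 1)   # 111.19
#' @export
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  if (any(abs(c(lat1, lat2)) > 90)) stop("latitude outside [-90, 90]")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371)
}

#' Per-bird migratory parameters
#'
#' Computes the standard migratory parameters from a bird's daily
#' positions: tracking duration (whole days from deployment to the last
#' transmission), maximum distance to the colony (furthest displacement from
#' the natal site), minimum distance covered (sum of distances between
#' consecutive daily positions; a lower bound on the true path length), and
#' mean/sd/max daily distance (per consecutive-position segment, regardless
#' of gap length; the number of gap segments spanning more than one day is
#' reported alongside).
#'
#' @param daily Daily positions for one bird (`date`, `lon`, `lat`).
#' @param colony_lon,colony_lat Natal colony coordinates.
#' @param deployment_date Deployment date (`Date` or parseable string).
#' @param bird_id,colony Labels carried into the summary.
#' @return One-row data frame (class `migration_summary`); distance
#'   statistics are `NA` when fewer than two positions are available.
#' @export
migration_summary <- function(daily, colony_lon, colony_lat, deployment_date,
                              bird_id = daily$bird_id[1], colony = NA_character_) {
  if (is.null(daily) || nrow(daily) == 0) stop("no daily positions")
  daily <- daily[order(daily$date), ]
  deployment_date <- as.Date(deployment_date)
  n <- nrow(daily)
  d_col <- great_circle_km(colony_lon, colony_lat, daily$lon, daily$lat)
  if (n >= 2) {
    segs <- great_circle_km(daily$lon[-n], daily$lat[-n],
                            daily$lon[-1], daily$lat[-1])
    gaps <- as.integer(diff(daily$date))
    min_cov <- sum(segs); mean_d <- mean(segs)
    sd_d <- if (n >= 3) stats::sd(segs) else NA_real_
    max_d <- max(segs); n_gap <- sum(gaps > 1)
  } else {
    min_cov <- mean_d <- sd_d <- max_d <- NA_real_; n_gap <- NA_integer_
  }
  out <- data.frame(
    bird_id = bird_id, colony = colony,
    deployment_date = deployment_date,
    departure_date = min(daily$date), end_date = max(daily$date),
    duration_days = as.integer(max(daily$date) - deployment_date),
    max_distance_colony_km = max(d_col),
    min_distance_covered_km = min_cov,
    mean_daily_km = mean_d, sd_daily_km = sd_d, max_daily_km = max_d,
    n_positions = n, n_gap_segments = n_gap)
  class(out) <- c("migration_summary", class(out))
  out
}

#' Cohort statistics of migratory parameters
#'
#' Arithmetic means and sample standard deviations (n-1 denominator) of the
#' per-bird migratory parameters, per colony and/or pooled, plus the total
#' tracking effort in bird-days. With a single bird the sd is reported as
#' `NA`, not 0.
#'
#' @param summaries Data frame of rows from [migration_summary()].
#' @param group `"colony"` for per-colony rows, `"all"` for a pooled row,
#'   or `c("colony", "all")` (default) for both.
#' @return Data frame with one row per group: `group`, `n_birds`,
#'   `total_duration_days`, and `mean_`/`sd_` columns per parameter.
#' @export
cohort_stats <- function(summaries, group = c("colony", "all")) {
  group <- match.arg(group, several.ok = TRUE)
  params <- c("duration_days", "max_distance_colony_km",
              "min_distance_covered_km", "mean_daily_km", "max_daily_km")
  one <- function(df, label) {
    n <- nrow(df)
    row <- data.frame(group = label, n_birds = n,
                      total_duration_days = sum(df$duration_days))
    for (p in params) {
      row[[paste0("mean_", p)]] <- mean(df[[p]])
      row[[paste0("sd_", p)]] <- if (n >= 2) stats::sd(df[[p]]) else NA_real_
    }
    row
  }
  out <- list()
  if ("colony" %in% group)
    for (cl in unique(summaries$colony))
      out[[cl]] <- one(summaries[summaries$colony == cl, ], cl)
  if ("all" %in% group) out[["all"]] <- one(summaries, "all")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Published migratory parameters of the 2007 juvenile king penguin cohort
#'
#' The per-bird migratory parameter table for the 18 juvenile king penguins
#' satellite-tracked from the Falkland Islands (FI, deployed 11 Dec 2007)
#' and South Georgia (SG, deployed 13 Dec 2007), as published: departure
#' and end-of-transmission dates, tracking duration, maximum distance to
#' the colony, minimum distance covered, and mean/max daily distance.
#' Dates in the source are day.month.year; they are parsed to `Date` here.
#'
#' @return Data frame with one row per bird.
#' @export
migration_parameters <- function() {
  f <- system.file("extdata", "kingpenguin_migration_2007.csv",
                   package = "pengdisp", mustWork = TRUE)
  x <- utils::read.csv(f, stringsAsFactors = FALSE)
  for (v in c("deployment_date", "departure_date", "end_date"))
    x[[v]] <- as.Date(x[[v]], format = "%d.%m.%Y")
  x
}
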