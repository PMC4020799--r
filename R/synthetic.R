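#' @name synthetic
#' @title Synthetic dispersal data with known ground truth
#' @description
#' The synthetic module generates (i) spatially autocorrelated environmental
#' fields rescaled into realistic value ranges, (ii) habitat-biased
#' correlated-random-walk tracks started at a colony, and (iii) Argos-like
#' duty-cycled observations of those tracks with class-dependent positional
#' error. Occupancy is driven by a known logistic habitat model, so the full
#' pipeline (gridding, occurrence building, GLM ensemble, mapping) can be
#' validated against ground truth.
NULL

# default value ranges of the candidate variables (natural units)
default_env_ranges <- function() {
  list(BAT  = c(0, 7958),     # depth, m
       CHLa = c(0, 24.91),    # mg m^-3
       SST  = c(0, 21.32),    # degC
       SSH  = c(46.30, 51.29))# cm
}

# Row/column band-smoother: gaussian kernel, rows renormalized so edges keep
# unit weight. O(n^2) construction; intended for desk-scale grids.
make_smoother <- function(n, sigma) {
  h <- ceiling(3 * sigma)
  d <- outer(seq_len(n), seq_len(n), "-")
  k <- ifelse(abs(d) <= h, stats::dnorm(d, 0, sigma), 0)
  k / rowSums(k)
}

smooth_field <- function(z, sigma) {
  if (sigma <= 0) return(z)
  sr <- make_smoother(nrow(z), sigma)
  sc <- make_smoother(ncol(z), sigma)
  sr %*% z %*% t(sc)
}

rescale_range <- function(z, lo, hi) {
  r <- range(z)
  if (r[1] == r[2]) return(matrix((lo + hi) / 2, nrow(z), ncol(z)))
  (z - r[1]) / (r[2] - r[1]) * (hi - lo) + lo
}

#' Generate monthly environmental layers
#'
#' Gaussian white noise is kernel-smoothed to the requested correlation
#' length and linearly rescaled into `value_range`, giving spatially
#' autocorrelated fields whose values never leave the configured range.
#' Months are generated independently.
#'
#' @param grid A `grid_spec`.
#' @param value_range Length-2 numeric `(min, max)` in the variable's units.
#' @param smoothness Spatial correlation length in grid cells (>= 0; 0 gives
#'   white noise).
#' @param months Vector of month indices to generate.
#' @param seed Integer seed; output is bit-identical under a repeated seed.
#' @return Named list of layer matrices, one per month.
#' @export
generate_env_layers <- function(grid, value_range, smoothness, months = 1L,
                                seed) {
  stopifnot(inherits(grid, "grid_spec"))
  if (length(value_range) != 2 || value_range[1] > value_range[2])
    stop("value_range must be (min, max) with min <= max")
  if (smoothness < 0) stop("smoothness must be >= 0")
  set.seed(seed)
  out <- lapply(months, function(m) {
    z <- matrix(stats::rnorm(n_cells(grid)), grid$n_rows, grid$n_cols)
    rescale_range(smooth_field(z, smoothness), value_range[1], value_range[2])
  })
  names(out) <- paste0("month", months)
  out
}

#' Build a complete synthetic environmental stack
#'
#' Generates monthly BAT, CHLa, SST and SSH fields within their default
#' ranges, composites the dynamic variables over the months, derives the
#' four proportional-change gradient layers ([gradient_pc()]) on the raw
#' composites, and standardizes everything, yielding the eight candidate
#' covariates ready for modelling.
#'
#' @param grid A `grid_spec`.
#' @param seed Integer seed.
#' @param smoothness Correlation length in cells for every field (default 4).
#' @param months Months to generate and composite (default 1:3, the
#'   January-March modelling window).
#' @param ranges Named list of `(min, max)` ranges; default
#'   `default_env_ranges()`.
#' @return A standardized `env_stack` with layers BAT, BAT.G3, CHLa,
#'   CHLa.G3, SST, SST.G3, SSH, SSH.G3.
#' @export
make_synthetic_stack <- function(grid, seed, smoothness = 4, months = 1:3,
                                 ranges = default_env_ranges()) {
  layers <- list()
  for (i in seq_along(ranges)) {
    v <- names(ranges)[i]
    monthly <- generate_env_layers(grid, ranges[[v]], smoothness,
                                   months = months, seed = seed + i)
    layers[[v]] <- temporal_composite(monthly)
  }
  for (v in names(ranges)) layers[[paste0(v, ".G3")]] <- gradient_pc(layers[[v]])
  layers <- layers[canonical_terms()]
  standardize_stack(env_stack(grid, layers))
}

#' Known logistic habitat model (simulation ground truth)
#'
#' @param coefficients Named numeric vector of coefficients on standardized
#'   covariates; the name `(Intercept)` is the intercept (0 if absent).
#' @return Object of class `habitat_model`.
#' @export
habitat_model <- function(coefficients) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)))
  if (!"(Intercept)" %in% names(coefficients))
    coefficients <- c("(Intercept)" = 0, coefficients)
  structure(list(coefficients = coefficients), class = "habitat_model")
}

model_linear_predictor <- function(model, stack) {
  co <- model$coefficients
  terms <- setdiff(names(co), "(Intercept)")
  missing_vars <- setdiff(terms, names(stack$layers))
  if (length(missing_vars))
    stop("stack has no layer(s): ", paste(missing_vars, collapse = ", "))
  eta <- matrix(co[["(Intercept)"]], stack$grid$n_rows, stack$grid$n_cols)
  for (v in terms) eta <- eta + co[[v]] * stack$layers[[v]]
  eta
}

#' Habitat suitability surface of a known model
#'
#' @param model A `habitat_model`.
#' @param stack A standardized `env_stack` containing every model term.
#' @return Matrix of inverse-logit suitabilities in (0, 1) (`NA` where a
#'   covariate is missing).
#' @export
suitability_map <- function(model, stack) {
  stats::plogis(model_linear_predictor(model, stack))
}

#' Calibrate a model intercept to an expected presence count
#'
#' Solves for the intercept at which the sum of per-cell occupancy
#' probabilities over the grid equals `target_presences`, so simulated
#' studies can be pinned to a realistic number of presence cells.
#'
#' @param model A `habitat_model`.
#' @param stack A standardized `env_stack`.
#' @param target_presences Expected number of occupied cells.
#' @return The model with its intercept recalibrated.
#' @export
calibrate_intercept <- function(model, stack, target_presences) {
  stopifnot(target_presences > 0)
  m0 <- model; m0$coefficients[["(Intercept)"]] <- 0
  eta0 <- model_linear_predictor(m0, stack)
  f <- function(b0) sum(stats::plogis(b0 + eta0), na.rm = TRUE) - target_presences
  b0 <- stats::uniroot(f, c(-50, 50))$root
  model$coefficients[["(Intercept)"]] <- b0
  model
}

#' Draw occupied cells from a known habitat model
#'
#' Each cell with defined covariates is occupied independently with its
#' model probability (Bernoulli draw), the generative counterpart of the
#' binomial/logit GLM fitted downstream.
#'
#' @param model A `habitat_model`.
#' @param stack A standardized `env_stack`.
#' @param seed Integer seed.
#' @return Sorted integer vector of occupied row-major cell ids.
#' @export
sample_presence_cells <- function(model, stack, seed) {
  p <- suitability_map(model, stack)
  set.seed(seed)
  u <- matrix(stats::runif(length(p)), nrow(p), ncol(p))
  occ <- !is.na(p) & u < p
  as.integer(which(t(occ)))
}

#' Simulation configuration
#'
#' Bundles movement and observation parameters for the track simulator.
#' Defaults reflect the study conditions: daily steps around 45 +/- 25 km,
#' a 4 h on / 20 h off transmitter duty cycle switched on at 01:00 GMT, and
#' an Argos location-class mix under which about 98.6\% of daily best fixes
#' are accurate to 1 km or better (class >= 1).
#'
#' @param step_km_mean,step_km_sd Mean and sd of the daily step length (km);
#'   steps are lognormal with this mean and sd.
#' @param turn_concentration Directional-persistence parameter (>= 0; 0 is
#'   an uncorrelated walk; larger values concentrate turns around the
#'   previous heading with circular sd `1/sqrt(turn_concentration)` rad).
#' @param habitat_bias Weight (>= 0) pulling steps toward higher suitability;
#'   candidate destinations are chosen with probability proportional to
#'   `exp(habitat_bias * suitability)`.
#' @param duty_on_hours,duty_off_hours Transmitter duty cycle (4/20).
#' @param duty_start_hour UTC hour at which the daily on-window opens (1).
#' @param class_probabilities Named probabilities of Argos classes
#'   `"0".."3"`; must sum to 1.
#' @param class_error_km Named positional error scale (RMS displacement, km)
#'   per class; must decrease from class 0 to class 3.
#' @param fixes_lambda Fixes per on-window are `1 + Poisson(fixes_lambda)`.
#' @param n_candidates Candidate destinations evaluated per daily step.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(step_km_mean = 45, step_km_sd = 25,
                       turn_concentration = 2, habitat_bias = 2,
                       duty_on_hours = 4, duty_off_hours = 20,
                       duty_start_hour = 1,
                       class_probabilities = c("0" = 0.088, "1" = 0.300,
                                               "2" = 0.350, "3" = 0.262),
                       class_error_km = c("0" = 1.5, "1" = 1.0,
                                          "2" = 0.35, "3" = 0.15),
                       fixes_lambda = 2, n_candidates = 24) {
  stopifnot(step_km_mean > 0, step_km_sd >= 0,
            turn_concentration >= 0, habitat_bias >= 0,
            duty_on_hours + duty_off_hours == 24)
  if (!setequal(names(class_probabilities), c("0", "1", "2", "3")))
    stop("class_probabilities must be named '0'..'3'")
  if (abs(sum(class_probabilities) - 1) > 1e-8)
    stop("class_probabilities must sum to 1")
  e <- class_error_km[c("0", "1", "2", "3")]
  if (any(diff(e) >= 0))
    stop("class_error_km must decrease strictly from class 0 to class 3")
  structure(list(step_km_mean = step_km_mean, step_km_sd = step_km_sd,
                 turn_concentration = turn_concentration,
                 habitat_bias = habitat_bias,
                 duty_on_hours = duty_on_hours,
                 duty_off_hours = duty_off_hours,
                 duty_start_hour = duty_start_hour,
                 class_probabilities = class_probabilities,
                 class_error_km = class_error_km,
                 fixes_lambda = fixes_lambda,
                 n_candidates = n_candidates),
            class = "sim_config")
}

KM_PER_DEG <- 6371 * pi / 180  # 111.1949 km per degree of latitude

#' Simulate a habitat-biased correlated random walk
#'
#' One position per day. Step lengths are lognormal with the configured
#' mean/sd; each day a set of candidate headings is drawn (persistent around
#' the previous heading when `turn_concentration > 0`, otherwise uniform)
#' and a destination is chosen with probability proportional to
#' `exp(habitat_bias * suitability)`. Candidates leaving the grid or landing
#' on undefined suitability are rejected; if every candidate is rejected the
#' animal stays put for the day.
#'
#' @param config A [sim_config()].
#' @param suitability Suitability matrix on `grid` (from [suitability_map()]).
#' @param grid A `grid_spec`.
#' @param colony_lon,colony_lat Start coordinates; must lie on the grid and
#'   on defined suitability.
#' @param start_date Deployment date (`Date`); position `d` is dated
#'   `start_date + d`.
#' @param n_days Number of daily positions (>= 1).
#' @param seed Integer seed.
#' @return Data frame with `day`, `date`, `lon`, `lat`.
#' @export
simulate_track <- function(config, suitability, grid, colony_lon, colony_lat,
                           start_date, n_days, seed) {
  stopifnot(inherits(config, "sim_config"), n_days >= 1)
  start_id <- cell_from_lonlat(grid, colony_lon, colony_lat)
  if (is.na(start_id)) stop("colony lies outside the grid")
  if (all(is.na(suitability))) stop("suitability is undefined everywhere")
  start_date <- as.Date(start_date)
  m <- config$step_km_mean; s <- config$step_km_sd
  sdlog <- sqrt(log(1 + (s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2
  set.seed(seed)
  lon <- colony_lon; lat <- colony_lat
  heading <- stats::runif(1, -pi, pi)
  out_lon <- numeric(n_days); out_lat <- numeric(n_days)
  K <- config$n_candidates
  for (d in seq_len(n_days)) {
    L <- stats::rlnorm(1, meanlog, sdlog)
    if (config$turn_concentration > 0) {
      hs <- heading + stats::rnorm(K, 0, 1 / sqrt(config$turn_concentration))
    } else {
      hs <- stats::runif(K, -pi, pi)
    }
    dest_lat <- lat + L * sin(hs) / KM_PER_DEG
    dest_lon <- lon + L * cos(hs) / (KM_PER_DEG * cos(lat * pi / 180))
    ids <- cell_from_lonlat(grid, dest_lon, dest_lat)
    suit <- rep(NA_real_, K)
    suit[!is.na(ids)] <- suitability[mat_index(grid, ids[!is.na(ids)])]
    w <- if (config$habitat_bias > 0) exp(config$habitat_bias * suit) else
      rep(1, K)
    w[is.na(suit)] <- 0
    if (any(w > 0)) {
      j <- sample.int(K, 1, prob = w)
      lon <- dest_lon[j]; lat <- dest_lat[j]; heading <- hs[j]
    }
    out_lon[d] <- lon; out_lat[d] <- lat
  }
  data.frame(day = seq_len(n_days), date = start_date + seq_len(n_days),
             lon = out_lon, lat = out_lat)
}

#' Observe a true track through an Argos-like system
#'
#' For each daily true position, a number of fixes (`1 + Poisson`) is
#' emitted at uniform times inside that day's 4-hour on-window (opening at
#' `duty_start_hour` UTC); each fix draws a location class from the
#' configured class mix and bivariate Gaussian positional noise whose RMS
#' displacement equals the class's error scale.
#'
#' @param track Data frame from [simulate_track()] (`date`, `lon`, `lat`).
#' @param config A [sim_config()].
#' @param bird_id Identifier attached to every fix.
#' @param seed Integer seed.
#' @return Data frame of fixes: `bird_id`, `timestamp` (POSIXct UTC), `lon`,
#'   `lat`, `location_class` (integer 0-3), time-ordered.
#' @export
apply_argos_observation <- function(track, config, bird_id, seed) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(track) == 0) stop("empty track")
  set.seed(seed)
  classes <- as.integer(names(config$class_probabilities))
  res <- vector("list", nrow(track))
  for (i in seq_len(nrow(track))) {
    n <- 1L + stats::rpois(1, config$fixes_lambda)
    offs <- sort(stats::runif(n, 0, config$duty_on_hours * 3600))
    ts <- as.POSIXct(paste0(track$date[i], " 00:00:00"), tz = "UTC") +
      config$duty_start_hour * 3600 + offs
    cls <- sample(classes, n, replace = TRUE,
                  prob = config$class_probabilities)
    err <- config$class_error_km[as.character(cls)] / sqrt(2)  # per-axis sd
    dx <- stats::rnorm(n, 0, 1) * err
    dy <- stats::rnorm(n, 0, 1) * err
    res[[i]] <- data.frame(
      bird_id = bird_id, timestamp = ts,
      lon = track$lon[i] + dx / (KM_PER_DEG * cos(track$lat[i] * pi / 180)),
      lat = track$lat[i] + dy / KM_PER_DEG,
      location_class = cls)
  }
  do.call(rbind, res)
}

#' Simulate a complete dispersal study
#'
#' Convenience wrapper: given a standardized stack and a known habitat
#' model, simulates habitat-biased tracks for every bird at every colony and
#' observes them through the Argos model, returning the raw fix table the
#' processing pipeline starts from. The walk is biased by *relative*
#' suitability (the model surface rescaled to `[0, 1]`), so the strength of
#' the movement bias does not depend on the occupancy intercept.
#'
#' @param config A [sim_config()].
#' @param stack A standardized `env_stack`.
#' @param model A `habitat_model` driving the movement bias.
#' @param colonies Data frame with `name`, `lon`, `lat`, `deployment_date`,
#'   `n_birds`.
#' @param n_days Tracking days per bird.
#' @param seed Integer seed.
#' @return List with `fixes` (all Argos fixes), `tracks` (list of true
#'   tracks), `birds` (bird/colony lookup), `model`, `config`.
#' @export
simulate_dispersal_study <- function(config, stack, model, colonies, n_days,
                                     seed) {
  suit <- suitability_map(model, stack)
  rng <- range(suit, na.rm = TRUE)
  if (diff(rng) > 0) suit <- (suit - rng[1]) / diff(rng)
  fixes <- list(); tracks <- list(); birds <- list()
  k <- 0L
  for (i in seq_len(nrow(colonies))) {
    for (b in seq_len(colonies$n_birds[i])) {
      k <- k + 1L
      id <- sprintf("%s_%02d", colonies$name[i], b)
      tr <- simulate_track(config, suit, stack$grid,
                           colonies$lon[i], colonies$lat[i],
                           colonies$deployment_date[i], n_days,
                           seed = seed + 97L * k)
      tracks[[id]] <- tr
      fixes[[id]] <- apply_argos_observation(tr, config, id,
                                             seed = seed + 97L * k + 1L)
      birds[[k]] <- data.frame(bird_id = id, colony = colonies$name[i],
                               deployment_date = as.Date(colonies$deployment_date[i]))
    }
  }
  list(fixes = do.call(rbind, fixes), tracks = tracks,
       birds = do.call(rbind, birds), model = model, config = config)
}
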