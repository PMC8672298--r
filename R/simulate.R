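# Synthetic scenes with known ground truth. Seasonal greenness follows a
# double-sigmoid (double-logistic) land-surface-phenology curve; clouds and
# snow corrupt observations downward and degrade the reliability code,
# which is exactly the artifact structure the quality mask and the
# negative-outlier screen are built to remove.

#' Configuration of a synthetic scene
#'
#' Defaults emulate a 20-year record (2001-2020) of 16-day composites over
#' a temperate forest landscape: winter NDVI around 0.5, summer NDVI
#' around 0.8 (per-pixel parameters drawn uniformly from the stated
#' ranges), green-up in late April, senescence in October, additive
#' Gaussian observation noise of 0.02, 10% cloud contamination per step,
#' and 5% snow contamination in winter steps. The same seed always
#' reproduces the same scene.
#'
#' @param n_rows,n_cols Scene dimensions (default 64 x 64).
#' @param years Calendar years of the record (default 2001:2020).
#' @param winter_ndvi,summer_amplitude,greenup_doy,senescence_doy Length-2
#'   ranges from which per-pixel seasonal-curve parameters are drawn.
#' @param greenup_rate,senescence_rate Logistic steepness (per day) of the
#'   green-up and senescence transitions.
#' @param noise_sd Additive observation noise standard deviation.
#' @param cloud_prob Probability that an observation is cloud-contaminated
#'   (reliability 3, value biased low).
#' @param snow_prob Probability of snow contamination (reliability 2) for
#'   winter steps (start DOY < 60 or > 330).
#' @param trend_per_decade Fractional greenness trend per decade (0 =
#'   stationary).
#' @param seed RNG seed; identical seeds give identical scenes.
#' @param non_forest_prob Probability that a pixel is non-forest (land
#'   cover 324) in all epochs.
#' @param change_prob Probability that a forest pixel converts to
#'   non-forest in the final land-cover epoch.
#' @return An object of class `fc_scene_config`.
#' @export
scene_config <- function(n_rows = 64L, n_cols = 64L, years = 2001:2020,
                         winter_ndvi = c(0.45, 0.55),
                         summer_amplitude = c(0.25, 0.35),
                         greenup_doy = c(110, 130),
                         senescence_doy = c(280, 300),
                         greenup_rate = 0.10, senescence_rate = 0.08,
                         noise_sd = 0.02, cloud_prob = 0.10,
                         snow_prob = 0.05, trend_per_decade = 0,
                         seed = 1L, non_forest_prob = 0.05,
                         change_prob = 0.02) {
  stopifnot(n_rows >= 1, n_cols >= 1, length(years) >= 2,
            noise_sd >= 0, cloud_prob >= 0, cloud_prob <= 1,
            snow_prob >= 0, snow_prob <= 1,
            non_forest_prob >= 0, non_forest_prob <= 1,
            change_prob >= 0, change_prob <= 1,
            all(summer_amplitude >= 0))
  structure(as.list(environment()), class = "fc_scene_config")
}

# Double-sigmoid seasonal curve evaluated at composite start DOYs.
double_sigmoid <- function(doy, winter, amplitude, greenup, senescence,
                           r_up, r_down) {
  winter + amplitude * (stats::plogis(r_up * (doy - greenup)) -
                          stats::plogis(r_down * (doy - senescence)))
}

#' Generate a synthetic scene with known ground truth
#'
#' Produces an NDVI cube (seasonal curve x (1 + trend) + noise, clipped to
#' \[-1, 1\]), a matching quality cube in which cloud/snow-contaminated
#' observations carry degraded reliability codes *and* biased-low NDVI, a
#' four-epoch land-cover stack, and a monthly mean-temperature climatology
#' (warm-season peak in July, in-season roughly April-October).
#'
#' @param config An [scene_config()].
#' @return A list of class `fc_scene`: `ndvi` ([raster_cube()]),
#'   `quality` ([quality_cube()]), `landcover` ([land_cover_stack()]),
#'   `climatology` (12 x rows x cols array), `params` (per-pixel seasonal
#'   parameters), `config`.
#' @export
generate_scene <- function(config = scene_config()) {
  stopifnot(inherits(config, "fc_scene_config"))
  set.seed(config$seed)
  nr <- config$n_rows; nc <- config$n_cols; np <- nr * nc
  cal <- composite_calendar(config$years)
  grid <- grid_spec(0, 0, nr, nc)
  ny <- length(config$years); spy <- cal$steps_per_year
  nt <- n_steps(cal)

  runif_range <- function(rng, n) stats::runif(n, rng[1], rng[2])
  params <- tibble::tibble(
    winter = runif_range(config$winter_ndvi, np),
    amplitude = runif_range(config$summer_amplitude, np),
    greenup = runif_range(config$greenup_doy, np),
    senescence = runif_range(config$senescence_doy, np)
  )
  # clean seasonal signal: step x pixel, repeated over years with trend
  season <- mapply(function(w, a, g, s) {
    double_sigmoid(cal$start_doys, w, a, g, s,
                   config$greenup_rate, config$senescence_rate)
  }, params$winter, params$amplitude, params$greenup, params$senescence)
  trend <- 1 + config$trend_per_decade *
    (config$years - config$years[1]) / 10
  clean <- array(season, c(spy, np))[rep(seq_len(spy), ny), , drop = FALSE] *
    rep(trend, each = spy)
  values <- clean + stats::rnorm(nt * np, sd = config$noise_sd)

  # contamination: degraded code plus a low-biased value
  codes <- matrix(0L, nt, np)
  marginal <- stats::runif(nt * np) < 0.05
  codes[marginal] <- 1L
  cloudy <- stats::runif(nt * np) < config$cloud_prob
  winter_step <- cal$start_doys < 60 | cal$start_doys > 330
  snowy <- (stats::runif(nt * np) < config$snow_prob) &
    rep(winter_step, ny)
  codes[snowy] <- 2L
  codes[cloudy] <- 3L
  contaminated <- cloudy | snowy
  values[contaminated] <- values[contaminated] -
    stats::runif(sum(contaminated), 0.1, 0.5)
  values <- pmin(pmax(values, -1), 1)

  # land cover: forest classes persist across epochs; a small fraction of
  # pixels is non-forest throughout or converts in the last epoch
  epochs <- c(2000L, 2006L, 2012L, 2018L)
  base_class <- sample(c(311L, 312L, 313L), np, replace = TRUE)
  non_forest <- stats::runif(np) < config$non_forest_prob
  base_class[non_forest] <- 324L
  changed <- stats::runif(np) < config$change_prob & !non_forest
  lc <- lapply(seq_along(epochs), function(e) {
    cl <- base_class
    if (e == length(epochs)) cl[changed] <- 324L
    matrix(cl, nr, nc)
  })
  names(lc) <- epochs

  # climatology: July-peaked annual cycle with a north-south gradient
  lat_gradient <- seq(1, -1, length.out = nr)[(seq_len(np) - 1L) %% nr + 1L]
  annual_mean <- 8 + 2 * lat_gradient
  clim <- t(sapply(1:12, function(m) annual_mean + 9 * cos(2 * pi * (m - 7) / 12)))

  structure(
    list(
      ndvi = raster_cube(array(values, c(nt, nr, nc)), grid, cal),
      quality = quality_cube(array(codes, c(nt, nr, nc)), grid, cal),
      landcover = land_cover_stack(lc, grid),
      climatology = array(clim, c(12L, nr, nc)),
      params = params,
      config = config
    ),
    class = "fc_scene"
  )
}

#' Disturbance specification
#'
#' @param footprint Logical matrix marking affected pixels.
#' @param year Calendar year of the disturbance.
#' @param steps Within-year composite steps (1-based) over which the full
#'   magnitude applies.
#' @param magnitude Fractional NDVI drop in \[0, 1\]: values are
#'   multiplied by `1 - magnitude` (0 leaves the cube unchanged).
#' @param recovery_steps Number of subsequent steps over which the drop
#'   fades out linearly (0 = abrupt end).
#' @return An object of class `fc_disturbance`.
#' @export
disturbance_spec <- function(footprint, year, steps, magnitude,
                             recovery_steps = 0L) {
  stopifnot(is.matrix(footprint), is.logical(footprint),
            magnitude >= 0, magnitude <= 1, all(steps >= 1))
  structure(list(footprint = footprint, year = as.integer(year),
                 steps = as.integer(steps), magnitude = magnitude,
                 recovery_steps = as.integer(recovery_steps)),
            class = "fc_disturbance")
}

#' Inject a disturbance into an NDVI cube
#'
#' Multiplies NDVI by `1 - magnitude` inside the footprint during the
#' specified year and steps, then fades the drop out linearly over
#' `recovery_steps` further steps (possibly crossing into the next year).
#' Returns the modified cube together with the ground-truth footprint.
#'
#' @param cube An NDVI [raster_cube()].
#' @param spec A [disturbance_spec()]; the footprint must match the grid
#'   and the year/steps must lie inside the calendar.
#' @return A list with `cube` and logical `truth` (the footprint).
#' @export
inject_disturbance <- function(cube, spec) {
  stopifnot(inherits(cube, "fc_cube"), inherits(spec, "fc_disturbance"))
  d <- dim(cube$values)
  if (!all(dim(spec$footprint) == d[2:3]))
    stop("footprint outside grid: shape mismatch", call. = FALSE)
  cal <- cube$calendar
  yi <- match(spec$year, cal$years)
  if (is.na(yi) || any(spec$steps > cal$steps_per_year))
    stop("disturbance year/steps outside the calendar", call. = FALSE)
  t_full <- (yi - 1L) * cal$steps_per_year + spec$steps
  factor_t <- rep(1, d[1])
  factor_t[t_full] <- 1 - spec$magnitude
  if (spec$recovery_steps > 0L) {
    after <- max(t_full) + seq_len(spec$recovery_steps)
    after <- after[after <= d[1]]
    ramp <- 1 - spec$magnitude *
      (1 - seq_along(after) / (spec$recovery_steps + 1L))
    factor_t[after] <- ramp
  }
  v <- cube$values
  idx <- which(spec$footprint)                   # pixel indices (row-major in matrix sense)
  if (length(idx)) {
    pm <- matrix(v, nrow = d[1])
    pm[, idx] <- pm[, idx] * factor_t
    v <- array(pm, d)
  }
  out <- cube
  out$values <- v
  list(cube = out, truth = spec$footprint)
}
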