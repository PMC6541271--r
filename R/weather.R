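#' Synthetic weather model configuration
#'
#' All parameters of the generative weather model live here rather than in
#' code constants. The model is a latitude-graded seasonal sinusoid with
#' AR(1) daily noise for mean temperature, a positive stochastic
#' mean-to-max offset, a clear-sky seasonal radiation curve attenuated by
#' random cloudiness, astronomical day length, and constant CO2.
#'
#' Temperature climatology: the seasonal mean on day-of-year \eqn{d} at
#' latitude \eqn{\phi} is
#' \deqn{T(d, \phi) = T_{mid} - lapse(\phi - 35) +
#'       (amp + amp_{slope}(\phi - 35)) \cos(2\pi (d - peak)/365)}
#' Defaults approximate Japanese lowland stations (annual mean ~16 C at
#' 35 N falling ~0.9 C per degree northward; seasonal amplitude ~10 C,
#' growing northward; warmest day around July 29).
#'
#' @param T_mid_ref Annual-mean temperature at 35 N (deg C).
#' @param T_lapse Decline of annual mean per degree latitude north (deg C).
#' @param T_amp_ref Seasonal half-amplitude at 35 N (deg C).
#' @param T_amp_slope Increase of half-amplitude per degree latitude.
#' @param T_peak_doy Day of year of the warmest day.
#' @param ar_phi AR(1) coefficient of daily temperature noise.
#' @param tmax_offset Mean Tmax - Tmean offset (deg C).
#' @param tmax_noise_sd SD of the daily offset perturbation (deg C).
#' @param S_base Clear-sky radiation at 35 N at the June solstice minus
#'   amplitude midpoint (MJ m-2 d-1).
#' @param S_amp Seasonal half-amplitude of clear-sky radiation.
#' @param S_lat_slope Decline of clear-sky radiation per degree north.
#' @param cloud_mean,cloud_sd,cloud_min Daily cloud transmission factor:
#'   a normal draw clamped to `[cloud_min, 1]`.
#' @param co2 CO2 concentration (ppm); constant over the season.
#' @return A list of class `weather_config`.
#' @export
weather_config <- function(T_mid_ref = 16, T_lapse = 0.9,
                           T_amp_ref = 10, T_amp_slope = 0.35,
                           T_peak_doy = 210, ar_phi = 0.6,
                           tmax_offset = 5.5, tmax_noise_sd = 1.2,
                           S_base = 15, S_amp = 7, S_lat_slope = 0.15,
                           cloud_mean = 0.72, cloud_sd = 0.18,
                           cloud_min = 0.15, co2 = 350) {
  cfg <- as.list(environment())
  stopifnot(cfg$co2 > 0, cfg$cloud_min > 0, abs(cfg$ar_phi) < 1)
  structure(cfg, class = "weather_config")
}

#' Scenario specification for synthetic weather
#'
#' Scenarios perturb the baseline generator to induce the damage modes the
#' simulator can express: `cool_summer` subtracts `delta_T` from Tmean
#' inside `window` (cool-summer spikelet sterility); `heat_anthesis` adds
#' `delta_T` to Tmax inside `window` (heat sterility at flowering);
#' `cold_region` subtracts `delta_T` from both Tmean and Tmax over the
#' whole season (a high-latitude season too cool to reach maturity).
#' Perturbations are applied after the stochastic draws, so a scenario
#' series differs from its seed-matched baseline by exactly the stated
#' deltas.
#'
#' @param name One of `"baseline"`, `"cool_summer"`, `"heat_anthesis"`,
#'   `"cold_region"`.
#' @param delta_T Perturbation magnitude in deg C (>= 0). Defaults depend
#'   on the scenario: 0, 4, 7, 8 respectively.
#' @param window Integer range of perturbed days as 0-based day indices
#'   from planting (both ends included). Defaults: whole season for
#'   `baseline`/`cold_region`, days 60--120 for `cool_summer` (panicle
#'   sensitivity period), days 75--110 for `heat_anthesis` (around
#'   anthesis).
#' @param noise_sd Innovation SD of the AR(1) daily temperature noise.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(name = c("baseline", "cool_summer",
                                   "heat_anthesis", "cold_region"),
                          delta_T = NULL, window = NULL, noise_sd = 1.5) {
  name <- match.arg(name)
  if (is.null(delta_T)) {
    delta_T <- switch(name, baseline = 0, cool_summer = 4,
                      heat_anthesis = 7, cold_region = 8)
  }
  if (is.null(window)) {
    window <- switch(name,
                     cool_summer = c(60L, 120L),
                     heat_anthesis = c(75L, 110L),
                     c(0L, 183L))
  }
  if (delta_T < 0) stop("delta_T must be >= 0")
  window <- as.integer(window)
  if (length(window) != 2 || window[1] > window[2] ||
      window[1] < 0 || window[2] > 183) {
    stop("window must be an increasing pair of day indices within 0..183")
  }
  structure(list(name = name, delta_T = delta_T, window = window,
                 noise_sd = noise_sd), class = "scenario_spec")
}

#' Generate one grid-cell-year of synthetic daily weather
#'
#' Produces a 184-day series (May 01 through Oct 31) of daily mean and
#' maximum temperature, daily total global solar radiation, day length,
#' and CO2 concentration, for one latitude, with seeded stochastic daily
#' variation. Identical arguments give bit-identical series. The random
#' draws do not depend on the scenario, so series generated with the same
#' seed under different scenarios differ only by the deterministic
#' scenario deltas.
#'
#' @param latitude Degrees north, `abs(latitude) < 66.5`.
#' @param year_index Integer year label (metadata only; the climatology
#'   has no trend).
#' @param scenario A [scenario_spec()].
#' @param seed Integer seed for the daily draws.
#' @param config A [weather_config()].
#' @param grid_id Identifier string (metadata).
#' @return An object of class `weather_series`: a list with `grid_id`,
#'   `year_index`, `latitude`, `scenario`, and `days`, a 184-row data
#'   frame with columns `day_index` (0-based), `date` (month-day),
#'   `Tmean`, `Tmax`, `S_incident`, `L`, `P`.
#' @export
synth_weather <- function(latitude, year_index = 1L,
                          scenario = scenario_spec("baseline"),
                          seed = 1L, config = weather_config(),
                          grid_id = "g001") {
  stopifnot(inherits(scenario, "scenario_spec"))
  n <- SEASON_DAYS
  doy <- PLANTING_DOY + seq_len(n) - 1L
  lat_d <- latitude - 35

  t_season <- (config$T_mid_ref - config$T_lapse * lat_d) +
    (config$T_amp_ref + config$T_amp_slope * lat_d) *
      cos(2 * pi * (doy - config$T_peak_doy) / 365)

  draws <- with_seed(seed, list(
    innov = rnorm(n, 0, scenario$noise_sd),
    offs = rnorm(n, 0, config$tmax_noise_sd),
    cloud = rnorm(n, config$cloud_mean, config$cloud_sd)
  ))
  e <- numeric(n)
  e[1] <- draws$innov[1] / sqrt(1 - config$ar_phi^2)
  for (t in 2:n) e[t] <- config$ar_phi * e[t - 1] + draws$innov[t]

  tmean_base <- t_season + e
  offs <- pmax(0, config$tmax_offset + draws$offs)

  in_window <- seq_len(n) - 1L >= scenario$window[1] &
    seq_len(n) - 1L <= scenario$window[2]
  d <- scenario$delta_T
  tmean <- tmean_base
  tmax <- tmean_base + offs
  if (scenario$name == "cool_summer") {
    tmean[in_window] <- tmean[in_window] - d
  } else if (scenario$name == "heat_anthesis") {
    tmax[in_window] <- tmax[in_window] + d
  } else if (scenario$name == "cold_region") {
    tmean[in_window] <- tmean[in_window] - d
    tmax[in_window] <- tmax[in_window] - d
  }

  s_clear <- pmax(1, config$S_base - config$S_lat_slope * lat_d +
                    config$S_amp * cos(2 * pi * (doy - 172) / 365))
  cloud <- pmin(1, pmax(config$cloud_min, draws$cloud))
  s_inc <- s_clear * cloud

  days <- data.frame(
    day_index = 0:(n - 1L),
    date = month_day_labels(),
    Tmean = tmean,
    Tmax = tmax,
    S_incident = s_inc,
    L = day_length(latitude, doy),
    P = rep(config$co2, n)
  )
  structure(list(grid_id = grid_id, year_index = as.integer(year_index),
                 latitude = latitude, scenario = scenario$name,
                 days = days),
            class = "weather_series")
}

#' Validate the invariants of a weather series
#'
#' Checks: exactly 184 daily records; `Tmax >= Tmean` each day;
#' `0 < L < 24`; `S_incident >= 0`; `P > 0`.
#'
#' @param ws A `weather_series`.
#' @return `ws`, invisibly; errors if an invariant fails.
#' @export
validate_weather_series <- function(ws) {
  if (!inherits(ws, "weather_series")) stop("not a weather_series")
  d <- ws$days
  if (nrow(d) != SEASON_DAYS) stop("weather series must have 184 days")
  if (!all(d$Tmax >= d$Tmean)) stop("Tmax < Tmean on some day")
  if (!all(d$L > 0 & d$L < 24)) stop("day length outside (0, 24)")
  if (!all(d$S_incident >= 0)) stop("negative incident radiation")
  if (!all(d$P > 0)) stop("non-positive CO2")
  invisible(ws)
}

#' @export
print.weather_series <- function(x, ...) {
  cat(sprintf("<weather_series> grid %s year %d, lat %.2f N, scenario %s\n",
              x$grid_id, x$year_index, x$latitude, x$scenario))
  cat(sprintf("  season mean Tmean %.1f C, mean S %.1f MJ/m2/d\n",
              mean(x$days$Tmean), mean(x$days$S_incident)))
  invisible(x)
}

#' Generate a multi-grid, multi-year collection of weather series
#'
#' Latitudes are spread evenly across `lat_range` (one per grid);
#' scenarios are assigned to grid-years by seeded weighted sampling. Each
#' grid-year gets an independent derived seed, so the collection is fully
#' reproducible and individual series can be regenerated in isolation.
#'
#' @param n_grids,n_years Positive integers.
#' @param lat_range Length-2 increasing latitude interval (degrees N).
#' @param scenario_weights Named nonnegative weights over scenario names;
#'   at least one positive. The default mixes baseline seasons with the
#'   two sterility-inducing scenarios and a small share of never-maturing
#'   cold seasons.
#' @param seed Master integer seed.
#' @param config A [weather_config()].
#' @return A list of `weather_series` of length `n_grids * n_years`, with
#'   a `meta` attribute data frame (grid_id, year_index, latitude,
#'   scenario, seed).
#' @export
synth_grid <- function(n_grids, n_years, lat_range = c(31, 43),
                       scenario_weights = c(baseline = 0.55,
                                            cool_summer = 0.2,
                                            heat_anthesis = 0.2,
                                            cold_region = 0.05),
                       seed = 1L, config = weather_config()) {
  stopifnot(n_grids >= 1, n_years >= 1)
  if (length(lat_range) != 2 || lat_range[1] > lat_range[2]) {
    stop("lat_range must be a non-empty increasing interval")
  }
  if (any(scenario_weights < 0) || sum(scenario_weights) <= 0) {
    stop("scenario_weights must be nonnegative with a positive sum")
  }
  lats <- if (n_grids == 1) mean(lat_range) else
    seq(lat_range[1], lat_range[2], length.out = n_grids)

  meta <- expand.grid(grid = seq_len(n_grids), year = seq_len(n_years))
  m <- nrow(meta)
  scen_names <- names(scenario_weights)
  assigned <- with_seed(derive_seed(seed, 0L), {
    sample(scen_names, m, replace = TRUE,
           prob = scenario_weights / sum(scenario_weights))
  })

  out <- vector("list", m)
  info <- data.frame(grid_id = sprintf("g%03d", meta$grid),
                     year_index = meta$year,
                     latitude = lats[meta$grid],
                     scenario = assigned,
                     seed = vapply(seq_len(m), function(i)
                       derive_seed(seed, i), integer(1)))
  for (i in seq_len(m)) {
    out[[i]] <- synth_weather(info$latitude[i], info$year_index[i],
                              scenario_spec(info$scenario[i]),
                              seed = info$seed[i], config = config,
                              grid_id = info$grid_id[i])
  }
  attr(out, "meta") <- info
  out
}

#' Write / read one weather series as CSV
#'
#' One file per grid-year. Metadata (grid id, year, latitude, scenario)
#' is stored in `#`-prefixed comment lines above the mandatory header
#' row; columns are `day_index, date, Tmean, Tmax, S_incident, L, P`,
#' UTF-8, `.` decimal separator.
#'
#' @param ws A `weather_series`.
#' @param path Output file path.
#' @return `path` invisibly (write); a `weather_series` (read).
#' @export
write_weather_csv <- function(ws, path) {
  validate_weather_series(ws)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# grid_id: %s", ws$grid_id),
               sprintf("# year_index: %d", ws$year_index),
               sprintf("# latitude: %.6f", ws$latitude),
               sprintf("# scenario: %s", ws$scenario)), con)
  write.csv(ws$days, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_weather_csv
#' @export
read_weather_csv <- function(path) {
  hdr <- readLines(path, n = 10L)
  meta_lines <- grep("^#", hdr, value = TRUE)
  get_meta <- function(key) {
    ln <- grep(sprintf("^# %s:", key), meta_lines, value = TRUE)
    if (length(ln) != 1) stop("missing metadata line: ", key)
    trimws(sub(sprintf("^# %s:", key), "", ln))
  }
  days <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  ws <- structure(list(grid_id = get_meta("grid_id"),
                       year_index = as.integer(get_meta("year_index")),
                       latitude = as.numeric(get_meta("latitude")),
                       scenario = get_meta("scenario"),
                       days = days),
                  class = "weather_series")
  validate_weather_series(ws)
}
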