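#' Developmental rate before heading
#'
#' Daily developmental rate (DVR) while `DVI <= 1`, driven by daily mean
#' temperature through a logistic response and, once the crop becomes
#' photoperiod sensitive (`DVI > DVI_star`), attenuated by day length:
#' \deqn{DVR = \frac{1 - \exp[B_p (L - L_c)]^{+}}
#'                  {G_v \{1 + \exp[-A (T_{mean} - T_h)]\}}}
#' where the photoperiod numerator is 1 in the insensitive phase, the
#' bracketed term when `L <= Lc`, and DVR is 0 outright when the crop is
#' sensitive and `L > Lc` (development stalls under supracritical day
#' lengths). At `Tmean = Th` the rate is half its high-temperature limit
#' `1/Gv`.
#'
#' @param Tmean Daily mean temperature (deg C).
#' @param L Day length (h).
#' @param DVI Current developmental index, in `[0, 1]`.
#' @param params A [cultivar_params()].
#' @return DVR per day, in `[0, 1/Gv]`.
#' @export
dvr_pre_heading <- function(Tmean, L, DVI, params) {
  denom <- params$Gv * (1 + exp(-params$A * (Tmean - params$Th)))
  if (DVI <= params$DVI_star) {
    1 / denom
  } else if (L <= params$Lc) {
    (1 - exp(params$Bp * (L - params$Lc))) / denom
  } else {
    0
  }
}

#' Developmental rate during grain filling
#'
#' Daily DVR for `1 < DVI <= 2`, a saturating exponential response to
#' temperature above the base `Tcr`:
#' \deqn{DVR = \max\{0, (1 - \exp[-K_r (T_{mean} - T_{cr})]) / G_r\}}
#' The floor at zero keeps development from running backwards below the
#' base temperature (the unfloored expression is negative there).
#'
#' @inheritParams dvr_pre_heading
#' @return DVR per day, in `[0, 1/Gr]`.
#' @export
dvr_grain_filling <- function(Tmean, params) {
  max(0, (1 - exp(-params$Kr * (Tmean - params$Tcr))) / params$Gr)
}

#' Canopy leaf area and absorbed radiation
#'
#' The canopy surrogate: leaf area index follows a documented DVI-driven
#' curve that rises as `LAI_max * DVI^LAI_rise` to its peak `LAI_max` at
#' `DVI = 1`, then declines linearly to `LAI_end_frac * LAI_max` at
#' maturity (`DVI = 2`). Absorption follows Beer's law,
#' \deqn{S_s = S (1 - e^{-k\,LAI}),} so `0 <= Ss <= S_incident`.
#'
#' @param S_incident Daily total incident global solar radiation
#'   (MJ m-2 d-1), >= 0.
#' @param DVI Developmental index.
#' @param params A [cultivar_params()].
#' @return A list with `LAI` (m2 m-2) and `Ss` (MJ m-2 d-1 absorbed).
#' @export
lai_and_absorption <- function(S_incident, DVI, params) {
  lai <- if (DVI <= 1) {
    params$LAI_max * max(0, DVI)^params$LAI_rise
  } else {
    params$LAI_max * (1 - (1 - params$LAI_end_frac) * (min(DVI, 2) - 1))
  }
  list(LAI = lai, Ss = S_incident * (1 - exp(-params$k_beer * lai)))
}

#' Radiation conversion efficiency
#'
#' Dry matter produced per MJ of absorbed radiation. The base efficiency
#' is constant (`C0`) through the vegetative phase and the front half of
#' grain filling, then declines toward zero:
#' \deqn{C_0^* = C_f (1 + B_f) / \{1 + B_f \exp[(DVI - 1)/t_f]\}}
#' for `1 <= DVI <= 2` (the boundary `DVI = 1` uses this branch; it is
#' continuous with `C0` when `Cf = C0`). The CO2 response multiplies it:
#' \deqn{C_s = C_0^* [1 + R_m (P - 330) / ((P - 330) + K_c)]}
#' which is exactly 1 at `P = 330` ppm and tends to `1 + Rm` as `P` grows.
#'
#' @param DVI Developmental index.
#' @param P CO2 concentration (ppm), > 0.
#' @param params A [cultivar_params()].
#' @return `Cs` in g DM per MJ, >= 0.
#' @export
conversion_efficiency <- function(DVI, P, params) {
  c0s <- if (DVI < 1) {
    params$C0
  } else {
    params$Cf * (1 + params$Bf) /
      (1 + params$Bf * exp((DVI - 1) / params$tf))
  }
  co2_factor <- 1 + params$Rm * (P - 330) / ((P - 330) + params$Kc)
  max(0, c0s * co2_factor)
}

#' Cooling degree sum over the panicle-sensitive window
#'
#' Accumulated shortfall of daily mean temperature below 22 C over days
#' whose developmental index lies in the cool-sensitivity window
#' `0.75 < DVI < 1.2`:
#' \deqn{Q_t = \sum \max(0, 22 - T_{mean})}
#' Days warmer than 22 C contribute nothing (the usual
#' cooling-degree-day clamp).
#'
#' @param Tmean_series Vector of daily mean temperatures.
#' @param dvi_by_day Vector of the same length with each day's DVI.
#' @return `Qt` in deg C days, >= 0.
#' @export
cooling_degree_sum <- function(Tmean_series, dvi_by_day) {
  if (length(Tmean_series) != length(dvi_by_day)) {
    stop("Tmean_series and dvi_by_day must have equal length")
  }
  w <- dvi_by_day > 0.75 & dvi_by_day < 1.2
  sum(pmax(0, 22 - Tmean_series[w]))
}

#' Spikelet sterility from cool-summer damage
#'
#' \deqn{\gamma_L = \mathrm{clamp}(\gamma_0 + K_q Q_t^{a}, 0, 1)}
#' Cooling accumulation increases sterility (the response is
#' nondecreasing in `Qt`); at `Qt = 0` only the baseline sterility
#' `gamma0` remains.
#'
#' @param Qt Cooling degree sum (deg C days), >= 0.
#' @param params A [cultivar_params()].
#' @return `gammaL`, a fraction in `[0, 1]`.
#' @export
sterility_cool <- function(Qt, params) {
  min(1, max(0, params$gamma0 + params$Kq * Qt^params$aq))
}

#' Spikelet sterility from heat at anthesis
#'
#' A fixed logistic in the mean daily maximum temperature over the
#' anthesis window (`0.96 < DVI <= 1.22`):
#' \deqn{\gamma_H = 1 / \{1 + \exp[-0.853 (T_H - 36.6)]\}}
#' Strictly increasing in `TH`, with midpoint 0.5 at 36.6 C.
#'
#' @param TH Mean daily maximum temperature over the anthesis window
#'   (deg C).
#' @return `gammaH` in (0, 1).
#' @export
sterility_heat <- function(TH) {
  1 / (1 + exp(-0.853 * (TH - 36.6)))
}

#' Harvest index
#'
#' \deqn{h = \max\{0,\; h_m (1 - \gamma)
#'        (1 - \exp[-K_h (DVI_{final} - 1.22)])\}}
#' Zero when sterility is total or when the season ends at or before
#' `DVI = 1.22`; approaches the cultivar maximum `hm` for a fully
#' matured, sterility-free season.
#'
#' @param final_DVI Developmental index at season end.
#' @param gamma Spikelet sterility fraction in `[0, 1]`.
#' @param params A [cultivar_params()].
#' @return `h` in `[0, hm]`.
#' @export
harvest_index <- function(final_DVI, gamma, params) {
  stopifnot(gamma >= 0, gamma <= 1)
  max(0, params$hm * (1 - gamma) * (1 - exp(-params$Kh * (final_DVI - 1.22))))
}

#' Simulate one rice season
#'
#' Deterministic daily-step loop over a 184-day weather series. Each day:
#' the developmental rate is computed from the start-of-day DVI (the
#' pre-heading response while `DVI <= 1`, the grain-filling response
#' after), DVI is advanced (capped at exactly 2.0 on the maturity day),
#' and dry matter accumulates as `Cs * Ss` from the canopy surrogate and
#' conversion efficiency evaluated at the updated DVI. Growth stops once
#' maturity is reached. Daily mean temperatures are accumulated into the
#' cooling sum `Qt` on days with `0.75 < DVI < 1.2`, and daily maxima
#' collected on days with `0.96 < DVI <= 1.22` for the heat-sterility
#' mean `TH` (if the crop never enters that window, heat sterility is
#' zero). At season end, sterility components combine as
#' `gamma = max(gammaL, gammaH)`, the harvest index follows, and yield is
#' `YG = h * Wt`. Heading is declared on the first day `DVI >= 1`,
#' maturity on the first day `DVI >= 2`. A season is flagged `excluded`
#' when DVI has not reached 2.0 by October 05 (season day 158).
#'
#' The simulator is a pure function: repeated calls on identical inputs
#' are bit-identical.
#'
#' @param weather A `weather_series` (validated on entry).
#' @param params A [cultivar_params()].
#' @return An object of class `season_result`: grain yield `YG` (g m-2),
#'   final dry matter `Wt_final` (g m-2), harvest indices `h`,
#'   `h_gammaH`, `h_gammaL` (the latter two using one sterility component
#'   alone), sterility fractions `gamma`, `gammaH`, `gammaL`, `Qt`, `TH`
#'   (NA if never in window), `final_DVI`, `dvi_by_day` (184 end-of-day
#'   values), `heading_day` and `maturity_day` (1-based season day or
#'   NA), and `excluded`.
#' @export
simulate_season <- function(weather, params) {
  validate_weather_series(weather)
  stopifnot(inherits(params, "cultivar_params"))
  d <- weather$days

  dvi <- 0
  wt <- 0
  qt <- 0
  th_sum <- 0
  th_n <- 0L
  heading <- NA_integer_
  maturity <- NA_integer_
  dvi_by_day <- numeric(SEASON_DAYS)

  for (t in seq_len(SEASON_DAYS)) {
    if (is.na(maturity)) {
      dvr <- if (dvi <= 1) {
        dvr_pre_heading(d$Tmean[t], d$L[t], dvi, params)
      } else {
        dvr_grain_filling(d$Tmean[t], params)
      }
      dvi <- min(2, dvi + dvr)
      if (is.na(heading) && dvi >= 1) heading <- t
      if (dvi >= 2) maturity <- t

      ca <- lai_and_absorption(d$S_incident[t], dvi, params)
      cs <- conversion_efficiency(dvi, d$P[t], params)
      wt <- wt + cs * ca$Ss

      if (dvi > 0.75 && dvi < 1.2) qt <- qt + max(0, 22 - d$Tmean[t])
      if (dvi > 0.96 && dvi <= 1.22) {
        th_sum <- th_sum + d$Tmax[t]
        th_n <- th_n + 1L
      }
    }
    dvi_by_day[t] <- dvi
  }

  gammaL <- sterility_cool(qt, params)
  th <- if (th_n > 0L) th_sum / th_n else NA_real_
  gammaH <- if (th_n > 0L) sterility_heat(th) else 0
  gamma <- max(gammaL, gammaH)

  h <- harvest_index(dvi, gamma, params)
  structure(list(
    YG = h * wt,
    Wt_final = wt,
    h = h,
    h_gammaH = harvest_index(dvi, gammaH, params),
    h_gammaL = harvest_index(dvi, gammaL, params),
    gamma = gamma, gammaH = gammaH, gammaL = gammaL,
    Qt = qt, TH = th,
    final_DVI = dvi,
    dvi_by_day = dvi_by_day,
    heading_day = heading, maturity_day = maturity,
    excluded = dvi_by_day[OCT05_DAY] < 2,
    grid_id = weather$grid_id, year_index = weather$year_index
  ), class = "season_result")
}

#' @export
print.season_result <- function(x, ...) {
  cat(sprintf("<season_result> grid %s year %d\n", x$grid_id, x$year_index))
  cat(sprintf("  yield %.1f g/m2 (%.2f t/ha), Wt %.1f g/m2, h %.3f\n",
              x$YG, x$YG * 0.01, x$Wt_final, x$h))
  cat(sprintf("  gamma %.3f (heat %.3f, cool %.3f), final DVI %.3f%s\n",
              x$gamma, x$gammaH, x$gammaL, x$final_DVI,
              if (x$excluded) " [excluded: immature by Oct 05]" else ""))
  invisible(x)
}

#' Simulate a batch of seasons
#'
#' Runs [simulate_season()] over a weather collection and gathers scalar
#' outputs into a data frame, with the per-day DVI trajectories in a
#' companion matrix.
#'
#' @param weather_list List of `weather_series` (e.g. from
#'   [synth_grid()]).
#' @param params A [cultivar_params()].
#' @return An object of class `season_batch`: a list with `results` (one
#'   row per grid-year: grid_id, year_index, YG, Wt_final, h, h_gammaH,
#'   h_gammaL, gamma, gammaH, gammaL, Qt, TH, final_DVI, heading_day,
#'   maturity_day, excluded) and `dvi` (184 x n matrix).
#' @export
simulate_batch <- function(weather_list, params) {
  res <- lapply(weather_list, simulate_season, params = params)
  scalars <- c("YG", "Wt_final", "h", "h_gammaH", "h_gammaL",
               "gamma", "gammaH", "gammaL", "Qt", "TH", "final_DVI")
  df <- data.frame(
    grid_id = vapply(res, `[[`, character(1), "grid_id"),
    year_index = vapply(res, `[[`, integer(1), "year_index"))
  for (s in scalars) df[[s]] <- vapply(res, `[[`, numeric(1), s)
  df$heading_day <- vapply(res, `[[`, integer(1), "heading_day")
  df$maturity_day <- vapply(res, `[[`, integer(1), "maturity_day")
  df$excluded <- vapply(res, `[[`, logical(1), "excluded")
  dvi <- vapply(res, `[[`, numeric(SEASON_DAYS), "dvi_by_day")
  structure(list(results = df, dvi = dvi), class = "season_batch")
}

#' Write a season batch as CSV
#'
#' Scalar results go to `<stem>_results.csv` (one row per grid-year) and
#' the DVI trajectories to `<stem>_dvi.csv` (184 rows, one column per
#' grid-year).
#'
#' @param batch A `season_batch`.
#' @param stem Output path stem (no extension).
#' @return The two paths, invisibly.
#' @export
write_results_csv <- function(batch, stem) {
  stopifnot(inherits(batch, "season_batch"))
  p1 <- paste0(stem, "_results.csv")
  p2 <- paste0(stem, "_dvi.csv")
  write.csv(batch$results, p1, row.names = FALSE)
  dvi <- as.data.frame(batch$dvi)
  names(dvi) <- paste(batch$results$grid_id, batch$results$year_index,
                      sep = "_y")
  write.csv(dvi, p2, row.names = FALSE)
  invisible(c(results = p1, dvi = p2))
}
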