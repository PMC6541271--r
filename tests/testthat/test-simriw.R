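p <- cultivar_params()

test_that("pre-heading developmental rate honors its analytic anchors", {
  # half the high-temperature limit at the half-rate temperature
  expect_equal(dvr_pre_heading(p$Th, 13, 0.2, p), 1 / (2 * p$Gv))
  # photoperiod-sensitive phase: zero at and above the critical day length
  expect_identical(dvr_pre_heading(25, p$Lc + 0.5, 0.9, p), 0)
  expect_equal(dvr_pre_heading(25, p$Lc, 0.9, p), 0)
  # logistic saturation toward 1/Gv
  expect_equal(dvr_pre_heading(1e3, 13, 0.2, p), 1 / p$Gv)
  # range property across regimes
  for (Tm in seq(-5, 45, by = 5)) {
    for (dvi in c(0, 0.3, 0.6, 1)) {
      for (L in c(10, 14, 17)) {
        v <- dvr_pre_heading(Tm, L, dvi, p)
        expect_true(v >= 0 && v <= 1 / p$Gv)
      }
    }
  }
})

test_that("grain-filling rate is floored, saturating, and anchored", {
  expect_identical(dvr_grain_filling(p$Tcr, p), 0)
  expect_identical(dvr_grain_filling(p$Tcr - 10, p), 0)
  expect_equal(dvr_grain_filling(1e4, p), 1 / p$Gr)
  expect_equal(dvr_grain_filling(p$Tcr + 1 / p$Kr, p),
               (1 - exp(-1)) / p$Gr)
})

test_that("canopy curve peaks at heading and absorption obeys Beer's law", {
  expect_equal(lai_and_absorption(10, 1, p)$LAI, p$LAI_max)
  expect_identical(lai_and_absorption(10, 0, p)$Ss, 0)
  # monotone rise then decline, always within [0, S]
  lais <- vapply(seq(0, 2, by = 0.1),
                 function(d) lai_and_absorption(12, d, p)$LAI, numeric(1))
  expect_true(all(diff(lais[1:11]) >= 0))
  expect_true(all(diff(lais[11:21]) <= 0))
  ss <- vapply(seq(0, 2, by = 0.1),
               function(d) lai_and_absorption(12, d, p)$Ss, numeric(1))
  expect_true(all(ss >= 0 & ss <= 12))
  # canopy closure: absorption approaches incident radiation
  p_big <- cultivar_params(LAI_max = 500)
  expect_equal(lai_and_absorption(12, 1, p_big)$Ss, 12, tolerance = 1e-12)
})

test_that("conversion efficiency responds to CO2 and grain-fill decline", {
  expect_equal(conversion_efficiency(0.5, 330, p), p$C0)
  expect_equal(conversion_efficiency(0.5, 1e12, p), p$C0 * (1 + p$Rm),
               tolerance = 1e-6)
  expect_lt(conversion_efficiency(2, 350, p),
            conversion_efficiency(1, 350, p))
  cs <- vapply(seq(1, 2, by = 0.05),
               function(d) conversion_efficiency(d, 350, p), numeric(1))
  expect_true(all(diff(cs) < 0))
})

test_that("cooling degree sum clamps warm days and windows on DVI", {
  dvi <- c(0.5, 0.8, 0.9, 1.0, 1.1, 1.3)
  expect_identical(cooling_degree_sum(rep(22, 6), dvi), 0)
  # five in-window days at 20 C contribute 2 C each
  expect_equal(cooling_degree_sum(c(10, 20, 20, 20, 20, 20),
                                  c(0.5, 0.8, 0.9, 1.0, 1.1, 1.19)), 10)
  expect_identical(cooling_degree_sum(rep(25, 6), dvi), 0)
  expect_error(cooling_degree_sum(rep(20, 5), dvi), "length")
})

test_that("sterility responses match their analytic anchors", {
  expect_equal(sterility_cool(0, p), p$gamma0)
  expect_equal(sterility_cool(1e6, p), 1)
  p01 <- cultivar_params(gamma0 = 0, Kq = 0.01, aq = 1)
  expect_equal(sterility_cool(10, p01), 0.1)
  qs <- vapply(seq(0, 100, by = 5), sterility_cool, numeric(1), params = p)
  expect_true(all(diff(qs) >= 0))

  expect_equal(sterility_heat(36.6), 0.5)
  expect_lt(sterility_heat(0), 1e-13)
  expect_equal(sterility_heat(40), 1 / (1 + exp(-0.853 * 3.4)))
  ths <- vapply(seq(20, 45, by = 1), sterility_heat, numeric(1))
  expect_true(all(diff(ths) > 0))
})

test_that("harvest index vanishes at its boundaries and caps at hm", {
  expect_identical(harvest_index(1.22, 0, p), 0)
  expect_identical(harvest_index(2, 1, p), 0)
  expect_equal(harvest_index(1e3, 0, p), p$hm)
  hs <- vapply(seq(0, 1, by = 0.1), function(g) harvest_index(2, g, p),
               numeric(1))
  expect_true(all(diff(hs) < 0))
  expect_true(all(hs >= 0 & hs <= p$hm))
})

test_that("favorable and cold seasons bracket the exclusion rule", {
  good <- simulate_season(make_test_weather(28, 32, L = 13), p)
  expect_false(good$excluded)
  expect_equal(good$final_DVI, 2)
  expect_false(is.na(good$heading_day))
  expect_lt(good$maturity_day, 158)

  cold <- simulate_season(make_test_weather(12, 16, L = 13), p)
  expect_true(cold$excluded)
  expect_lt(cold$final_DVI, 2)
  expect_true(is.na(cold$maturity_day))
})

test_that("season accounting identities hold on every run", {
  for (seed in 1:6) {
    scen <- c("baseline", "cool_summer", "heat_anthesis")[(seed %% 3) + 1]
    ws <- synth_weather(32 + seed * 2, 1, scenario_spec(scen), seed = seed)
    r <- simulate_season(ws, p)
    expect_equal(r$YG, r$h * r$Wt_final, tolerance = 1e-12)
    expect_identical(r$gamma, max(r$gammaL, r$gammaH))
    expect_true(r$h >= 0 && r$h <= p$hm)
    expect_true(all(diff(r$dvi_by_day) >= 0))
    expect_true(all(r$dvi_by_day <= 2))
  }
})

test_that("the simulator is a pure function of its inputs", {
  ws <- synth_weather(39, 1, scenario_spec("cool_summer"), seed = 5)
  expect_identical(simulate_season(ws, p), simulate_season(ws, p))
})

test_that("daily trajectories match the straight-line oracle", {
  specs <- list(
    list(lat = 33, scen = "baseline", seed = 11),
    list(lat = 36, scen = "cool_summer", seed = 12),
    list(lat = 39, scen = "heat_anthesis", seed = 13),
    list(lat = 42, scen = "cold_region", seed = 14),
    list(lat = 43, scen = "baseline", seed = 15))
  for (s in specs) {
    ws <- synth_weather(s$lat, 1, scenario_spec(s$scen), seed = s$seed)
    r <- simulate_season(ws, p)
    o <- oracle_season(ws$days, p)
    expect_equal(r$dvi_by_day, o$dvi, tolerance = 1e-9)
    expect_equal(r$Wt_final, o$wt[184], tolerance = 1e-9)
    expect_equal(r$Qt, o$qt[184], tolerance = 1e-9)
    expect_equal(r$gammaL, o$gammaL, tolerance = 1e-9)
    expect_equal(r$gammaH, o$gammaH, tolerance = 1e-9)
    expect_equal(r$YG, o$YG, tolerance = 1e-9)
    if (!is.na(r$heading_day)) expect_identical(r$heading_day, as.integer(o$heading))
  }
})

test_that("a heat wave confined to anthesis raises heat sterility and cuts yield", {
  ws <- synth_weather(34, 1, scenario_spec("baseline"), seed = 21)
  base <- simulate_season(ws, p)
  anth <- base$dvi_by_day > 0.96 & base$dvi_by_day <= 1.22
  ws_hot <- ws
  ws_hot$days$Tmax[anth] <- ws_hot$days$Tmax[anth] + 5
  hot <- simulate_season(ws_hot, p)
  expect_gt(hot$gammaH, base$gammaH)
  expect_lte(hot$YG, base$YG)
})
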