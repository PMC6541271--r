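p <- cultivar_params()

# a small kept/excluded mixture reused across tests
mini_batchset <- function(n_grids = 4, n_years = 4, seed = 31) {
  wx <- synth_grid(n_grids, n_years, seed = seed)
  list(wx = wx, batch = simulate_batch(wx, p))
}

test_that("input matrices carry the factor columns and zero padding", {
  ws <- make_test_weather(Tmean = 20, Tmax = 26, S = 15, L = 13.5, P = 350)
  r <- simulate_season(ws, p)
  im <- make_matrix(ws, r)
  expect_identical(dim(im$values), c(184L, 5L))
  expect_identical(colnames(im$values), c("L", "Tmean", "Tmax", "Ss", "P"))
  # column recovery before padding: each factor constant at its value
  pre <- seq_len(im$maturity_day)
  expect_true(all(im$values[pre, "L"] == 13.5))
  expect_true(all(im$values[pre, "Tmean"] == 20))
  expect_true(all(im$values[pre, "Tmax"] == 26))
  expect_true(all(im$values[pre, "Ss"] == 15))
  expect_true(all(im$values[pre, "P"] == 350))
  # rows strictly after maturity are all zero
  expect_lt(im$maturity_day, 184L)
  expect_true(all(im$values[(im$maturity_day + 1):184, ] == 0))

  # excluded seasons are rejected
  cold <- make_test_weather(10, 14)
  rc <- simulate_season(cold, p)
  expect_error(make_matrix(cold, rc), "excluded")
})

test_that("a season maturing on the final day has no padded rows", {
  ws <- make_test_weather(25, 30)
  r <- simulate_season(ws, p)
  r$maturity_day <- 184L   # boundary case
  im <- make_matrix(ws, r)
  expect_true(all(im$values[, "Tmean"] == 25))
})

test_that("immature seasons are excluded, boundary DVI 2.0 is kept", {
  mb <- mini_batchset()
  part <- exclude_immature(mb$batch)
  expect_setequal(c(part$kept, part$excluded), seq_along(mb$wx))
  expect_length(intersect(part$kept, part$excluded), 0)
  expect_true(all(mb$batch$results$final_DVI[part$kept] >= 2))
  expect_true(all(mb$batch$dvi[158, part$excluded] < 2))
  # boundary: exactly 2.0 at the Oct-05 index counts as kept
  fake <- mb$batch
  fake$results <- fake$results[1, , drop = FALSE]
  fake$results$excluded <- FALSE
  fake$dvi <- matrix(c(rep(1.99, 157), rep(2, 27)), ncol = 1)
  fake$results$final_DVI <- 2
  expect_identical(exclude_immature(fake)$kept, 1L)
  # empty input
  empty <- mb$batch
  empty$results <- empty$results[0, , drop = FALSE]
  empty$dvi <- empty$dvi[, 0, drop = FALSE]
  expect_identical(exclude_immature(empty),
                   list(kept = integer(0), excluded = integer(0)))
})

test_that("normalization is a train-statistics z-score with exact inverse", {
  mb <- mini_batchset(5, 5)
  part <- exclude_immature(mb$batch)
  mats <- lapply(part$kept, function(i) {
    r <- mb$batch$results[i, ]
    sr <- structure(list(YG = r$YG, dvi_by_day = mb$batch$dvi[, i],
                         maturity_day = r$maturity_day, excluded = FALSE,
                         grid_id = r$grid_id, year_index = r$year_index),
                    class = "season_result")
    make_matrix(mb$wx[[i]], sr)
  })
  st <- fit_normalizer(mats)
  normed <- lapply(mats, apply_normalizer, stats = st)
  for (cn in c("L", "Tmean", "Tmax", "Ss")) {
    cells <- unlist(lapply(normed, function(im)
      im$values[seq_len(im$maturity_day), cn]))
    expect_equal(mean(cells), 0, tolerance = 1e-6)
    expect_equal(sd(cells), 1, tolerance = 1e-6)
  }
  # constant CO2 column maps to unit magnitude, padding stays zero
  pcells <- unlist(lapply(normed, function(im)
    im$values[seq_len(im$maturity_day), "P"]))
  expect_true(all(abs(pcells - 1) < 1e-12))
  for (im in normed) {
    if (im$maturity_day < 184) {
      expect_true(all(im$values[(im$maturity_day + 1):184, ] == 0))
    }
  }
  # exact algebraic inverse
  back <- invert_normalizer(normed[[1]], st)
  expect_equal(back$values, mats[[1]]$values, tolerance = 1e-9)
})

test_that("a zero-variance non-CO2 column is rejected by name", {
  ws <- make_test_weather(20, 26, L = 13)   # constant L too
  r <- simulate_season(ws, p)
  im <- make_matrix(ws, r)
  expect_error(fit_normalizer(list(im)), "L")
})

test_that("noise injection is bounded, centered, seeded, and pad-safe", {
  ws <- make_test_weather(25, 30)
  r <- simulate_season(ws, p)
  im <- make_matrix(ws, r)
  expect_identical(add_noise(im, amplitude = 0), im)

  # accumulate many cells for the bound / mean checks
  deltas <- unlist(lapply(1:2000, function(s) {
    pert <- add_noise(im, 0.001, seed = s)
    (pert$values - im$values)[seq_len(im$maturity_day), ]
  }))
  expect_gt(length(deltas), 1e6)
  expect_lte(max(abs(deltas)), 0.001)
  expect_lt(abs(mean(deltas)), 1e-4)

  pert <- add_noise(im, 0.001, seed = 1)
  expect_identical(pert, add_noise(im, 0.001, seed = 1))
  expect_true(all(pert$values[(im$maturity_day + 1):184, ] == 0))
})

test_that("the grid-year split is sized, disjoint, exhaustive, seeded", {
  sp <- split_corpus(100, seed = 4)
  expect_length(sp$train, 75)
  expect_length(sp$validation, 25)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_setequal(c(sp$train, sp$validation), 1:100)
  expect_identical(sp, split_corpus(100, seed = 4))
  expect_false(identical(sp$train, split_corpus(100, seed = 5)$train))
  expect_error(split_corpus(100, train_fraction = 1.2), "train_fraction")
  expect_error(split_corpus(100, train_fraction = 0), "train_fraction")
})

test_that("the corpus builder ties the stages together without leakage", {
  mb <- mini_batchset(6, 6, seed = 77)
  corpus <- build_corpus(mb$wx, mb$batch, seed = 9)
  n <- length(corpus$y)
  expect_identical(dim(corpus$X), c(184L, 5L, n))
  expect_identical(n + corpus$n_excluded, length(mb$wx))
  expect_setequal(c(corpus$train, corpus$validation), seq_len(n))
  # padding survives normalization + noise
  for (i in seq_len(n)) {
    md <- corpus$maturity_day[i]
    if (md < 184) expect_true(all(corpus$X[(md + 1):184, , i] == 0))
  }
  # normalization statistics depend on the training split membership:
  # a different split seed changes them
  c2 <- build_corpus(mb$wx, mb$batch, seed = 10)
  expect_false(isTRUE(all.equal(corpus$norm_stats$center,
                                c2$norm_stats$center)))
  # determinism
  c3 <- build_corpus(mb$wx, mb$batch, seed = 9)
  expect_identical(corpus$X, c3$X)
})

test_that("an all-immature batch aborts corpus construction", {
  wx <- synth_grid(2, 2, lat_range = c(40, 43),
                   scenario_weights = c(cold_region = 1), seed = 3)
  batch <- simulate_batch(wx, p)
  expect_error(build_corpus(wx, batch), "no datasets survived exclusion")
})
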