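#' Build the 184 x 5 surrogate input matrix for one grid-year
#'
#' Columns in fixed order `L, Tmean, Tmax, Ss, P`. The `Ss` column is the
#' daily incident global solar radiation from the weather record (the
#' five columns are meteorological drivers; canopy-absorbed radiation is
#' a simulator internal). Rows strictly after the maturity day are zeroed
#' (vertical zero padding), so a season maturing on the final day has no
#' padded rows. The DVI trajectory and maturity day are carried along for
#' later saliency binning.
#'
#' @param weather A `weather_series`.
#' @param result The matching `season_result`; must not be excluded.
#' @return An object of class `input_matrix`: a list with `values`
#'   (184 x 5 matrix), `target_YG`, `dvi_by_day`, `maturity_day`,
#'   `grid_id`, `year_index`.
#' @export
make_matrix <- function(weather, result) {
  stopifnot(inherits(result, "season_result"))
  if (result$excluded) {
    stop("cannot build an input matrix from an excluded (immature) season")
  }
  d <- weather$days
  m <- cbind(L = d$L, Tmean = d$Tmean, Tmax = d$Tmax,
             Ss = d$S_incident, P = d$P)
  mat_day <- result$maturity_day
  if (!is.na(mat_day) && mat_day < SEASON_DAYS) {
    m[(mat_day + 1L):SEASON_DAYS, ] <- 0
  }
  structure(list(values = m,
                 target_YG = result$YG,
                 dvi_by_day = result$dvi_by_day,
                 maturity_day = mat_day,
                 grid_id = weather$grid_id,
                 year_index = weather$year_index),
            class = "input_matrix")
}

#' Partition simulated seasons into kept and excluded
#'
#' A season is kept when its DVI reached 2.0 by October 05 (boundary
#' value 2.0 exactly is kept). The partition is exhaustive and disjoint.
#'
#' @param batch A `season_batch` from [simulate_batch()].
#' @return A list with integer index vectors `kept` and `excluded`.
#' @export
exclude_immature <- function(batch) {
  stopifnot(inherits(batch, "season_batch"))
  excl <- batch$results$excluded
  list(kept = which(!excl), excluded = which(excl))
}

#' Fit and apply per-factor normalization
#'
#' `fit_normalizer()` computes a per-column z-score center and scale over
#' the non-padded cells of the training matrices only. A zero-variance
#' column is an error, except the constant CO2 column `P`, which falls
#' back to scale-only normalization (center 0, scale = root mean square
#' of the column), mapping the constant to 1: the column keeps its
#' information and its padding zeros, but enters the network at unit
#' magnitude like every other factor. (A raw 350 ppm column saturates
#' the first convolution and stalls training.) `apply_normalizer()`
#' standardizes a matrix and re-zeroes its padded rows, so padding stays
#' exactly zero; `invert_normalizer()` is the exact algebraic inverse on
#' the non-padded rows.
#'
#' @param matrices List of `input_matrix` (the training split).
#' @param stats A `norm_stats` object.
#' @param im An `input_matrix`.
#' @return `fit_normalizer()`: a `norm_stats` list with `center` and
#'   `scale` (named length-5 vectors). `apply_normalizer()` /
#'   `invert_normalizer()`: a transformed `input_matrix`.
#' @export
fit_normalizer <- function(matrices) {
  stopifnot(length(matrices) > 0)
  pooled <- lapply(FACTOR_COLS, function(cn) {
    unlist(lapply(matrices, function(im) {
      im$values[seq_len(im$maturity_day), cn]
    }), use.names = FALSE)
  })
  center <- vapply(pooled, mean, numeric(1))
  scale <- vapply(pooled, sd, numeric(1))
  names(center) <- names(scale) <- FACTOR_COLS
  degenerate <- scale < 1e-12
  if (any(degenerate)) {
    bad <- FACTOR_COLS[degenerate]
    if (!all(bad == "P")) {
      stop("zero-variance factor column(s): ",
           paste(setdiff(bad, "P"), collapse = ", "))
    }
    rms <- sqrt(mean(pooled[[match("P", FACTOR_COLS)]]^2))
    center["P"] <- 0
    scale["P"] <- if (rms > 1e-12) rms else 1
  }
  structure(list(center = center, scale = scale), class = "norm_stats")
}

#' @rdname fit_normalizer
#' @export
apply_normalizer <- function(im, stats) {
  stopifnot(inherits(im, "input_matrix"), inherits(stats, "norm_stats"))
  v <- sweep(sweep(im$values, 2, stats$center, "-"), 2, stats$scale, "/")
  if (im$maturity_day < SEASON_DAYS) {
    v[(im$maturity_day + 1L):SEASON_DAYS, ] <- 0
  }
  im$values <- v
  im
}

#' @rdname fit_normalizer
#' @export
invert_normalizer <- function(im, stats) {
  v <- sweep(sweep(im$values, 2, stats$scale, "*"), 2, stats$center, "+")
  if (im$maturity_day < SEASON_DAYS) {
    v[(im$maturity_day + 1L):SEASON_DAYS, ] <- 0
  }
  im$values <- v
  im
}

#' Inject uniform noise into an input matrix
#'
#' Adds an independent uniform draw in `[-amplitude, +amplitude]` to
#' every cell, then re-zeroes the padded rows so zero padding survives
#' perturbation. Seeded and deterministic.
#'
#' @param im An `input_matrix` (normally already normalized).
#' @param amplitude Noise half-width; default 0.001.
#' @param seed Integer seed.
#' @return The perturbed `input_matrix`.
#' @export
add_noise <- function(im, amplitude = 0.001, seed = 1L) {
  stopifnot(amplitude >= 0)
  if (amplitude == 0) return(im)
  v <- im$values
  v <- v + with_seed(seed, matrix(runif(length(v), -amplitude, amplitude),
                                  nrow(v), ncol(v)))
  if (im$maturity_day < SEASON_DAYS) {
    v[(im$maturity_day + 1L):SEASON_DAYS, ] <- 0
  }
  im$values <- v
  im
}

#' Random train/validation split of grid-year units
#'
#' Splits whole grid-years (a matrix is never divided) uniformly at
#' random into `round(train_fraction * n)` training units and the rest
#' for validation; disjoint and exhaustive, seeded.
#'
#' @param n Number of units (>= 4).
#' @param train_fraction Fraction for training, in (0, 1); default 0.75.
#' @param seed Integer seed.
#' @return A list with sorted integer vectors `train` and `validation`.
#' @export
split_corpus <- function(n, train_fraction = 0.75, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be strictly between 0 and 1")
  }
  stopifnot(n >= 4)
  n_train <- round(train_fraction * n)
  tr <- with_seed(seed, sort(sample.int(n, n_train)))
  list(train = tr, validation = setdiff(seq_len(n), tr))
}

#' Build the surrogate training corpus from simulated seasons
#'
#' The full dataset-preparation chain: drop immature seasons, shape each
#' kept grid-year into a padded 184 x 5 matrix, split 75/25 by grid-year,
#' fit the normalizer on the training split only, normalize everything,
#' and inject uniform noise (after normalization, per the stated
#' pipeline order) into training and validation alike.
#'
#' @param weather_list Weather collection, aligned with `batch`.
#' @param batch The matching `season_batch`.
#' @param noise Uniform noise half-width (applied post-normalization).
#' @param train_fraction Training fraction of kept grid-years.
#' @param seed Integer seed (drives split and noise).
#' @return An object of class `yield_corpus`: `X` (184 x 5 x n array of
#'   normalized, noise-injected inputs), `y` (target yields, g m-2),
#'   `dvi` (184 x n), `maturity_day`, `meta` (grid_id, year_index),
#'   `norm_stats`, `train`, `validation` (index vectors into the kept
#'   set), and `n_excluded`.
#' @export
build_corpus <- function(weather_list, batch, noise = 0.001,
                         train_fraction = 0.75, seed = 1L) {
  part <- exclude_immature(batch)
  if (length(part$kept) == 0) {
    stop("no datasets survived exclusion: every season was immature")
  }
  if (length(part$kept) < 4) {
    stop("only ", length(part$kept),
         " season(s) survived exclusion; at least 4 are needed for a split")
  }
  res_rows <- part$kept
  mats <- lapply(res_rows, function(i) {
    r <- batch$results[i, ]
    sr <- structure(list(YG = r$YG, dvi_by_day = batch$dvi[, i],
                         maturity_day = r$maturity_day,
                         excluded = r$excluded,
                         grid_id = r$grid_id, year_index = r$year_index),
                    class = "season_result")
    make_matrix(weather_list[[i]], sr)
  })
  n <- length(mats)
  sp <- split_corpus(n, train_fraction, seed = derive_seed(seed, 1L))
  stats <- fit_normalizer(mats[sp$train])
  mats <- lapply(mats, apply_normalizer, stats = stats)
  mats <- lapply(seq_len(n), function(i) {
    add_noise(mats[[i]], amplitude = noise,
              seed = derive_seed(seed, 1000L + i))
  })

  X <- array(0, dim = c(SEASON_DAYS, length(FACTOR_COLS), n),
             dimnames = list(NULL, FACTOR_COLS, NULL))
  for (i in seq_len(n)) X[, , i] <- mats[[i]]$values
  structure(list(
    X = X,
    y = vapply(mats, `[[`, numeric(1), "target_YG"),
    dvi = vapply(mats, `[[`, numeric(SEASON_DAYS), "dvi_by_day"),
    maturity_day = vapply(mats, function(im) as.integer(im$maturity_day),
                          integer(1)),
    meta = data.frame(
      grid_id = vapply(mats, `[[`, character(1), "grid_id"),
      year_index = vapply(mats, `[[`, integer(1), "year_index")),
    norm_stats = stats,
    train = sp$train, validation = sp$validation,
    n_excluded = length(part$excluded)
  ), class = "yield_corpus")
}

#' @export
print.yield_corpus <- function(x, ...) {
  cat(sprintf(
    "<yield_corpus> %d matrices (%d train / %d validation), %d excluded upstream\n",
    length(x$y), length(x$train), length(x$validation), x$n_excluded))
  cat(sprintf("  target yield: mean %.1f g/m2, sd %.1f\n",
              mean(x$y), sd(x$y)))
  invisible(x)
}
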