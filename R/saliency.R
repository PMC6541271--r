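#' Gradient of the model output with respect to its input
#'
#' Generic over surrogate types. For a `yield_cnn` the gradient is
#' computed by exact backpropagation through the network (on the raw
#' yield scale, i.e. including the internal target rescaling); for the
#' [linear_surrogate()] toy model it is the weight matrix itself.
#'
#' @param model A trained surrogate.
#' @param X Inputs: a 184 x 5 x n array (or anything
#'   [predict.yield_cnn()] accepts).
#' @param ... Method-specific arguments.
#' @return An array shaped like the input, one signed gradient map per
#'   sample.
#' @export
input_gradient <- function(model, X, ...) UseMethod("input_gradient")

#' @export
input_gradient.yield_cnn <- function(model, X, ...) {
  Xa <- as_input_array(X)
  cnn_input_grad_cpp(model$params, Xa, model$dims) * model$y_scale
}

#' Linear toy surrogate
#'
#' A minimal differentiable "model" `y = sum(w * x)` used to validate
#' the saliency machinery against exact and finite-difference gradients.
#'
#' @param weights A matrix of weights, one per input cell.
#' @return An object of class `linear_surrogate`.
#' @export
linear_surrogate <- function(weights) {
  structure(list(weights = as.matrix(weights)), class = "linear_surrogate")
}

#' @export
predict.linear_surrogate <- function(object, newdata, ...) {
  Xa <- if (is.matrix(newdata)) array(newdata, c(dim(newdata), 1)) else newdata
  apply(Xa, 3, function(m) sum(object$weights * m))
}

#' @export
input_gradient.linear_surrogate <- function(model, X, ...) {
  Xa <- if (is.matrix(X)) array(X, c(dim(X), 1)) else X
  array(rep(model$weights, dim(Xa)[3]), dim = dim(Xa))
}

#' Positive saliency maps
#'
#' The rectified input gradient of the scalar output: cells whose
#' increase raises the predicted yield. Negative gradient entries are
#' set to zero and each map is rescaled to a maximum of 1 (an
#' identically zero map stays zero). This is the simplest attribution
#' consistent with "increases the output"; alternative backprop variants
#' can be swapped behind the same contract.
#'
#' @param model A trained surrogate (any type with an [input_gradient()]
#'   method).
#' @param X Normalized inputs, one or more maps.
#' @return An array shaped like the input; entries in `[0, 1]`.
#' @export
positive_saliency <- function(model, X) {
  g <- input_gradient(model, X)
  g[g < 0] <- 0
  for (i in seq_len(dim(g)[3])) {
    mx <- max(g[, , i])
    if (mx > 0) g[, , i] <- g[, , i] / mx
  }
  g
}

#' Select the analysis case from simulated results
#'
#' `all` keeps everything; `low_h_gammaH` keeps kept grid-years whose
#' heat-only harvest index `h_gammaH` falls strictly below the given
#' percentile of the current corpus; `low_h_gammaL` analogously for the
#' cool-only index. Percentile thresholds are computed on the data at
#' hand, not imported from any external corpus.
#'
#' @param results Data frame of kept season results (must contain
#'   `h_gammaH` and `h_gammaL`).
#' @param case `"all"`, `"low_h_gammaH"`, or `"low_h_gammaL"`.
#' @param percentile Defining percentile, in (0, 100); default 10.
#' @return Integer indices into `results`.
#' @export
select_case <- function(results, case = c("all", "low_h_gammaH",
                                          "low_h_gammaL"),
                        percentile = 10) {
  case <- match.arg(case)
  stopifnot(nrow(results) > 0, percentile > 0, percentile <= 100)
  if (case == "all" || percentile == 100) return(seq_len(nrow(results)))
  col <- if (case == "low_h_gammaH") "h_gammaH" else "h_gammaL"
  thr <- quantile(results[[col]], percentile / 100, names = FALSE)
  idx <- which(results[[col]] < thr)
  if (length(idx) == 0) {
    stop(sprintf("case %s is empty at the %g th percentile", case, percentile))
  }
  idx
}

#' Sample saliency seed inputs from the training split
#'
#' Seeded sampling of `n` grid-years from a subset, without replacement
#' when the subset is large enough, otherwise with replacement.
#'
#' @param subset Integer vector of candidate indices.
#' @param n Number of samples (default 500).
#' @param seed Integer seed.
#' @return Integer vector of length `n` (empty if `n = 0`).
#' @export
sample_inputs <- function(subset, n = 500L, seed = 1L) {
  stopifnot(length(subset) > 0, n >= 0)
  if (n == 0) return(integer(0))
  with_seed(seed, {
    if (length(subset) >= n) sample(subset, n)
    else sample(subset, n, replace = TRUE)
  })
}

#' Aggregate saliency maps into per-factor DVI profiles
#'
#' Each non-padded day-row of each map is assigned the developmental
#' index its simulation had on that day, then per-factor saliency is
#' averaged within DVI bins across all rows and maps (day-rows first,
#' then binned). Padded rows never contribute.
#'
#' @param maps 184 x 5 x n array of saliency maps.
#' @param dvi 184 x n matrix of matching DVI trajectories.
#' @param maturity_day Length-n vector; rows after this day are padding.
#' @param bin_width DVI bin width over `[0, 2]`; default 0.05.
#' @param case Label stored with the profile.
#' @return A data frame of class `saliency_profile` with columns `case`,
#'   `factor`, `dvi_bin` (midpoint), `mean_saliency`, `n_obs`, plus
#'   attributes `bin_width` and `n_maps`.
#' @export
profile_by_dvi <- function(maps, dvi, maturity_day, bin_width = 0.05,
                           case = "all") {
  n <- dim(maps)[3]
  if (!is.matrix(dvi) || ncol(dvi) != n || length(maturity_day) != n) {
    stop("each saliency map must be paired with a DVI trajectory")
  }
  breaks <- seq(0, 2, by = bin_width)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    keep <- seq_len(maturity_day[i])
    bin <- findInterval(dvi[keep, i], breaks, rightmost.closed = TRUE,
                        left.open = TRUE)
    bin[bin < 1] <- 1L
    rows[[i]] <- data.frame(bin = rep(bin, times = dim(maps)[2]),
                            factor = rep(FACTOR_COLS, each = length(keep)),
                            sal = as.vector(maps[keep, , i]))
  }
  long <- do.call(rbind, rows)
  agg <- aggregate(sal ~ factor + bin, data = long,
                   FUN = function(v) c(mean = mean(v), n = length(v)))
  out <- data.frame(case = case,
                    factor = agg$factor,
                    dvi_bin = breaks[agg$bin] + bin_width / 2,
                    mean_saliency = agg$sal[, "mean"],
                    n_obs = as.integer(agg$sal[, "n"]))
  out <- out[order(out$factor, out$dvi_bin), ]
  rownames(out) <- NULL
  attr(out, "bin_width") <- bin_width
  attr(out, "n_maps") <- n
  class(out) <- c("saliency_profile", "data.frame")
  out
}

#' Plot saliency-vs-DVI profiles
#'
#' One panel per meteorological factor, mean saliency against the DVI
#' bin midpoint; multiple cases are overlaid when the profile data frame
#' holds more than one.
#'
#' @param x A `saliency_profile` (or several rbind-ed together).
#' @param ... Unused.
#' @export
plot.saliency_profile <- function(x, ...) {
  cases <- unique(x$case)
  cols <- grDevices::hcl.colors(max(3, length(cases)), "Dark 3")
  op <- graphics::par(mfrow = c(1, length(FACTOR_COLS)),
                      mar = c(4, 3, 2, 0.5))
  on.exit(graphics::par(op))
  for (f in FACTOR_COLS) {
    sub <- x[x$factor == f, ]
    graphics::plot(NA, xlim = c(0, 2), ylim = range(0, sub$mean_saliency),
                   xlab = "DVI", ylab = "", main = f)
    for (j in seq_along(cases)) {
      s <- sub[sub$case == cases[j], ]
      graphics::lines(s$dvi_bin, s$mean_saliency, col = cols[j], lwd = 1.5)
    }
    if (f == FACTOR_COLS[1]) {
      graphics::legend("topleft", legend = cases, col = cols[seq_along(cases)],
                       lwd = 1.5, bty = "n", cex = 0.8)
    }
  }
  invisible(x)
}

#' Permutation test for a saliency contrast across a DVI window
#'
#' For each map, the mean saliency of one factor over day-rows whose DVI
#' lies inside `window` is compared with the mean over non-padded rows
#' outside it; the per-map paired differences are tested against zero
#' with a seeded sign-flip permutation test. Maps with no rows inside
#' the window are dropped.
#'
#' @param maps 184 x 5 x n saliency array.
#' @param dvi 184 x n DVI matrix.
#' @param maturity_day Length-n padding boundary.
#' @param factor One of `L, Tmean, Tmax, Ss, P`.
#' @param window Length-2 DVI interval (open on the left, closed on the
#'   right).
#' @param n_perm Number of sign-flip permutations.
#' @param seed Integer seed.
#' @return A list with `statistic` (mean inside-minus-outside
#'   difference), `p_value` (two-sided), and `n_maps` used.
#' @export
saliency_window_test <- function(maps, dvi, maturity_day, factor,
                                 window, n_perm = 999L, seed = 1L) {
  stopifnot(factor %in% FACTOR_COLS, length(window) == 2)
  fcol <- match(factor, FACTOR_COLS)
  n <- dim(maps)[3]
  diffs <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    keep <- seq_len(maturity_day[i])
    dv <- dvi[keep, i]
    inside <- dv > window[1] & dv <= window[2]
    if (!any(inside) || all(inside)) next
    diffs[i] <- mean(maps[keep[inside], fcol, i]) -
      mean(maps[keep[!inside], fcol, i])
  }
  diffs <- diffs[is.finite(diffs)]
  if (length(diffs) < 2) stop("too few maps intersect the DVI window")
  obs <- mean(diffs)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      mean(diffs * sample(c(-1, 1), length(diffs), replace = TRUE))
    }, numeric(1))
  })
  p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  list(statistic = obs, p_value = p, n_maps = length(diffs))
}

#' Write saliency profiles as tidy CSV
#' @param profile A `saliency_profile` (or rbind of several).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
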