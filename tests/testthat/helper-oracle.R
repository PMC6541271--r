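# Independent reference implementations used as oracles. These are
# deliberately written as straight-line code, separate from the package
# internals, and must not call package functions for the quantity they
# check.

# Daylight duration, coded independently from the same standard
# declination / hour-angle construction.
oracle_day_length <- function(lat_deg, doy) {
  decl_deg <- -23.44 * cos(2 * pi * (doy + 10) / 365)
  phi <- lat_deg * pi / 180
  delta <- decl_deg * pi / 180
  x <- -tan(phi) * tan(delta)
  x <- min(1, max(-1, x))
  2 * (acos(x) * 180 / pi) / 15
}

# Straight-line season loop returning the full daily state trajectory.
oracle_season <- function(days, p) {
  n <- nrow(days)
  dvi <- 0; wt <- 0; qt <- 0; th_sum <- 0; th_n <- 0
  dvi_tr <- numeric(n); wt_tr <- numeric(n); qt_tr <- numeric(n)
  heading <- NA; maturity <- NA
  for (t in 1:n) {
    if (is.na(maturity)) {
      Tm <- days$Tmean[t]; L <- days$L[t]
      if (dvi <= 1) {
        den <- p$Gv * (1 + exp(-p$A * (Tm - p$Th)))
        dvr <- if (dvi <= p$DVI_star) 1 / den
               else if (L <= p$Lc) (1 - exp(p$Bp * (L - p$Lc))) / den
               else 0
      } else {
        dvr <- max(0, (1 - exp(-p$Kr * (Tm - p$Tcr))) / p$Gr)
      }
      dvi <- min(2, dvi + dvr)
      if (is.na(heading) && dvi >= 1) heading <- t
      if (dvi >= 2) maturity <- t
      lai <- if (dvi <= 1) p$LAI_max * max(0, dvi)^p$LAI_rise
             else p$LAI_max * (1 - (1 - p$LAI_end_frac) * (min(dvi, 2) - 1))
      ss <- days$S_incident[t] * (1 - exp(-p$k_beer * lai))
      c0s <- if (dvi < 1) p$C0
             else p$Cf * (1 + p$Bf) / (1 + p$Bf * exp((dvi - 1) / p$tf))
      cs <- max(0, c0s * (1 + p$Rm * (days$P[t] - 330) /
                            ((days$P[t] - 330) + p$Kc)))
      wt <- wt + cs * ss
      if (dvi > 0.75 && dvi < 1.2) qt <- qt + max(0, 22 - Tm)
      if (dvi > 0.96 && dvi <= 1.22) { th_sum <- th_sum + days$Tmax[t]; th_n <- th_n + 1 }
    }
    dvi_tr[t] <- dvi; wt_tr[t] <- wt; qt_tr[t] <- qt
  }
  gl <- min(1, max(0, p$gamma0 + p$Kq * qt^p$aq))
  gh <- if (th_n > 0) 1 / (1 + exp(-0.853 * (th_sum / th_n - 36.6))) else 0
  g <- max(gl, gh)
  h <- max(0, p$hm * (1 - g) * (1 - exp(-p$Kh * (dvi - 1.22))))
  list(dvi = dvi_tr, wt = wt_tr, qt = qt_tr,
       gammaL = gl, gammaH = gh, gamma = g, h = h, YG = h * wt,
       heading = heading, maturity = maturity)
}

# Double-precision forward pass of the surrogate network, written with
# explicit convolution loops (no im2col), for checking the compiled
# engine on small geometries.
oracle_cnn_forward <- function(params, dims, x) {
  K <- dims$K; P <- dims$P
  conv <- function(A, W, b) {
    # A: H x W x Cin array; W: (Cin*K*K) x Cout; column index layout
    # c*K*K + kw*K + kh + 1
    Hh <- dim(A)[1]; Ww <- dim(A)[2]; Cin <- dim(A)[3]
    Ho <- Hh + 2 * P - K + 1; Wo <- Ww + 2 * P - K + 1
    Cout <- ncol(W)
    out <- array(0, c(Ho, Wo, Cout))
    for (co in 1:Cout) {
      for (oh in 1:Ho) for (ow in 1:Wo) {
        acc <- b[co]
        for (ci in 1:Cin) for (kh in 0:(K - 1)) for (kw in 0:(K - 1)) {
          ih <- oh - P + kh; iw <- ow - P + kw
          if (ih >= 1 && ih <= Hh && iw >= 1 && iw <= Ww) {
            wrow <- (ci - 1) * K * K + kw * K + kh + 1
            acc <- acc + A[ih, iw, ci] * W[wrow, co]
          }
        }
        out[oh, ow, co] <- acc
      }
    }
    pmax(out, 0)
  }
  a1 <- conv(array(x, c(dim(x), 1)), params$W1, params$b1)
  a2 <- conv(a1, params$W2, params$b2)
  # flatten position-major within channel: p = h + Ho*(w-1), then channel
  z <- as.vector(apply(a2, 3, function(m) as.vector(m)))
  hidden <- pmax(as.vector(t(params$Wd) %*% z + params$bd), 0)
  sum(hidden * params$Wo) + params$bo
}

# Compact constructors for controlled weather fixtures.
make_test_weather <- function(Tmean, Tmax = Tmean + 5, S = 15, L = 13,
                              P = 350, grid_id = "t001", year_index = 1L,
                              latitude = 36) {
  rep184 <- function(x) if (length(x) == 1) rep(x, 184) else x
  days <- data.frame(day_index = 0:183,
                     date = sprintf("d%03d", 0:183),
                     Tmean = rep184(Tmean), Tmax = rep184(Tmax),
                     S_incident = rep184(S), L = rep184(L), P = rep184(P))
  structure(list(grid_id = grid_id, year_index = year_index,
                 latitude = latitude, scenario = "fixture", days = days),
            class = "weather_series")
}
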