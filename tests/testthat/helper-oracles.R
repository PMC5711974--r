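# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# quadratic least squares via explicit normal equations
normal_eq_quadratic <- function(t, y) {
  X <- cbind(1, t, t^2)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# grid-search minimiser of the Q10 model SSE over an (f10, q10) lattice
grid_search_q10 <- function(rs, tc, f10_grid, q10_grid) {
  best <- c(NA, NA); best_sse <- Inf
  for (q in q10_grid) {
    x <- q^((tc - 10) / 10)
    a <- sum(x^2); b <- sum(rs * x); cc <- sum(rs^2)
    sse <- cc - 2 * f10_grid * b + f10_grid^2 * a
    i <- which.min(sse)
    if (sse[i] < best_sse) {
      best_sse <- sse[i]
      best <- c(f10_grid[i], q)
    }
  }
  list(f10 = best[1], q10 = best[2], sse = best_sse)
}

# fine-grid (1-minute) numerical integration of the Q10 model over an
# analytic annual sinusoid temperature course
integrate_q10_sinusoid <- function(f10, q10, mean_c, amp_c, days = 365,
                                   step_s = 60) {
  tt <- seq(0, days * 86400 - step_s, by = step_s)
  doy <- tt / 86400
  temp <- mean_c + amp_c * cos(2 * pi * (doy - 196) / 365)
  rs <- f10 * q10^((temp - 10) / 10)
  sum(rs * step_s) * 12.011e-6 * 0.01  # t C ha-1
}

# the same analytic sinusoid sampled at 3-h resolution as a series
sinusoid_series <- function(mean_c, amp_c, days = 365) {
  t0 <- as.POSIXct("2014-01-01 00:00:00", tz = "UTC")
  dt <- t0 + seq(0, by = 3 * 3600, length.out = days * 8)
  doy <- as.numeric(difftime(dt, t0, units = "days"))
  data.frame(datetime = dt,
             soil_temp_c = mean_c + amp_c * cos(2 * pi * (doy - 196) / 365))
}
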