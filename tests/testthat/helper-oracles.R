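# Independent oracles used across tests.

# Numerical integration of dS/dt = P(t) - k S with an external solver,
# independent of the package's closed-form updates. `production` may be a
# constant or a step function of time.
ode_stock_oracle <- function(production, k, times, S0 = 0) {
  pfun <- if (is.function(production)) production else function(t) production
  deriv <- function(t, y, parms) list(pfun(t) - k * y)
  out <- deSolve::lsoda(c(S = S0), times = times, func = deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  as.numeric(out[, "S"])
}

# Textbook OLS slope/intercept from raw sums (independent of stats::lm)
hand_ols <- function(x, y) {
  n <- length(x)
  slope <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

# Plan-area fraction of a conical basin above depth z, from the geometry of
# similar triangles: the basin cross-section at depth z is a disk of radius
# r(z) = R (1 - z/D), so the area deeper than z is (1 - z/D)^2 of the total.
cone_fraction_oracle <- function(z, max_depth) {
  1 - (1 - pmin(z, max_depth) / max_depth)^2
}
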