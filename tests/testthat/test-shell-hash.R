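test_that("equilibrium stock is P/k and matches long-horizon integration", {
  expect_equal(equilibrium_stock(0, shell_params(0.3)), 0)
  expect_equal(equilibrium_stock(1, shell_params(0.05)), 20)
  expect_equal(equilibrium_stock(1, shell_params(2)), 0.5)
  # independent check: integrate the ODE far past its slowest time scale
  for (k in c(0.05, 0.3, 2)) {
    s_long <- ode_stock_oracle(1, k, times = c(0, 500))[2]
    expect_equal(equilibrium_stock(1, shell_params(k)), s_long, tolerance = 1e-6)
  }
})

test_that("parameter and domain errors are caught", {
  expect_error(shell_params(0), "positive")
  expect_error(shell_params(-0.05), "positive")
  expect_error(stock_at_time(1, shell_params(1), t = -1), "non-negative")
  expect_error(equilibrium_stock(-1, shell_params(1)), "non-negative")
  expect_error(production_series(numeric(0), numeric(0)), "non-empty")
  expect_error(production_series(c(1, 1), c(1, 1)), "strictly increasing")
  expect_error(production_series(1:2, c(1, -1)), "non-negative")
  expect_error(time_to_fraction(shell_params(1), 1), "between 0 and 1")
  expect_error(time_to_fraction(shell_params(1), 0), "between 0 and 1")
})

test_that("closed-form stock matches the initial condition, asymptote and oracle", {
  p <- shell_params(0.05)
  expect_equal(stock_at_time(1, p, t = 0, S0 = 3), 3)
  expect_equal(stock_at_time(1, shell_params(2), t = 1e3), 0.5)
  expect_equal(stock_at_time(1, p, t = 10), 20 * (1 - exp(-0.5)))
  expect_equal(stock_at_time(1, p, t = 10), 7.8694, tolerance = 1e-4)
  tt <- seq(0, 100, by = 0.5)
  for (k in c(0.05, 0.3, 2)) {
    num <- ode_stock_oracle(1, k, times = tt, S0 = 0.2)
    cf <- stock_at_time(1, shell_params(k), t = tt, S0 = 0.2)
    expect_lt(max(abs(cf - num) / pmax(num, 1e-12)), 1e-3)
  }
})

test_that("simulated trajectories asymptote, decay and ignore reporting resolution", {
  # constant forcing: within 1% of the 0.5 asymptote by year 3 (ln(100)/2 ~ 2.3)
  traj <- simulate_stock(production_series(1:10, rep(1, 10)), shell_params(2))
  at3 <- traj$stock[traj$time >= 4][1]   # stock after 3 full years of forcing
  expect_lt(abs(at3 - 0.5) / 0.5, 0.01)
  expect_true(all(diff(traj$stock) >= 0))
  # unforced decay from S0 = 1 is exp(-2t)
  dec <- simulate_stock(production_series(0:5, rep(0, 6)), shell_params(2), S0 = 1)
  expect_equal(dec$stock, exp(-2 * (1:6)), tolerance = 1e-12)
  # identical piecewise-constant forcing on coarser marks gives identical stock
  fine <- simulate_stock(production_series(1:10, rep(1, 10)), shell_params(0.3))
  coarse <- simulate_stock(production_series(seq(1, 9, 2), rep(1, 5)), shell_params(0.3))
  expect_equal(coarse$stock[5], fine$stock[10], tolerance = 1e-12)
})

test_that("time to a fraction of equilibrium matches root-finding on the integrated ODE", {
  expect_equal(time_to_fraction(shell_params(2), 0.95), log(20) / 2)
  expect_equal(time_to_fraction(shell_params(0.05), 0.95), 59.915, tolerance = 1e-4)
  expect_lt(time_to_fraction(shell_params(2), 1e-9), 1e-6)
  for (k in c(0.3, 2)) {
    eq <- 1 / k
    hit <- uniroot(function(t) {
      ode_stock_oracle(1, k, times = c(0, t))[2] - 0.95 * eq
    }, c(1e-6, 200), tol = 1e-10)$root
    expect_equal(time_to_fraction(shell_params(k), 0.95), hit, tolerance = 1e-6)
  }
})

test_that("equilibrium and approach-time respond monotonically to k and frac", {
  ks <- c(0.05, 0.1, 0.3, 1, 2)
  eq <- sapply(ks, function(k) equilibrium_stock(1, shell_params(k)))
  expect_true(all(diff(eq) < 0))
  t95 <- sapply(ks, function(k) time_to_fraction(shell_params(k), 0.95))
  expect_true(all(diff(t95) < 0))
  fr <- seq(0.1, 0.9, 0.2)
  tf <- time_to_fraction(shell_params(0.3), fr)
  expect_true(all(diff(tf) > 0))
  # equilibrium ratio to annual production is 1/k; linear in P through origin
  for (k in ks) {
    p <- shell_params(k)
    expect_equal(equilibrium_stock(1, p) / 1, 1 / k)
    expect_equal(equilibrium_stock(c(0, 1, 2, 5), p), c(0, 1, 2, 5) / k)
  }
})

test_that("long-run mass balance holds under variable forcing", {
  series <- generate_trajectory(trajectory_params(n_years = 2000, seed = 11))
  for (k in c(0.05, 0.3, 2)) {
    traj <- simulate_stock(series, shell_params(k))
    expect_equal(mean(traj$stock_mean) * k, mean(traj$production), tolerance = 0.01)
  }
})

test_that("production-stock coupling contrasts fast and slow dissolution", {
  series <- generate_trajectory(hudson_trajectory(n_years = 150, seed = 5))
  fast <- production_stock_coupling(series, shell_params(2))
  slow <- production_stock_coupling(series, shell_params(0.05))
  expect_false(fast$undefined)
  expect_gt(fast$r, 0.95)
  expect_lt(abs(slow$r), 0.5)
  # stock varies far less, in relative terms, than its forcing when k is small
  cv <- function(x) sd(x) / mean(x)
  expect_lt(cv(slow$points$stock), cv(slow$points$production) / 3)
  # constant production: correlation undefined and flagged
  const <- production_stock_coupling(production_series(1:40, rep(1, 40)),
                                     shell_params(0.3))
  expect_true(const$undefined)
  expect_true(is.na(const$r))
  # too-short records are refused rather than silently extrapolated
  expect_error(
    production_stock_coupling(generate_trajectory(trajectory_params(12, seed = 1)),
                              shell_params(0.05)),
    "burn-in")
})
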