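test_that("within-system curves are linear through the origin with the type slope", {
  expect_equal(within_system_curve(ecosystem_type(0), c(0, 3, 7))$impact, c(0, 0, 0))
  cv <- within_system_curve(ecosystem_type(2), c(0, 1, 2))
  expect_equal(cv$impact, c(0, 2, 4))
  expect_equal(curve_kind(cv), "within_system")
  # three types give three distinct lines over a common grid
  slopes <- c(3, 1, 0.2)
  grids <- lapply(slopes, function(s) within_system_curve(ecosystem_type(s), 1:5))
  for (j in 1:3) expect_equal(grids[[j]]$impact, slopes[j] * (1:5))
})

test_that("OLS fitting recovers exact lines and matches a hand computation", {
  exact <- fit_linear(within_system_curve(ecosystem_type(3), 0:4))
  expect_equal(exact$slope, 3, tolerance = 1e-12)
  expect_equal(exact$intercept, 0, tolerance = 1e-12)
  expect_equal(exact$r_squared, 1)
  # adversarial construction: high-slope lakes seen at low abundance,
  # low-slope lakes at high abundance -> pooled slope negative although
  # every within-system slope is positive
  x <- c(1, 2, 8, 10)
  y <- c(3 * 1, 3 * 2, 0.2 * 8, 0.2 * 10)
  adv <- fit_linear(abundance_impact_curve(x, y, kind = "snapshot"))
  oracle <- hand_ols(x, y)
  expect_equal(adv$slope, oracle$slope, tolerance = 1e-12)
  expect_equal(adv$intercept, oracle$intercept, tolerance = 1e-12)
  expect_lt(adv$slope, 0)
  expect_error(fit_linear(abundance_impact_curve(c(2, 2), c(1, 3), "snapshot")),
               "distinct abundances")
})

test_that("pooled slope of a mixture of origin-through lines stays within the slope range", {
  preset <- design_presets()[["equal-even"]]
  snap <- snapshot_sample(preset$landscape, seed = 1, abundances = preset$abundances)
  pooled <- fit_linear(snap)
  slopes <- vapply(preset$landscape$types, `[[`, numeric(1), "slope")
  expect_gt(pooled$slope, min(slopes))
  expect_lt(pooled$slope, max(slopes))
})

test_that("snapshot sampling is seed-deterministic and honours the landscape", {
  ls <- design_presets()[["equal-uneven"]]$landscape
  a <- snapshot_sample(ls, seed = 42)
  b <- snapshot_sample(ls, seed = 42)
  expect_identical(a$abundance, b$abundance)
  expect_identical(a$impact, b$impact)
  c <- snapshot_sample(ls, seed = 43)
  expect_false(identical(a$abundance, c$abundance))
  expect_equal(curve_kind(a), "snapshot")
  expect_equal(as.vector(table(a$type)[c("high-slope", "low-slope", "moderate-slope")]),
               c(10, 10, 10))
})

test_that("a single-type linear landscape is recovered exactly by every design", {
  ls <- landscape(list(ecosystem_type(2, "only")), 1, n_lakes = 12,
                  trajectory = trajectory_params(n_years = 20, mean_level = 3))
  snap_fit <- fit_linear(snapshot_sample(ls, seed = 9))
  expect_equal(snap_fit$slope, 2, tolerance = 1e-9)
  expect_equal(snap_fit$intercept, 0, tolerance = 1e-9)
  lt_fit <- fit_linear(long_term_sample(ls, seed = 9))
  expect_equal(lt_fit$slope, 2, tolerance = 1e-9)
  cmp <- compare_designs(ls, seed = 9)
  expect_equal(unname(cmp$within_slopes), 2)
  expect_equal(cmp$snapshot_fit$slope, 2, tolerance = 1e-9)
  expect_equal(cmp$long_term_fit$slope, 2, tolerance = 1e-9)
  expect_true(all(cmp$discrepancy$sign_agreement))
})

test_that("long-term means sit on the line for linear responses and show the Jensen gap otherwise", {
  lin <- landscape(list(ecosystem_type(1.5)), 1, n_lakes = 8,
                   trajectory = trajectory_params(n_years = 30, mean_level = 2))
  lt <- long_term_sample(lin, seed = 3)
  expect_equal(lt$impact, 1.5 * lt$abundance, tolerance = 1e-12)
  # convex response I = N^2: mean impact exceeds the response at mean abundance
  convex <- landscape(list(ecosystem_type(1, response = function(n) n^2)), 1,
                      n_lakes = 10,
                      trajectory = trajectory_params(n_years = 30, mean_level = 2,
                                                     log_sd = 0.5))
  ltc <- long_term_sample(convex, seed = 3)
  expect_true(all(ltc$impact > ltc$abundance^2))
  # concave response reverses the direction
  concave <- landscape(list(ecosystem_type(1, response = sqrt)), 1, n_lakes = 10,
                       trajectory = trajectory_params(n_years = 30, mean_level = 2,
                                                      log_sd = 0.5))
  ltv <- long_term_sample(concave, seed = 3)
  expect_true(all(ltv$impact < sqrt(ltv$abundance)))
})

test_that("average and marginal per-capita effects diverge off the origin line", {
  lin <- within_system_curve(ecosystem_type(2.5), seq(0, 10, 0.5))
  pc <- per_capita_effects(lin, 4)
  expect_equal(pc$average, 2.5, tolerance = 1e-9)
  expect_equal(pc$marginal, 2.5, tolerance = 1e-9)
  # quadratic: average N, marginal 2N (calculus vs finite difference)
  n <- seq(0, 4, 0.01)
  sq <- abundance_impact_curve(n, n^2, kind = "within_system")
  pc2 <- per_capita_effects(sq, 2)
  expect_equal(pc2$average, 2, tolerance = 1e-3)
  expect_equal(pc2$marginal, 4, tolerance = 1e-2)
  # saturating curve: marginal < average at high abundance
  sat <- abundance_impact_curve(n, n / (1 + n), kind = "within_system")
  pc3 <- per_capita_effects(sat, 3.5)
  expect_lt(pc3$marginal, pc3$average)
  # abundance zero: average undefined and flagged
  pc0 <- per_capita_effects(sq, 0)
  expect_false(pc0$average_defined)
  expect_true(is.na(pc0$average))
  expect_error(per_capita_effects(sq, 99), "observed range")
})

test_that("design comparison flags sign reversal and converges for stable abundances", {
  # adversarial layout through the full pipeline: fixed abundances place
  # high-slope lakes low and low-slope lakes high
  ls <- landscape(list(ecosystem_type(3, "high"), ecosystem_type(0.2, "low")),
                  c(0.5, 0.5), n_lakes = 4,
                  trajectory = trajectory_params(n_years = 10, mean_level = 5))
  cmp <- compare_designs(ls, seed = 1, abundances = c(1, 2, 8, 10))
  expect_lt(cmp$snapshot_fit$slope, 0)
  expect_true(all(cmp$within_slopes > 0))
  snap_rows <- cmp$discrepancy[cmp$discrepancy$design == "snapshot", ]
  expect_false(any(snap_rows$sign_agreement))
  # nearly stable abundances: each lake's snapshot point nearly coincides
  # with its long-term mean, so the two curves are near-duplicates
  stable <- landscape(list(ecosystem_type(3, "high"), ecosystem_type(1, "mod")),
                      c(0.5, 0.5), n_lakes = 20,
                      trajectory = trajectory_params(n_years = 25, mean_level = 4,
                                                     log_sd = 0.02))
  snap <- snapshot_sample(stable, seed = 2)
  lt <- long_term_sample(stable, seed = 2)
  expect_lt(max(abs(snap$abundance - lt$abundance) / lt$abundance), 0.1)
  expect_lt(max(abs(snap$impact - lt$impact) / lt$impact), 0.1)
})
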