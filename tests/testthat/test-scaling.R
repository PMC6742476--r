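test_that("complete_shape_table fills geometry without touching given values", {
  tab <- complete_shape_table(tiny_shape_table())
  expect_equal(tab$surface_um2[1], 4 * pi)
  expect_equal(tab$volume_um3[1], pi - pi / 12)
  expect_equal(tab$eta[1], 4)
  # rows with S, V given keep them; eta comes from inverting the prefactor
  expect_equal(tab$surface_um2[3], 10)
  expect_equal(tab$volume_um3[3], 2)
  expect_equal(tab$eta[3], eta_from_gamma_rod(10 / 2^(2 / 3)))
  # empty tables pass through
  expect_equal(nrow(complete_shape_table(tiny_shape_table()[0, ])), 0L)
})

test_that("shape-table validation addresses the offending row", {
  bad <- tiny_shape_table()
  bad$surface_um2[3] <- NA
  expect_error(complete_shape_table(bad), "row 3")
  bad2 <- tiny_shape_table()
  bad2$width_um[2] <- -1
  expect_error(complete_shape_table(bad2), "width_um.*row 2")
})

test_that("spheroid rows are completed with the spheroid formulas", {
  tab <- data.frame(
    condition = "coccoid", length_um = 1.38, width_um = 1,
    geometry = "spheroid"
  )
  out <- complete_shape_table(tab)
  expect_equal(out$surface_um2, spheroid_surface(0.5, 0.69))
  expect_equal(out$volume_um3, spheroid_volume(0.5, 0.69))
  expect_equal(out$eta, 1.38)
})

test_that("power-law fit is exact on noiseless data and recovers noisy parameters", {
  noiseless <- make_population_table(n = 50, sigma_log = 0, seed = 11)
  f <- fit_power_law(noiseless)
  expect_equal(f$gamma, 6.24, tolerance = 1e-10)
  expect_equal(f$exponent, 2 / 3, tolerance = 1e-10)
  expect_lt(f$gamma_se, 1e-8)
  expect_lt(f$exponent_se, 1e-8)
  ff <- fit_power_law(noiseless, exponent = "fixed")
  expect_equal(ff$gamma, f$gamma, tolerance = 1e-9)
  expect_identical(ff$exponent, 2 / 3)
  expect_identical(ff$exponent_se, 0)

  noisy <- make_population_table(n = 1000, sigma_log = 0.05, seed = 12)
  g <- fit_power_law(noisy)
  expect_gt(g$exponent, 0.66)
  expect_lt(g$exponent, 0.68)
  expect_rel(g$gamma, 6.24, 0.02)
})

test_that("degenerate designs are rejected", {
  two <- data.frame(
    condition = "x", length_um = c(4, 4), width_um = c(1, 1),
    geometry = "rod"
  )
  expect_error(fit_power_law(two), "at least 3")
  same_v <- data.frame(
    condition = "x", length_um = rep(4, 5), width_um = rep(1, 5),
    geometry = "rod"
  )
  expect_error(fit_power_law(same_v), "degenerate")
})

test_that("fit is invariant to row order and scales correctly with units", {
  tab <- make_population_table(n = 200, seed = 13)
  f1 <- fit_power_law(tab)
  f2 <- fit_power_law(tab[sample(nrow(tab)), ])
  expect_equal(f1$gamma, f2$gamma)
  expect_equal(f1$exponent, f2$exponent)
  # multiplying all lengths by s: S, V scale as s^2, s^3; the exponent is
  # unchanged in both modes, and gamma (dimensionless) is unchanged when
  # the exponent is pinned at the geometric 2/3
  s <- 2.5
  scaled <- data.frame(
    condition = tab$condition,
    length_um = tab$length_um * s, width_um = tab$width_um * s,
    geometry = "rod"
  )
  ctab <- complete_shape_table(scaled)
  orig <- complete_shape_table(tab)
  expect_equal(ctab$surface_um2, orig$surface_um2 * s^2, tolerance = 1e-9)
  expect_equal(ctab$volume_um3, orig$volume_um3 * s^3, tolerance = 1e-9)
  f3 <- fit_power_law(scaled)
  expect_equal(f3$exponent, f1$exponent, tolerance = 1e-6)
  expect_equal(
    fit_power_law(scaled, "fixed")$gamma,
    fit_power_law(tab, "fixed")$gamma,
    tolerance = 1e-9
  )
})

test_that("sv_fit methods behave like a model object", {
  tab <- make_population_table(n = 300, seed = 14)
  f <- fit_power_law(tab)
  expect_named(coef(f), c("gamma", "exponent"))
  expect_equal(
    predict(f, data.frame(volume_um3 = 2)),
    f$gamma * 2^f$exponent
  )
  expect_length(residuals(f), f$n)
  expect_equal(mean(residuals(f)), 0, tolerance = 1e-10)
  s <- summary(f)
  expect_s3_class(s, "summary.sv_fit")
  expect_equal(s$implied_eta, eta_from_gamma_rod(f$gamma))
  sim <- simulate(f, nsim = 2, seed = 1)
  expect_length(sim, 2)
  expect_equal(nrow(sim[[1]]), f$n)
  expect_output(print(f), "gamma")
})

test_that("growth law fit recovers generating parameters", {
  set.seed(21)
  kap <- runif(50, 0.2, 2)
  V <- 1 * exp(1 * kap) * exp(rnorm(50, 0, 0.03))
  gl <- fit_growth_law(kap, V)
  expect_rel(gl$V0, 1, 0.05)
  expect_rel(gl$alpha, 1, 0.05)
  # two exact points interpolate exactly
  gl2 <- fit_growth_law(c(0.5, 1.5), 2 * exp(0.8 * c(0.5, 1.5)))
  expect_equal(gl2$V0, 2, tolerance = 1e-10)
  expect_equal(gl2$alpha, 0.8, tolerance = 1e-10)
  # constant volume: alpha = 0
  gl3 <- fit_growth_law(c(0.5, 1, 1.5), rep(2, 3))
  expect_equal(gl3$alpha, 0, tolerance = 1e-12)
  expect_error(fit_growth_law(c(1, 1), c(1, 2)), "distinct")
})

test_that("S/V prediction matches the growth law algebraically", {
  params <- list(V0 = 0.8, alpha = 1.2)
  expect_equal(sv_ratio_prediction(0, params), 2 * pi * 0.8^(-1 / 3))
  kap <- seq(0, 2, by = 0.25)
  V <- params$V0 * exp(params$alpha * kap)
  expect_equal(sv_ratio_prediction(kap, params), 2 * pi / V^(1 / 3))
  expect_true(all(diff(sv_ratio_prediction(kap, params)) < 0))
  # e-folding: kappa = 3/alpha divides the kappa = 0 value by e
  expect_equal(
    sv_ratio_prediction(3 / params$alpha, params),
    sv_ratio_prediction(0, params) / exp(1)
  )
})

test_that("aspect-ratio summary matches log-normal moment formulas", {
  set.seed(31)
  x <- exp(rnorm(1e4, log(4.14), 0.14))
  s <- aspect_ratio_summary(x)
  expect_equal(s$mean, 4.14 * exp(0.14^2 / 2), tolerance = 0.01)
  expect_equal(s$cv, sqrt(exp(0.14^2) - 1), tolerance = 0.01)
  expect_equal(s$meanlog, log(4.14), tolerance = 0.01)
  expect_equal(s$sdlog, 0.14, tolerance = 0.01)
  s2 <- aspect_ratio_summary(c(4, 4, 4))
  expect_equal(s2$mean, 4)
  expect_equal(s2$cv, 0)
  expect_error(aspect_ratio_summary(c(4, 0)), "positive")
})

test_that("lineage autocorrelation is 1 at lag 0, null for white noise, and AR(1)-consistent", {
  expect_identical(lineage_autocorrelation(rnorm(10), 0), 1.0)
  set.seed(41)
  wn <- replicate(100, rnorm(101), simplify = FALSE)
  expect_lt(abs(lineage_autocorrelation(wn, 1)), 0.03)
  ar <- replicate(100, {
    x <- numeric(101)
    for (i in 2:101) x[i] <- 0.5 * x[i - 1] + rnorm(1)
    x
  }, simplify = FALSE)
  expect_lt(abs(lineage_autocorrelation(ar, 1) - 0.5), 0.03)
  expect_error(lineage_autocorrelation(list(1:2), 5), "no valid")
})
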