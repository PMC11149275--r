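make_curve <- function(t, load, disp = 25 * t) {
  indentation_curve(t, disp, load, sample_id = "cp")
}

test_that("Savitzky-Golay smoothing reproduces polynomials and keeps length", {
  t <- seq(0, 2, by = 0.01)
  quad <- 0.3 + 0.2 * t - 0.05 * t^2
  curve <- make_curve(t, quad)
  sm <- smooth_curve(curve, window_length = 11, polyorder = 2)
  expect_length(sm$load, length(t))
  expect_equal(sm$load, quad, tolerance = 1e-9)
  # cubic signal, polyorder 3
  cub <- 1 + t - 0.3 * t^2 + 0.08 * t^3
  sm3 <- smooth_curve(make_curve(t, cub), window_length = 21, polyorder = 3)
  expect_equal(sm3$load, cub, tolerance = 1e-9)
})

test_that("smoothing suppresses noise below the input sigma on a quadratic", {
  t <- seq(0, 3, by = 0.005)
  quad <- 0.1 + 0.5 * t + 0.2 * t^2
  sigma <- 0.05
  set.seed(21)
  rms <- replicate(100, {
    noisy <- make_curve(t, quad + rnorm(length(t), 0, sigma))
    sm <- smooth_curve(noisy, window_length = 51, polyorder = 3)
    sqrt(mean((sm$load - quad)^2))
  })
  expect_lt(mean(rms), sigma)
})

test_that("invalid smoothing parameters are refused", {
  t <- seq(0, 1, by = 0.01)
  curve <- make_curve(t, t)
  expect_error(smooth_curve(curve, window_length = 10), "odd",
               class = "cartindent_parameter_error")
  expect_error(smooth_curve(curve, window_length = 3, polyorder = 3),
               class = "cartindent_parameter_error")
  expect_error(smooth_curve(curve, window_length = 1001),
               class = "cartindent_parameter_error")
})

test_that("an exact line fits with its slope and R^2 = 1", {
  t <- seq(0, 2, by = 0.01)
  curve <- make_curve(t, load = 0.04 * (25 * t))
  fit <- fit_loading_slope(curve)
  expect_equal(fit$slope, 0.04, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_gte(fit$n_points, 10)
})

test_that("the noise-free SLS loading slope matches a hereditary-integral oracle", {
  sim <- fixture_sls(0.5, 1.5, 1, id = "slope")
  seg <- segment_phases(sim$curve)
  loading <- extract_phase(sim$curve, seg, "loading")
  fit <- fit_loading_slope(smooth_curve(loading))
  # numerical convolution of G against the same trajectory, evaluated at the
  # fitted window's sample times, with the preload baseline subtracted
  tr <- sim$truth
  prot <- protocol_spec()
  dt <- 0.01
  t_c1 <- (tr$i_loading - 1) * dt
  t_c2 <- (tr$i_hold - 1) * dt
  traj <- function(t) {
    x_p <- tr$x_p
    t_app <- max(dt, round(x_p / (4 * prot$ramp_rate) / dt) * dt)
    pmin(t / t_app, 1) * x_p + pmax(pmin(t - t_c1, t_c2 - t_c1), 0) * prot$ramp_rate
  }
  base_i <- seg$preload[2] - 1
  sel <- loading$displacement >= (1 - 0.35) * max(loading$displacement)
  t_abs <- sim$curve$time[seq(seg$loading[1], seg$loading[2] - 1)][sel]
  P <- oracle_sls_load(c((base_i - 1) * dt, t_abs), traj, tr$E_inf, tr$E_0,
                       tr$tau, tr$load_factor)
  x <- loading$displacement[sel]
  slope_oracle <- stats::cov(x, P[-1] - P[1]) / stats::var(x)
  expect_equal(fit$slope, slope_oracle, tolerance = 1e-3)
  expect_equal(fit$slope, tr$slope_upper35, tolerance = 3e-3)
})

test_that("slope scales exactly with load scaling and R^2 is unchanged", {
  set.seed(31)
  t <- seq(0, 2, by = 0.01)
  load <- 0.002 * 25 * t + rnorm(length(t), 0, 1e-4)
  c1 <- make_curve(t, load)
  c2 <- make_curve(t, 3.7 * load)
  f1 <- fit_loading_slope(c1)
  f2 <- fit_loading_slope(c2)
  expect_equal(f2$slope, 3.7 * f1$slope, tolerance = 1e-12)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-12)
})

test_that("white-noise loads fit with near-zero R^2 and degenerate windows error", {
  set.seed(13)
  t <- seq(0, 2, by = 0.01)
  fit <- fit_loading_slope(make_curve(t, rnorm(length(t))))
  expect_lt(fit$r_squared, 0.3)
  expect_false(qc_gate(fit)$accept)
  short <- make_curve(seq(0, 0.6, by = 0.01), seq(0, 0.6, by = 0.01))
  expect_error(fit_loading_slope(short, upper_fraction = 0.05), "samples",
               class = "cartindent_fit_error")
  flatd <- indentation_curve(t, rep(0, length(t)), t, "flat")
  expect_error(fit_loading_slope(flatd), class = "cartindent_fit_error")
})

test_that("the QC gate rejects strictly below the threshold", {
  mk <- function(r2) structure(list(slope = 1, intercept = 0, r_squared = r2,
                                    n_points = 50, window = "test"),
                               class = "linear_fit")
  expect_false(qc_gate(mk(0.79))$accept)
  expect_match(qc_gate(mk(0.79))$reason, "R\\^2 < 0.80")
  expect_true(qc_gate(mk(0.80))$accept)   # strict less-than: 0.80 passes
  expect_true(qc_gate(mk(1.0))$accept)
})

test_that("equilibrium load averages the hold tail and flags incomplete relaxation", {
  t <- seq(0, 13, by = 0.01)
  hold <- indentation_curve(t, rep(50, length(t)), rep(0.5, length(t)), "h")
  eq <- equilibrium_load(hold)
  expect_equal(eq$P_eq, 0.5)
  expect_equal(eq$x0_eq, 50)
  expect_equal(eq$dPdt_tail, 0, tolerance = 1e-12)

  # SLS hold approaches the analytic asymptote 2 R kappa E_inf x0 / (1-nu^2)
  sim <- fixture_sls(0.5, 1.5, 1, id = "eqm")
  seg <- segment_phases(sim$curve)
  eq2 <- equilibrium_load(extract_phase(sim$curve, seg, "hold"))
  geom <- fixture_geometry()
  asym <- 2 * geom$indenter_radius_R * sim$truth$kappa * 0.5 * 50 /
    (1 - geom$poisson_nu^2) * 1e-6
  expect_equal(eq2$P_eq, asym, tolerance = 0.01)

  t3 <- seq(0, 0.5, by = 0.005)
  short <- indentation_curve(t3, rep(50, length(t3)), rep(0.5, length(t3)), "s")
  expect_error(equilibrium_load(short), "1 s", class = "cartindent_validation_error")
})

test_that("relaxing fixtures show P_eq/x0 below the upper-35% slope", {
  set.seed(77)
  for (i in 1:20) {
    E_inf <- runif(1, 0.3, 2)
    ratio <- runif(1, 1.5, 4)
    sim <- fixture_sls(E_inf, E_inf * ratio, runif(1, 0.4, 2), id = "rel")
    seg <- segment_phases(sim$curve)
    fit <- fit_loading_slope(smooth_curve(extract_phase(sim$curve, seg, "loading")))
    eq <- equilibrium_load(extract_phase(sim$curve, seg, "hold"))
    expect_lt(eq$P_eq / eq$x0_eq, fit$slope)
  }
})
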