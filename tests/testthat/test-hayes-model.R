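test_that("kappa approaches 1 in the half-space limit", {
  for (nu in c(0, 0.2, 0.4, 0.45))
    expect_equal(solve_kappa(1e-6, nu), 1, tolerance = 1e-3)
})

test_that("kappa exceeds 1 for a layer as thick as the punch radius", {
  expect_gt(solve_kappa(1.0, 0.4), 1)
})

test_that("the production solver agrees with the fine-mesh Richardson oracle", {
  for (pt in list(c(2.0, 0.3), c(1.0, 0.4))) {
    k_prod <- solve_kappa(pt[1], pt[2])
    k_or <- oracle_kappa(pt[1], pt[2])
    expect_equal(k_prod, k_or, tolerance = 5e-3)
  }
})

test_that("kappa is monotone in alpha and in nu on a test grid", {
  tab <- build_kappa_table(alpha_grid = c(0.25, 0.5, 1, 2, 4),
                           nu_grid = c(0, 0.2, 0.35, 0.45))
  expect_true(all(tab$kappa >= 1))
  expect_true(all(apply(tab$kappa, 2, function(col) all(diff(col) >= 0))))
  # confinement grows with incompressibility for alpha >= 0.5
  sel <- tab$alpha_grid >= 0.5
  expect_true(all(apply(tab$kappa[sel, , drop = FALSE], 1,
                        function(row) all(diff(row) >= 0))))
})

test_that("halving the solver step changes kappa by well under 0.2%", {
  for (pt in list(c(0.5, 0.1), c(1, 0.4), c(4, 0.45))) {
    k1 <- solve_kappa(pt[1], pt[2], step = 0.01)
    k2 <- solve_kappa(pt[1], pt[2], step = 0.005)
    expect_lt(abs(k2 - k1) / k1, 0.002)
  }
})

test_that("doubling the kernel truncation leaves kappa unchanged to 1e-6", {
  k1 <- solve_kappa(2, 0.3, tail_limit = 30)
  k2 <- solve_kappa(2, 0.3, tail_limit = 60)
  expect_lt(abs(k2 - k1), 1e-6)
})

test_that("solver domain contracts are enforced", {
  expect_error(solve_kappa(1, 0.5), class = "cartindent_validation_error")
  expect_error(solve_kappa(0, 0.4), class = "cartindent_validation_error")
  expect_error(solve_kappa(1, 0.4, step = 0.5), class = "cartindent_validation_error")
})

test_that("kappa tables interpolate within error budget and round-trip to disk", {
  tab <- build_kappa_table(alpha_grid = seq(0.5, 2, by = 0.125),
                           nu_grid = seq(0.3, 0.45, by = 0.025))
  # node query is exact
  expect_identical(interpolate_kappa(tab, 1, 0.4), tab$kappa["1", "0.4"])
  # midpoint query bounded by neighbours and within 0.5% of a direct solve
  mid <- interpolate_kappa(tab, 1.0625, 0.3875)
  rng <- range(tab$kappa[c("1", "1.125"), c("0.375", "0.4")])
  expect_gte(mid, rng[1]); expect_lte(mid, rng[2])
  expect_equal(mid, solve_kappa(1.0625, 0.3875), tolerance = 5e-3)
  expect_error(interpolate_kappa(tab, 3, 0.4), class = "cartindent_extrapolation_error")

  path <- withr::local_tempfile(fileext = ".csv")
  write_kappa_table(tab, path)
  back <- read_kappa_table(path)
  expect_identical(back$kappa[, ], tab$kappa[, ])
  expect_identical(back$solver_step, tab$solver_step)

  one <- build_kappa_table(1, 0.4)
  expect_equal(interpolate_kappa(one, 1, 0.4), solve_kappa(1, 0.4))
})

test_that("tangent and equilibrium moduli follow the layered-punch formula", {
  geom <- specimen_geometry(indenter_radius_R = 525, thickness_h = 525, poisson_nu = 0.4)
  fit <- structure(list(slope = 0.04, intercept = 0, r_squared = 1,
                        n_points = 50, window = "test"), class = "linear_fit")
  # kappa = 1 Hertz limit: 0.04 * 0.84 / (2*525) N/um^2 = 32 MPa
  expect_equal(tangent_modulus(fit, geom, kappa = 1), 32, tolerance = 1e-12)
  expect_equal(equilibrium_modulus(2, 50, geom, kappa = 1), 32, tolerance = 1e-12)
  # proportionality: doubling kappa halves the modulus
  expect_equal(tangent_modulus(fit, geom, kappa = 2), 16, tolerance = 1e-12)
  # rejected fits are refused
  bad <- structure(list(slope = 0.04, intercept = 0, r_squared = 0.5,
                        n_points = 50, window = "t"), class = "linear_fit")
  expect_error(tangent_modulus(bad, geom, 1, qc = qc_gate(bad)),
               class = "cartindent_qc_error")
  expect_error(equilibrium_modulus(2, 0, geom, 1), class = "cartindent_validation_error")
})

test_that("moduli scale linearly in load and inversely in R and kappa", {
  set.seed(41)
  for (i in 1:25) {
    slope <- runif(1, 0.001, 0.1)
    R <- runif(1, 100, 1000)
    h <- runif(1, 200, 1000)
    nu <- runif(1, 0, 0.45)
    kap <- runif(1, 1, 5)
    g1 <- specimen_geometry(R, h, nu)
    g2 <- specimen_geometry(2 * R, h, nu)
    e1 <- tangent_modulus(slope, g1, kap)
    expect_equal(tangent_modulus(3 * slope, g1, kap), 3 * e1, tolerance = 1e-12)
    expect_equal(tangent_modulus(slope, g2, kap), e1 / 2, tolerance = 1e-12)
    expect_equal(tangent_modulus(slope, g1, 2 * kap), e1 / 2, tolerance = 1e-12)
    expect_equal(equilibrium_modulus(slope * 50, 50, g1, kap), e1, tolerance = 1e-12)
  }
})

test_that("noise-free generator curves round-trip to their true moduli", {
  sim <- fixture_sls(2.5, 2.5, 1, id = "round")   # elastic, E = 2.5 MPa
  seg <- segment_phases(sim$curve)
  fit <- fit_loading_slope(smooth_curve(extract_phase(sim$curve, seg, "loading")))
  geom <- fixture_geometry()
  kap <- solve_kappa(geom$alpha, geom$poisson_nu)
  expect_equal(tangent_modulus(fit, geom, kap), 2.5, tolerance = 0.01)

  sim2 <- fixture_sls(0.5, 1.5, 1, id = "round2")
  seg2 <- segment_phases(sim2$curve)
  eq <- equilibrium_load(extract_phase(sim2$curve, seg2, "hold"))
  E_eq <- equilibrium_modulus(eq$P_eq, eq$x0_eq, geom, kap)
  expect_equal(E_eq, 0.5, tolerance = 0.01)
  fit2 <- fit_loading_slope(smooth_curve(extract_phase(sim2$curve, seg2, "loading")))
  expect_lt(E_eq, tangent_modulus(fit2, geom, kap))
})
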