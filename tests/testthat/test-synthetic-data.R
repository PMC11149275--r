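test_that("the elastic degenerate case is linear in ramp and flat in hold", {
  sim <- fixture_sls(1.0, 1.0, 1, id = "el")
  seg <- segment_phases(sim$curve)
  loading <- extract_phase(sim$curve, seg, "loading")
  # strict proportionality of load to displacement during the ramp
  fit <- fit_loading_slope(loading, upper_fraction = 0.999)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  hold <- extract_phase(sim$curve, seg, "hold")
  expect_lt(diff(range(hold$load)) / max(hold$load), 1e-9)
  # recovered moduli equal E_inf within 0.5%
  geom <- fixture_geometry()
  kap <- solve_kappa(geom$alpha, geom$poisson_nu)
  f <- fit_loading_slope(smooth_curve(loading))
  eq <- equilibrium_load(hold)
  expect_equal(tangent_modulus(f, geom, kap), 1.0, tolerance = 0.005)
  expect_equal(equilibrium_modulus(eq$P_eq, eq$x0_eq, geom, kap), 1.0,
               tolerance = 0.005)
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_sls_curve(sls_params(0.7, 2, 1, fixture_geometry()),
                          noise = noise_spec(0.002, 0.1, seed = 99))
  b <- generate_sls_curve(sls_params(0.7, 2, 1, fixture_geometry()),
                          noise = noise_spec(0.002, 0.1, seed = 99))
  expect_identical(a$curve$load, b$curve$load)
  expect_identical(a$curve$displacement, b$curve$displacement)
  c1 <- generate_cohort(seed = 5)
  c2 <- generate_cohort(seed = 5)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$curves[[1]]$load, c2$curves[[1]]$load)
})

test_that("noise-free loads stay non-negative through ramp and hold", {
  set.seed(23)
  for (i in 1:20) {
    E_inf <- runif(1, 0.1, 3)
    sim <- fixture_sls(E_inf, E_inf * runif(1, 1, 5), runif(1, 0.1, 2), id = "pos")
    end_hold <- sim$truth$i_unloading
    expect_true(all(sim$curve$load[seq_len(end_hold)] >= 0))
  }
})

test_that("the SLS response collapses to its elastic limits in tau", {
  # net of the preload baseline, the ramp response approaches E_inf as
  # tau -> 0 and E_0 as tau -> infinity
  elastic_sup_err <- function(tau, E_ref) {
    sim <- fixture_sls(1, 3, tau, kappa = 1, id = "lim")
    seg <- segment_phases(sim$curve)
    loading <- extract_phase(sim$curve, seg, "loading")
    C <- sim$truth$load_factor
    max(abs(loading$load - C * E_ref * loading$displacement)) /
      max(C * E_ref * loading$displacement)
  }
  expect_lt(elastic_sup_err(0.001, 1), 0.01)
  expect_lt(elastic_sup_err(1e5, 3), 0.01)
})

test_that("cohort specs validate and emit pipeline-ready outputs", {
  expect_error(group_spec("A", n = 1), class = "cartindent_validation_error")
  expect_error(group_spec("A", E_inf = c(1, -1)), class = "cartindent_validation_error")
  coh <- generate_cohort(list(group_spec("g1", 3), group_spec("g2", 3)), seed = 2)
  expect_length(coh$curves, 6)
  expect_identical(sort(names(coh$curves)), sort(coh$specimens$sample_id))
  expect_true(all(coh$truth$E_0 >= coh$truth$E_inf))
  expect_true(all(coh$truth$tau > 0 & coh$truth$tau <= 2))
  st <- specimen_table(coh$specimens)
  expect_s3_class(st$geometry[[1]], "specimen_geometry")
})

test_that("voxel phantoms realize their requested bone fractions", {
  roi <- cylinder_roi(diameter = 1.5, depth = 1.5, depth_start = 0.1)
  solid <- generate_voxel_phantom(c(40, 40, 40), 0.05, roi, bone_fraction = 1,
                                  structure = "solid")
  mask <- cylinder_mask(solid$volume, roi)
  bin <- suppressMessages(apply_threshold(solid$volume, 50))
  expect_equal(bvtv(bin, mask), 1.0)
  expect_equal(solid$true_fraction, 1.0)

  lat <- generate_voxel_phantom(c(40, 40, 40), 0.05, roi, bone_fraction = 0.25,
                                structure = "lattice")
  expect_equal(bvtv(suppressMessages(apply_threshold(lat$volume, 50)), mask),
               lat$true_fraction)
  expect_equal(lat$true_fraction, 0.25, tolerance = 0.01)

  r1 <- generate_voxel_phantom(c(40, 40, 40), 0.05, roi, 0.3, "random", seed = 6)
  r2 <- generate_voxel_phantom(c(40, 40, 40), 0.05, roi, 0.3, "random", seed = 6)
  expect_identical(r1$volume$values, r2$volume$values)
  expect_equal(bvtv(suppressMessages(apply_threshold(r1$volume, 50)), mask),
               r1$true_fraction)
})

test_that("recovered moduli bracket the truth over a parameter sweep", {
  geom <- fixture_geometry()
  kap <- solve_kappa(geom$alpha, geom$poisson_nu)
  for (E_inf in c(0.4, 1.5)) for (ratio in c(1, 3)) for (tau in c(0.5, 2)) {
    sim <- fixture_sls(E_inf, E_inf * ratio, tau, id = "sweep")
    seg <- segment_phases(sim$curve)
    fit <- fit_loading_slope(smooth_curve(extract_phase(sim$curve, seg, "loading")))
    eq <- equilibrium_load(extract_phase(sim$curve, seg, "hold"))
    E_eq <- equilibrium_modulus(eq$P_eq, eq$x0_eq, geom, kap)
    E_tan <- tangent_modulus(fit, geom, kap)
    expect_equal(E_eq, E_inf, tolerance = 0.01)
    expect_gte(E_tan, E_inf * (1 - 1e-6))
    expect_lte(E_tan, E_inf * ratio * (1 + 1e-6))
  }
})
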