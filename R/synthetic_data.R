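#' Standard-linear-solid parameters for the synthetic generator
#'
#' The generator uses a standard linear solid (SLS) as a phenomenological
#' surrogate for cartilage stress relaxation: relaxation modulus
#' `G(t) = E_inf + (E_0 - E_inf) exp(-t/tau)` with instantaneous modulus
#' `E_0 >= E_inf > 0` and relaxation time `tau > 0`.
#'
#' @param E_inf Long-time (equilibrium) modulus, MPa.
#' @param E_0 Instantaneous modulus, MPa, `>= E_inf`.
#' @param tau Relaxation time, seconds.
#' @param geometry [specimen_geometry()] of the simulated specimen.
#' @return An object of class `sls_params`.
#' @export
sls_params <- function(E_inf, E_0 = E_inf, tau = 1,
                       geometry = specimen_geometry(thickness_h = 525)) {
  assert_scalar_num(E_inf, "E_inf", lower = 0, lower_open = TRUE)
  assert_scalar_num(E_0, "E_0", lower = E_inf)
  assert_scalar_num(tau, "tau", lower = 0, lower_open = TRUE)
  stopifnot(inherits(geometry, "specimen_geometry"))
  structure(list(E_inf = E_inf, E_0 = E_0, tau = tau, geometry = geometry),
            class = "sls_params")
}

#' Measurement-noise specification
#'
#' @param load_sigma Gaussian load noise SD, newtons.
#' @param displacement_sigma Gaussian displacement noise SD, micrometres.
#' @param seed Integer seed; required whenever either sigma is positive.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(load_sigma = 0, displacement_sigma = 0, seed = NULL) {
  assert_scalar_num(load_sigma, "load_sigma", lower = 0)
  assert_scalar_num(displacement_sigma, "displacement_sigma", lower = 0)
  if ((load_sigma > 0 || displacement_sigma > 0) && is.null(seed))
    stop_cartindent("noise requested without a seed; all randomness must flow from an explicit seed",
                    "cartindent_validation_error")
  structure(list(load_sigma = load_sigma, displacement_sigma = displacement_sigma,
                 seed = seed), class = "noise_spec")
}

# Closed-form hereditary integral of an SLS relaxation modulus against a
# piecewise-linear displacement history. segs: data.frame(t0, t1, rate).
# Returns load/C at times t, where C is the geometric load factor:
# P(t) = C * [E_inf x(t) + (E_0 - E_inf) sum_j v_j tau (e^{-(t-min(t,t1))/tau}
#                                                     - e^{-(t-t0)/tau})]_+
sls_response <- function(t, segs, E_inf, E_0, tau) {
  x <- numeric(length(t))
  trans <- numeric(length(t))
  for (j in seq_len(nrow(segs))) {
    t0 <- segs$t0[j]; t1 <- segs$t1[j]; v <- segs$rate[j]
    if (v == 0) next
    active <- t > t0
    te <- pmin(t[active], t1)
    x[active] <- x[active] + v * (te - t0)
    trans[active] <- trans[active] +
      v * tau * (exp(-(t[active] - te) / tau) - exp(-(t[active] - t0) / tau))
  }
  E_inf * x + (E_0 - E_inf) * trans
}

#' Generate one SLS stress-relaxation indentation curve
#'
#' Builds the preload-ramp-hold-unload displacement trajectory of the
#' indentation protocol and evaluates the load as the exact closed-form
#' hereditary integral of the SLS relaxation modulus against the
#' piecewise-linear displacement history, mapped to force through the same
#' layered-contact factor `2 R kappa / (1 - nu^2)` used by the analysis.
#' Gaussian measurement noise is added per the noise specification.
#'
#' The preload is emulated physically: a fast approach to the displacement
#' that carries the preload force at the instantaneous modulus, followed by
#' a preload dwell (default 13 s) so the preload transient has decayed
#' before the main ramp starts.
#'
#' @param params [sls_params()].
#' @param protocol [protocol_spec()].
#' @param rate_hz Sampling rate, Hz, at least 20.
#' @param noise [noise_spec()].
#' @param preload_dwell_s Dwell at the preload position before the main
#'   ramp, seconds.
#' @param kappa Layered correction used in the force mapping; `NULL` solves
#'   it for the specimen geometry, `1` gives the elastic half-space (Hertz
#'   flat-punch) variant for closed-form cross-checks.
#' @param sample_id Identifier for the curve.
#' @return List with `curve` (an [indentation_curve()]) and `truth`, a list
#'   carrying the ground-truth phase boundary indices (`i_loading`,
#'   `i_hold`, `i_unloading`: first sample of each phase), `E_inf`, `E_0`,
#'   `tau`, `kappa`, the preload displacement `x_p` (um), the analytic
#'   equilibrium load `P_eq` (N, net of the preload baseline) and the
#'   analytic OLS slope of the upper-35% loading window `slope_upper35`
#'   (N/um).
#' @export
generate_sls_curve <- function(params, protocol = protocol_spec(), rate_hz = 100,
                               noise = noise_spec(), preload_dwell_s = 13,
                               kappa = NULL, sample_id = "sls") {
  stopifnot(inherits(params, "sls_params"), inherits(protocol, "protocol_spec"),
            inherits(noise, "noise_spec"))
  if (rate_hz < 20)
    stop_cartindent("rate_hz must be at least 20 Hz", "cartindent_validation_error")
  geom <- params$geometry
  if (is.null(kappa)) kappa <- solve_kappa(geom$alpha, geom$poisson_nu)
  C <- hayes_load_factor(geom, kappa)
  dt <- 1 / rate_hz
  snap <- function(x) max(dt, round(x / dt) * dt)

  x_p <- protocol$preload_N / (C * params$E_0)   # preload depth at E_0
  d_app <- snap(x_p / (4 * protocol$ramp_rate))  # fast approach
  d_dwell <- snap(preload_dwell_s)
  d_ramp <- snap(protocol$ramp_depth / protocol$ramp_rate)
  d_hold <- snap(protocol$hold_duration)

  t_c0 <- d_app                      # preload reached
  t_c1 <- t_c0 + d_dwell             # main ramp starts (corner)
  t_c2 <- t_c1 + d_ramp              # peak reached (corner)
  t_c3 <- t_c2 + d_hold              # unloading starts (corner)
  t_end <- t_c3 + d_ramp             # back at preload depth

  segs <- data.frame(
    t0 = c(0, t_c1, t_c3),
    t1 = c(t_c0, t_c2, t_end),
    rate = c(x_p / d_app, protocol$ramp_depth / d_ramp,
             -protocol$ramp_depth / d_ramp))

  t <- seq(0, t_end, by = dt)
  n <- length(t)
  x <- numeric(n)
  for (j in seq_len(nrow(segs))) {
    active <- t > segs$t0[j]
    x[active] <- x[active] + segs$rate[j] * (pmin(t[active], segs$t1[j]) - segs$t0[j])
  }
  load <- C * sls_response(t, segs, params$E_inf, params$E_0, params$tau)

  if (noise$load_sigma > 0 || noise$displacement_sigma > 0) {
    set.seed(noise$seed)
    if (noise$displacement_sigma > 0)
      x <- x + stats::rnorm(n, 0, noise$displacement_sigma)
    if (noise$load_sigma > 0)
      load <- load + stats::rnorm(n, 0, noise$load_sigma)
  }

  curve <- indentation_curve(t, x, load, sample_id = sample_id,
                             sampling_rate_hint = rate_hz)

  # analytic upper-35% OLS slope from the noise-free closed form (fine grid)
  tf <- seq(t_c1 + 0.65 * d_ramp, t_c2, length.out = 2000)
  Pf <- C * sls_response(tf, segs, params$E_inf, params$E_0, params$tau)
  xf <- x_p + (tf - t_c1) * protocol$ramp_depth / d_ramp
  slope_upper35 <- stats::cov(xf, Pf) / stats::var(xf)

  idx_of <- function(tc) as.integer(round(tc / dt)) + 1L
  truth <- list(E_inf = params$E_inf, E_0 = params$E_0, tau = params$tau,
                kappa = kappa, x_p = x_p,
                i_loading = idx_of(t_c1), i_hold = idx_of(t_c2),
                i_unloading = idx_of(t_c3),
                P_eq = C * params$E_inf * protocol$ramp_depth,
                slope_upper35 = slope_upper35,
                load_factor = C)
  list(curve = curve, truth = truth)
}

#' Specification of one simulated experimental group
#'
#' Per-specimen SLS parameters are drawn from normal distributions truncated
#' at physical bounds (`E_inf >= 0.05` MPa, `E_0/E_inf >= 1`,
#' `0.05 <= tau <= 2` s).
#'
#' @param label Group label.
#' @param n Specimens per group, at least 2.
#' @param E_inf Mean and SD (MPa) of the equilibrium modulus.
#' @param ratio Mean and SD of the instantaneous-to-equilibrium modulus
#'   ratio `E_0/E_inf`.
#' @param tau Mean and SD (s) of the relaxation time.
#' @return A list usable in [generate_cohort()].
#' @export
group_spec <- function(label, n = 10, E_inf = c(1, 0.3), ratio = c(3, 0.5),
                       tau = c(1, 0.2)) {
  if (n < 2) stop_cartindent("each group needs n >= 2", "cartindent_validation_error")
  for (p in list(E_inf, ratio, tau))
    if (length(p) != 2L || !all(is.finite(p)) || p[2] < 0)
      stop_cartindent("distribution specs must be c(mean, sd) with sd >= 0",
                      "cartindent_validation_error")
  list(label = label, n = as.integer(n), E_inf = E_inf, ratio = ratio, tau = tau)
}

#' The six-group study design with literature-scale moduli
#'
#' Six groups of n = 10, with equilibrium-modulus means and SDs at the scale
#' reported for osteochondral repair tissue in the rabbit trochlea (sham
#' ~1.4 MPa, untreated defect and hydrogel repairs 0.4-0.6 MPa).
#'
#' @param n Specimens per group.
#' @return List of [group_spec()]s.
#' @export
default_study_groups <- function(n = 10) {
  list(group_spec("Sham",            n, E_inf = c(1.36, 0.72)),
       group_spec("Defect",          n, E_inf = c(0.50, 0.35)),
       group_spec("GelMA",           n, E_inf = c(0.39, 0.17)),
       group_spec("GelMA+PRP",       n, E_inf = c(0.54, 0.50)),
       group_spec("GelMA+ASC",       n, E_inf = c(0.56, 0.65)),
       group_spec("GelMA+ASC+PRP",   n, E_inf = c(0.61, 0.53)))
}

rtruncnorm1 <- function(n, mean, sd, lower, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lower), upper)
}

#' Generate a multi-group cohort of SLS curves
#'
#' @param groups List of [group_spec()]s.
#' @param protocol [protocol_spec()].
#' @param rate_hz Sampling rate, Hz.
#' @param noise [noise_spec()] applied to every curve (per-curve sub-seeds
#'   are derived from `seed`; the `seed` field of `noise` is ignored).
#' @param seed Master seed for all randomness.
#' @param geometry [specimen_geometry()] shared by all specimens.
#' @return List with `curves` (named list of [indentation_curve()]),
#'   `specimens` (data frame: sample_id, R_um, h_um, nu, group) and `truth`
#'   (data frame of per-specimen ground-truth parameters).
#' @export
generate_cohort <- function(groups = default_study_groups(),
                            protocol = protocol_spec(), rate_hz = 100,
                            noise = noise_spec(), seed = 1,
                            geometry = specimen_geometry(thickness_h = 525)) {
  stopifnot(is.list(groups), length(groups) >= 1L)
  set.seed(seed)
  curves <- list()
  spec_rows <- list()
  truth_rows <- list()
  k <- 0L
  for (g in groups) {
    if (is.null(g$label) || is.null(g$n) || g$n < 2)
      stop_cartindent("invalid group spec (label/n)", "cartindent_validation_error")
    E_inf <- rtruncnorm1(g$n, g$E_inf[1], g$E_inf[2], lower = 0.05)
    ratio <- rtruncnorm1(g$n, g$ratio[1], g$ratio[2], lower = 1)
    tau <- rtruncnorm1(g$n, g$tau[1], g$tau[2], lower = 0.05, upper = 2)
    sub_seeds <- sample.int(.Machine$integer.max - 1L, g$n)
    for (i in seq_len(g$n)) {
      k <- k + 1L
      sid <- sprintf("S%03d_%s", k, gsub("[^A-Za-z0-9]+", "", g$label))
      ns <- if (noise$load_sigma > 0 || noise$displacement_sigma > 0)
        noise_spec(noise$load_sigma, noise$displacement_sigma, seed = sub_seeds[i])
      else noise_spec()
      sim <- generate_sls_curve(
        sls_params(E_inf[i], E_inf[i] * ratio[i], tau[i], geometry),
        protocol = protocol, rate_hz = rate_hz, noise = ns, sample_id = sid)
      curves[[sid]] <- sim$curve
      spec_rows[[k]] <- data.frame(sample_id = sid,
                                   R_um = geometry$indenter_radius_R,
                                   h_um = geometry$thickness_h,
                                   nu = geometry$poisson_nu,
                                   group = g$label)
      truth_rows[[k]] <- data.frame(sample_id = sid, group = g$label,
                                    E_inf = E_inf[i], E_0 = E_inf[i] * ratio[i],
                                    tau = tau[i], kappa = sim$truth$kappa,
                                    P_eq = sim$truth$P_eq,
                                    slope_upper35 = sim$truth$slope_upper35)
    }
  }
  list(curves = curves,
       specimens = do.call(rbind, spec_rows),
       truth = do.call(rbind, truth_rows))
}

#' Generate a voxel phantom with known bone fraction
#'
#' Fills a cylindrical region of interest with "bone" voxels at a requested
#' fraction: `"random"` marks each in-ROI voxel independently (binomial
#' realized count), `"lattice"` marks an evenly strided exact count, and
#' `"solid"` marks an axial slab with an exact count. The realized fraction
#' is returned alongside the volume.
#'
#' @param dim Integer grid dimensions (3).
#' @param voxel_size Voxel edge length(s), mm (scalar or length 3).
#' @param roi [cylinder_roi()].
#' @param bone_fraction Target fraction in `[0, 1]`.
#' @param structure One of `"random"`, `"lattice"`, `"solid"`.
#' @param seed Seed for `"random"` structure.
#' @param bone_value,background Voxel values for bone and non-bone.
#' @return List with `volume` (a [voxel_volume()]), `true_fraction`
#'   (realized in-ROI bone fraction) and `n_inside` (ROI voxel count).
#' @export
generate_voxel_phantom <- function(dim = c(120, 120, 120), voxel_size = 0.05,
                                   roi = cylinder_roi(), bone_fraction = 0.5,
                                   structure = c("random", "lattice", "solid"),
                                   seed = 1, bone_value = 100, background = 0) {
  structure_mode <- match.arg(structure)
  assert_scalar_num(bone_fraction, "bone_fraction", lower = 0, upper = 1)
  if (length(dim) != 3L || any(dim < 1))
    stop_cartindent("dim must be three positive integers", "cartindent_validation_error")
  vol <- voxel_volume(array(background, dim = as.integer(dim)), voxel_size)
  mask <- cylinder_mask(vol, roi)
  inside <- which(mask$values)
  n_in <- length(inside)
  target <- round(bone_fraction * n_in)
  sel <- switch(structure_mode,
    random = {
      set.seed(seed)
      inside[stats::runif(n_in) < bone_fraction]
    },
    lattice = if (target > 0) inside[unique(round(seq(1, n_in, length.out = target)))] else integer(),
    solid = {
      ax <- axis_index(roi$axis)
      coord <- arrayInd(inside, .dim = base::dim(vol$values))[, ax]
      inside[order(coord)][seq_len(target)]
    })
  vol$values[sel] <- bone_value
  list(volume = vol, true_fraction = length(sel) / n_in, n_inside = n_in)
}
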