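#' @name hayes_model
#' @title Layered-elastic correction for flat-punch indentation
#'
#' @description
#' A rigid flat-ended cylindrical indenter of radius `R` pressed a distance
#' `x0` into an elastic half space carries the load
#' `P = 2 R E x0 / (1 - nu^2)`. Articular cartilage is a thin layer of
#' thickness `h` bonded to the much stiffer subchondral bone, so the
#' half-space relation underestimates the true contact stiffness. Modelling
#' the tissue as an infinite elastic layer bonded to a rigid substrate yields
#'
#' `P = 2 R E x0 kappa(alpha, nu) / (1 - nu^2)`,  `alpha = R/h`,
#'
#' where `kappa >= 1` is a dimensionless compensatory function of the aspect
#' ratio and Poisson's ratio. Inverting this relation for `E` is how the
#' tangent and equilibrium elastic moduli are computed.
#'
#' `kappa` is obtained from the mixed boundary-value problem of the bonded
#' layer. Writing the contact pressure through an auxiliary function
#' `omega(t)` on `[0, 1]`, the problem reduces to a Fredholm integral
#' equation of the second kind,
#'
#' `omega(t) - (alpha/pi) * integral_0^1 omega(s) [K(t+s) + K(|t-s|)] ds = 1`,
#'
#' with kernel `K(u) = integral_0^inf (1 - N(x)) cos(alpha u x) dx`, where
#' `N(x)` is the surface response of the bonded layer in Hankel space,
#'
#' `N(x) = [k3 (1 - e^{-4x}) - 4x e^{-2x}] / [k3 (1 + e^{-4x}) + (4x^2 + k3^2 + 1) e^{-2x}]`,
#'
#' `k3 = 3 - 4 nu`. Then `kappa = integral_0^1 omega(t) dt`. As `alpha -> 0`
#' the kernel term vanishes and `kappa -> 1` (half-space limit); `1 - N`
#' decays like `x^2 e^{-2x}`, so the kernel integral converges rapidly.
NULL

# 1 - N(x): deviation of the bonded-layer surface response from the half
# space, in an overflow-safe form. k3 = 3 - 4*nu.
layer_response_deficit <- function(x, nu) {
  k3 <- 3 - 4 * nu
  e2 <- exp(-2 * x)
  e4 <- e2 * e2
  den <- k3 * (1 + e4) + (4 * x^2 + k3^2 + 1) * e2
  e2 * (2 * k3 * e2 + 4 * x + 4 * x^2 + k3^2 + 1) / den
}

# K(u) = int_0^inf (1 - N(x)) cos(alpha*u*x) dx evaluated at a vector of u,
# by composite Gauss-Legendre panels on [0, tail_limit]. The integrand decays
# like x^2 exp(-2x), so tail_limit = 30 leaves a remainder ~1e-19; panels are
# narrow enough to resolve the cosine oscillation for alpha*u up to ~100.
kernel_K <- function(u, alpha, nu, tail_limit = 30, panel_width = 0.25,
                     panel_nodes = 12L) {
  gl <- pracma::gaussLegendre(panel_nodes, 0, panel_width)
  starts <- seq(0, tail_limit - panel_width, by = panel_width)
  x <- as.vector(outer(gl$x, starts, "+"))
  gw <- layer_response_deficit(x, nu) * rep(gl$w, length(starts))
  drop(cos((alpha * u) %o% x) %*% gw)
}

.kappa_cache <- new.env(parent = emptyenv())

#' Solve the layered-punch correction kappa(alpha, nu)
#'
#' Solves the Fredholm integral equation of the second kind governing the
#' bonded-layer flat-punch contact (see [hayes_model]) with a Nystrom
#' discretization: a uniform grid of the given `step` over the punch radius
#' with trapezoidal weights, and the layer kernel evaluated by composite
#' Gauss-Legendre quadrature of its rapidly decaying infinite integral.
#' Results are cached per `(alpha, nu, step)`.
#'
#' @param alpha Aspect ratio `R/h`, > 0.
#' @param nu Poisson's ratio in `[0, 0.5)`; the incompressible bonded layer
#'   is singular and refused.
#' @param step Grid step of the Nystrom discretization, in `(0, 0.1]`.
#'   Default 0.01.
#' @param tail_limit Upper truncation of the kernel integral. The integrand
#'   decays like `x^2 e^{-2x}`; doubling the default changes kappa by far
#'   less than 1e-6.
#' @return Scalar `kappa >= 1`.
#' @examples
#' solve_kappa(1, 0.4)      # layered correction at alpha = 1
#' solve_kappa(1e-6, 0.4)   # half-space limit, ~1
#' @export
solve_kappa <- function(alpha, nu, step = 0.01, tail_limit = 30) {
  assert_scalar_num(alpha, "alpha", lower = 0, lower_open = TRUE)
  assert_scalar_num(nu, "nu", lower = 0, upper = 0.5, upper_open = TRUE)
  assert_scalar_num(step, "step", lower = 0, upper = 0.1, lower_open = TRUE)
  key <- sprintf("%.17g|%.17g|%.17g|%.17g", alpha, nu, step, tail_limit)
  hit <- .kappa_cache[[key]]
  if (!is.null(hit)) return(hit)

  m <- max(2L, as.integer(round(1 / step)))
  h <- 1 / m
  i <- 0:m
  Kv <- kernel_K((0:(2L * m)) * h, alpha, nu, tail_limit = tail_limit)
  if (any(!is.finite(Kv)))
    stop_cartindent("kernel quadrature produced non-finite values",
                    "cartindent_numerical_error")
  Kmat <- matrix(Kv[outer(i, i, "+") + 1L] + Kv[abs(outer(i, i, "-")) + 1L],
                 m + 1L, m + 1L)
  w <- trapezoid_weights(m + 1L, h)
  A <- diag(m + 1L) - (alpha / pi) * sweep(Kmat, 2L, w, "*")
  omega <- tryCatch(solve(A, rep(1, m + 1L)), error = function(e)
    stop_cartindent(sprintf("Nystrom system is singular (alpha=%g, nu=%g): %s",
                            alpha, nu, conditionMessage(e)),
                    "cartindent_numerical_error"))
  kappa <- sum(w * omega)
  if (!is.finite(kappa) || kappa < 1 - 1e-6)
    stop_cartindent(sprintf("kappa solve failed or violated kappa >= 1 (got %g)", kappa),
                    "cartindent_numerical_error")
  kappa <- max(kappa, 1)
  assign(key, kappa, envir = .kappa_cache)
  kappa
}

#' Precompute kappa on an (alpha, nu) grid
#'
#' @param alpha_grid Sorted vector of aspect ratios, > 0.
#' @param nu_grid Sorted vector of Poisson's ratios in `[0, 0.5)`.
#' @param step Nystrom grid step, see [solve_kappa()].
#' @return A `kappa_table`: list with `alpha_grid`, `nu_grid`, the kappa
#'   `matrix` (alpha in rows, nu in columns) and `solver_step`.
#' @export
build_kappa_table <- function(alpha_grid, nu_grid, step = 0.01) {
  if (is.unsorted(alpha_grid, strictly = TRUE) || is.unsorted(nu_grid, strictly = TRUE))
    stop_cartindent("alpha_grid and nu_grid must be strictly increasing",
                    "cartindent_validation_error")
  kap <- matrix(NA_real_, length(alpha_grid), length(nu_grid),
                dimnames = list(alpha = signif(alpha_grid, 8),
                                nu = signif(nu_grid, 8)))
  for (j in seq_along(nu_grid))
    for (i in seq_along(alpha_grid))
      kap[i, j] <- tryCatch(solve_kappa(alpha_grid[i], nu_grid[j], step = step),
                            error = function(e)
        stop_cartindent(sprintf("kappa solve failed at alpha=%g, nu=%g: %s",
                                alpha_grid[i], nu_grid[j], conditionMessage(e)),
                        "cartindent_numerical_error"))
  structure(list(alpha_grid = as.numeric(alpha_grid),
                 nu_grid = as.numeric(nu_grid),
                 kappa = kap, solver_step = step),
            class = "kappa_table")
}

#' @export
print.kappa_table <- function(x, ...) {
  cat(sprintf("<kappa_table> %d alpha x %d nu values, solver step %g\n",
              length(x$alpha_grid), length(x$nu_grid), x$solver_step))
  invisible(x)
}

#' Write / read a kappa table as self-describing text
#'
#' Long-format CSV with `#`-prefixed metadata header lines; values round-trip
#' at full double precision.
#'
#' @param table A `kappa_table` from [build_kappa_table()].
#' @param path File path.
#' @return `write_kappa_table` returns `path` invisibly; `read_kappa_table`
#'   returns the reconstructed `kappa_table`.
#' @export
write_kappa_table <- function(table, path) {
  stopifnot(inherits(table, "kappa_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# cartindent kappa table: flat-punch bonded-layer correction",
               sprintf("# solver_step: %.17g", table$solver_step),
               "alpha,nu,kappa"), con)
  grid <- expand.grid(i = seq_along(table$alpha_grid), j = seq_along(table$nu_grid))
  writeLines(sprintf("%.17g,%.17g,%.17g",
                     table$alpha_grid[grid$i], table$nu_grid[grid$j],
                     table$kappa[cbind(grid$i, grid$j)]), con)
  invisible(path)
}

#' @rdname write_kappa_table
#' @export
read_kappa_table <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  step_line <- grep("solver_step:", meta, value = TRUE)
  step <- if (length(step_line)) as.numeric(sub(".*solver_step:", "", step_line[1])) else NA_real_
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  alpha_grid <- sort(unique(df$alpha))
  nu_grid <- sort(unique(df$nu))
  kap <- matrix(NA_real_, length(alpha_grid), length(nu_grid),
                dimnames = list(alpha = signif(alpha_grid, 8), nu = signif(nu_grid, 8)))
  kap[cbind(match(df$alpha, alpha_grid), match(df$nu, nu_grid))] <- df$kappa
  structure(list(alpha_grid = alpha_grid, nu_grid = nu_grid, kappa = kap,
                 solver_step = step), class = "kappa_table")
}

#' Bilinear interpolation in a kappa table
#'
#' Queries outside the table hull are refused (no silent extrapolation).
#'
#' @param table A `kappa_table`.
#' @param alpha,nu Query point.
#' @return Interpolated kappa.
#' @export
interpolate_kappa <- function(table, alpha, nu) {
  stopifnot(inherits(table, "kappa_table"))
  ag <- table$alpha_grid; ng <- table$nu_grid
  if (alpha < ag[1] || alpha > ag[length(ag)] || nu < ng[1] || nu > ng[length(ng)])
    stop_cartindent(sprintf(
      "query (alpha=%g, nu=%g) outside kappa table hull [%g, %g] x [%g, %g]; extend the table instead of extrapolating",
      alpha, nu, ag[1], ag[length(ag)], ng[1], ng[length(ng)]),
      "cartindent_extrapolation_error")
  i <- findInterval(alpha, ag, rightmost.closed = TRUE)
  j <- findInterval(nu, ng, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(ag) - 1L)
  j <- min(max(j, 1L), length(ng) - 1L)
  if (length(ag) == 1L) i <- 1L
  if (length(ng) == 1L) j <- 1L
  ta <- if (length(ag) > 1L) (alpha - ag[i]) / (ag[i + 1L] - ag[i]) else 0
  tn <- if (length(ng) > 1L) (nu - ng[j]) / (ng[j + 1L] - ng[j]) else 0
  k <- table$kappa
  i2 <- min(i + 1L, length(ag)); j2 <- min(j + 1L, length(ng))
  (1 - ta) * (1 - tn) * k[i, j] + ta * (1 - tn) * k[i2, j] +
    (1 - ta) * tn * k[i, j2] + ta * tn * k[i2, j2]
}

# N/um^2 -> MPa: 1 N/um^2 = 1e12 Pa = 1e6 MPa
.N_PER_UM2_TO_MPA <- 1e6

#' Tangent elastic modulus from a loading-phase fit
#'
#' `E_tan = slope * (1 - nu^2) / (2 R kappa)`, with the slope in N/um and `R`
#' in um, reported in MPa. The fit must have passed the R-squared quality
#' gate; a rejected fit is refused with its QC reason.
#'
#' @param fit A `linear_fit` from [fit_loading_slope()], or a bare slope in
#'   N/um.
#' @param geom [specimen_geometry()].
#' @param kappa Layered correction for this specimen's `(alpha, nu)`; see
#'   [solve_kappa()] / [interpolate_kappa()].
#' @param qc Optional decision from [qc_gate()]; if rejecting, the modulus is
#'   refused.
#' @return `E_tan` in MPa.
#' @export
tangent_modulus <- function(fit, geom, kappa, qc = NULL) {
  stopifnot(inherits(geom, "specimen_geometry"))
  if (!is.null(qc) && !isTRUE(qc$accept))
    stop_cartindent(sprintf("fit rejected by QC gate (%s); refusing modulus computation",
                            qc$reason), "cartindent_qc_error")
  slope <- if (inherits(fit, "linear_fit")) fit$slope else fit
  assert_scalar_num(slope, "slope")
  assert_scalar_num(kappa, "kappa", lower = 1 - 1e-9)
  slope * (1 - geom$poisson_nu^2) /
    (2 * geom$indenter_radius_R * kappa) * .N_PER_UM2_TO_MPA
}

#' Equilibrium elastic modulus from the relaxed hold-phase load
#'
#' `E_eq = P_eq * (1 - nu^2) / (2 R x0 kappa)` in MPa, with `P_eq` in N and
#' `x0` (the held displacement beyond the preload position) in um.
#'
#' @param P_eq Equilibrium load, N.
#' @param x0 Applied displacement at equilibrium, um, > 0.
#' @param geom [specimen_geometry()].
#' @param kappa Layered correction, see [tangent_modulus()].
#' @return `E_eq` in MPa.
#' @export
equilibrium_modulus <- function(P_eq, x0, geom, kappa) {
  stopifnot(inherits(geom, "specimen_geometry"))
  assert_scalar_num(P_eq, "P_eq")
  assert_scalar_num(x0, "x0", lower = 0, lower_open = TRUE)
  assert_scalar_num(kappa, "kappa", lower = 1 - 1e-9)
  P_eq * (1 - geom$poisson_nu^2) /
    (2 * geom$indenter_radius_R * x0 * kappa) * .N_PER_UM2_TO_MPA
}

# Geometric load factor C such that P [N] = C * E [MPa] * x [um]:
# C = 2 R kappa / (1 - nu^2) * 1e-6  (R in um). Shared with the generator.
hayes_load_factor <- function(geom, kappa) {
  2 * geom$indenter_radius_R * kappa / (1 - geom$poisson_nu^2) / .N_PER_UM2_TO_MPA
}
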