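# Independent oracles used across the test suite. These deliberately avoid
# the package's production code paths.

# --- fine-mesh Richardson-extrapolated kappa oracle ------------------------
# Nystrom solve of the bonded-layer flat-punch Fredholm equation written
# independently of the package internals: finer grid (steps 2e-3 and 1e-3,
# Richardson-extrapolated under the trapezoid rule's O(h^2) error) and a
# doubled-truncation kernel quadrature with a different panel layout.
oracle_layer_deficit <- function(x, nu) {
  k3 <- 3 - 4 * nu
  num <- 2 * k3 * sinh(2 * x) - 4 * x
  den <- 2 * k3 * cosh(2 * x) + 4 * x^2 + k3^2 + 1
  ifelse(x > 300, 0, 1 - num / den)   # naive form; overflow-guarded
}

oracle_kernel_K <- function(u, alpha, nu, xmax = 60, npanel = 600, nodes = 8) {
  gl <- pracma::gaussLegendre(nodes, 0, xmax / npanel)
  starts <- seq(0, xmax - xmax / npanel, by = xmax / npanel)
  x <- as.vector(outer(gl$x, starts, "+"))
  gw <- oracle_layer_deficit(x, nu) * rep(gl$w, length(starts))
  drop(cos((alpha * u) %o% x) %*% gw)
}

oracle_kappa_step <- function(alpha, nu, step) {
  m <- round(1 / step)
  i <- 0:m
  Kv <- oracle_kernel_K((0:(2 * m)) * step, alpha, nu)
  Kmat <- matrix(Kv[outer(i, i, "+") + 1L] + Kv[abs(outer(i, i, "-")) + 1L],
                 m + 1L, m + 1L)
  w <- rep(step, m + 1L); w[c(1L, m + 1L)] <- step / 2
  A <- diag(m + 1L) - (alpha / pi) * sweep(Kmat, 2L, w, "*")
  omega <- solve(A, rep(1, m + 1L))
  sum(w * omega)
}

oracle_kappa <- function(alpha, nu) {
  k2 <- oracle_kappa_step(alpha, nu, 0.002)
  k1 <- oracle_kappa_step(alpha, nu, 0.001)
  k1 + (k1 - k2) / 3
}

# --- definitional one-way ANOVA --------------------------------------------
# Grand-mean sums-of-squares decomposition computed longhand.
oracle_anova_oneway <- function(values, groups) {
  groups <- as.factor(groups)
  grand <- mean(values)
  ss_between <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - grand)^2))
  ss_within <- sum(unlist(tapply(values, groups, function(v) (v - mean(v))^2)))
  df_b <- nlevels(groups) - 1L
  df_w <- length(values) - nlevels(groups)
  F <- (ss_between / df_b) / (ss_within / df_w)
  list(ss_between = ss_between, ss_within = ss_within,
       ss_total = sum((values - grand)^2),
       df = c(df_b, df_w), F = F,
       p = stats::pf(F, df_b, df_w, lower.tail = FALSE))
}

# --- numerical hereditary-integral SLS load oracle --------------------------
# Trapezoid convolution of G(t - s) with the displacement rate on a fine
# grid, independent of the generator's closed form. traj: function(t) -> um.
oracle_sls_load <- function(t_eval, traj, E_inf, E_0, tau, C, dt_fine = 5e-4) {
  tg <- seq(0, max(t_eval), by = dt_fine)
  xg <- traj(tg)
  rate <- diff(xg) / dt_fine
  tm <- (tg[-1] + tg[-length(tg)]) / 2
  vapply(t_eval, function(t) {
    keep <- tm < t
    G <- E_inf + (E_0 - E_inf) * exp(-(t - tm[keep]) / tau)
    C * sum(G * rate[keep]) * dt_fine
  }, numeric(1))
}

# --- shared fixtures --------------------------------------------------------
fixture_geometry <- function() specimen_geometry(thickness_h = 525)

fixture_sls <- function(E_inf = 0.5, E_0 = 1.5, tau = 1, noise = noise_spec(),
                        rate_hz = 100, kappa = NULL, id = "fix") {
  generate_sls_curve(sls_params(E_inf, E_0, tau, fixture_geometry()),
                     rate_hz = rate_hz, noise = noise, kappa = kappa,
                     sample_id = id)
}

# a curve that is pure white noise in load with a valid displacement protocol
fixture_noise_curve <- function(seed, id = "noisy") {
  sim <- fixture_sls(id = id)
  set.seed(seed)
  curve <- sim$curve
  curve$load <- stats::rnorm(length(curve$time), mean = 0.2, sd = 0.05)
  curve
}
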