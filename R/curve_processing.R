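#' Savitzky-Golay smoothing of a curve
#'
#' Replaces the load channel (and optionally displacement) by local
#' least-squares polynomial estimates. The filter preserves polynomial
#' signals up to its order and never changes the array length; endpoints are
#' handled by one-sided polynomial fits.
#'
#' @param curve An [indentation_curve()].
#' @param window_length Odd window length in samples, `> polyorder` and at
#'   most the number of samples. `NULL` picks the odd number nearest 5% of
#'   the sample count, with a floor of 11.
#' @param polyorder Polynomial order, default 3.
#' @param channels Channels to smooth, subset of
#'   `c("load", "displacement")`.
#' @return The smoothed [indentation_curve()].
#' @export
smooth_curve <- function(curve, window_length = NULL, polyorder = 3,
                         channels = "load") {
  stopifnot(inherits(curve, "indentation_curve"))
  n <- length(curve$time)
  if (is.null(window_length)) window_length <- default_sg_window(n)
  if (window_length %% 2 == 0)
    stop_cartindent(sprintf("window_length must be odd, got %d", window_length),
                    "cartindent_parameter_error")
  if (window_length <= polyorder)
    stop_cartindent("window_length must exceed polyorder", "cartindent_parameter_error")
  if (window_length > n)
    stop_cartindent(sprintf("window_length %d exceeds the %d available samples",
                            window_length, n), "cartindent_parameter_error")
  out <- curve
  for (ch in match.arg(channels, c("load", "displacement"), several.ok = TRUE))
    out[[ch]] <- signal::sgolayfilt(curve[[ch]], p = polyorder, n = window_length)
  out
}

#' Default Savitzky-Golay window for a phase of n samples
#'
#' The odd number nearest 5% of `n`, floored at 11 (and capped at `n`).
#'
#' @param n Sample count.
#' @return Odd window length.
#' @export
default_sg_window <- function(n) {
  w <- max(11L, 2L * round(0.05 * n / 2) + 1L)
  w <- as.integer(w)
  if (w > n) w <- if (n %% 2L == 1L) n else n - 1L
  w
}

#' Fit the upper fraction of the loading curve
#'
#' Ordinary least squares of load on displacement, restricted to samples
#' whose displacement is at least `(1 - upper_fraction)` times the phase's
#' maximum displacement. The default fits the upper 35% of the loading
#' phase's displacement span, matching strain-controlled indentation where
#' displacement is the controlled variable.
#'
#' @param loading Loading-phase sub-curve (see [extract_phase()]), usually
#'   smoothed first.
#' @param upper_fraction Fraction of the displacement span to fit, in (0, 1].
#' @return A `linear_fit`: slope (N/um), intercept (N), `r_squared`,
#'   `n_points` and a `window` description.
#' @export
fit_loading_slope <- function(loading, upper_fraction = 0.35) {
  stopifnot(inherits(loading, "indentation_curve"))
  assert_scalar_num(upper_fraction, "upper_fraction", lower = 0, upper = 1,
                    lower_open = TRUE)
  x <- loading$displacement
  y <- loading$load
  xmax <- max(x)
  if (!(xmax > 0))
    stop_cartindent("loading phase has no positive displacement span",
                    "cartindent_fit_error")
  sel <- x >= (1 - upper_fraction) * xmax
  if (sum(sel) < 10L)
    stop_cartindent(sprintf("only %d samples in the upper %.0f%% window (need >= 10)",
                            sum(sel), 100 * upper_fraction), "cartindent_fit_error")
  xs <- x[sel]; ys <- y[sel]
  sxx <- sum((xs - mean(xs))^2)
  if (sxx <= 0)
    stop_cartindent("zero displacement variance in the fit window", "cartindent_fit_error")
  slope <- sum((xs - mean(xs)) * (ys - mean(ys))) / sxx
  intercept <- mean(ys) - slope * mean(xs)
  ss_res <- sum((ys - intercept - slope * xs)^2)
  ss_tot <- sum((ys - mean(ys))^2)
  r2 <- if (ss_tot > 0) max(0, 1 - ss_res / ss_tot) else 1
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r2, n_points = sum(sel),
                 window = sprintf("upper %.0f%% of displacement span (x >= %.3f um of %.3f um)",
                                  100 * upper_fraction, (1 - upper_fraction) * xmax, xmax)),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> slope %.5g N/um, R^2 = %.4f, n = %d (%s)\n",
              x$slope, x$r_squared, x$n_points, x$window))
  invisible(x)
}

#' R-squared quality gate for a loading-phase fit
#'
#' Curves whose restricted linear fit fails `R^2 < threshold` (strict
#' less-than) are rejected and excluded from downstream statistics.
#'
#' @param fit A `linear_fit`.
#' @param r2_threshold Rejection threshold, default 0.80.
#' @return List with `accept` (logical), `r_squared` and `reason`.
#' @export
qc_gate <- function(fit, r2_threshold = 0.80) {
  stopifnot(inherits(fit, "linear_fit"))
  reject <- fit$r_squared < r2_threshold
  list(accept = !reject,
       r_squared = fit$r_squared,
       reason = if (reject)
         sprintf("R^2 < %.2f (got %.4f)", r2_threshold, fit$r_squared)
       else "ok")
}

#' Equilibrium load and displacement from the hold phase
#'
#' The equilibrium load is the mean load over the final `tail_fraction` of
#' the hold phase; the applied displacement at equilibrium is the mean
#' displacement over the same tail. A relaxation-completeness diagnostic
#' (the load rate over the tail, N/s, from an OLS fit) is reported so that
#' incomplete relaxation is visible rather than silent.
#'
#' @param hold Hold-phase sub-curve (see [extract_phase()]).
#' @param tail_fraction Fraction of the hold duration to average, default 0.10.
#' @return List with `P_eq` (N), `x0_eq` (um), `dPdt_tail` (N/s) and
#'   `n_tail`.
#' @export
equilibrium_load <- function(hold, tail_fraction = 0.10) {
  stopifnot(inherits(hold, "indentation_curve"))
  assert_scalar_num(tail_fraction, "tail_fraction", lower = 0, upper = 1,
                    lower_open = TRUE)
  dur <- hold$time[length(hold$time)] - hold$time[1]
  if (dur < 1)
    stop_cartindent(sprintf("hold phase lasts %.2f s; at least 1 s is required to read an equilibrium load",
                            dur), "cartindent_validation_error")
  t_cut <- hold$time[length(hold$time)] - tail_fraction * dur
  sel <- hold$time >= t_cut
  if (sum(sel) < 5L)
    stop_cartindent(sprintf("hold tail has %d samples (need >= 5)", sum(sel)),
                    "cartindent_validation_error")
  tt <- hold$time[sel]
  pp <- hold$load[sel]
  dPdt <- stats::lm.fit(cbind(1, tt), pp)$coefficients[[2]]
  list(P_eq = mean(pp), x0_eq = mean(hold$displacement[sel]),
       dPdt_tail = dPdt, n_tail = sum(sel))
}
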