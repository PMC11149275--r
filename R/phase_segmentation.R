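#' Segment a ramp-hold-unload record into protocol phases
#'
#' Partitions a curve into preload, loading, hold and unloading phases by
#' classifying the displacement rate against the protocol's ramp rate. The
#' rate is estimated on a lightly smoothed displacement (running median,
#' window 5, then a Savitzky-Golay derivative filter), so the detector is
#' robust to single-sample spikes and to modest sensor noise. Coarse phase
#' boundaries are then refined to the corner of the piecewise-linear
#' displacement trajectory by intersecting local line fits, which recovers
#' exact boundary indices on noise-free data.
#'
#' @param curve An [indentation_curve()].
#' @param protocol A [protocol_spec()].
#' @param tolerances List of detector tolerances:
#'   `rate_tol` (fraction of the ramp rate within which a sample counts as
#'   ramping, default 0.40), `hold_frac` (|rate| below this fraction of the
#'   ramp rate counts as holding, default 0.10), `depth_tol` (allowed relative
#'   deviation of the loading-phase displacement rise from `ramp_depth`,
#'   default 0.20), `deriv_window` (odd sample count of the derivative
#'   filter, default 11).
#' @return A `phase_segmentation`: list with half-open index ranges
#'   `preload`, `loading`, `hold`, `unloading` as `c(start, end)` pairs
#'   (1-based, `end` exclusive; the four ranges partition the curve), plus
#'   phase durations in seconds.
#' @export
segment_phases <- function(curve, protocol = protocol_spec(),
                           tolerances = list()) {
  stopifnot(inherits(curve, "indentation_curve"))
  tol <- utils::modifyList(list(rate_tol = 0.40, hold_frac = 0.10,
                                depth_tol = 0.20, deriv_window = 11L),
                           tolerances)
  t <- curve$time
  n <- length(t)
  dt <- mean(diff(t))
  if (1 / dt < 20)
    stop_cartindent(sprintf("sampling rate %.1f Hz below the 20 Hz minimum", 1 / dt),
                    "cartindent_validation_error")
  v <- protocol$ramp_rate

  d_med <- stats::runmed(curve$displacement, 5, endrule = "median")
  odd_cap <- function(w) min(as.integer(w), if (n %% 2L == 1L) n else n - 1L)
  w <- odd_cap(tol$deriv_window)
  # fast rate for ramp-edge localization; long-window rate for the
  # low-threshold hold classification (variance of a local-slope estimate
  # falls like window^-3, and the corner refinement restores edge accuracy)
  rate <- signal::sgolayfilt(d_med, p = 2, n = w, m = 1, ts = dt)
  w_slow <- odd_cap(max(w, 51L))
  rate_slow <- signal::sgolayfilt(d_med, p = 2, n = w_slow, m = 1, ts = dt)

  ramping_up <- rate > (1 - tol$rate_tol) * v & rate < (1 + tol$rate_tol) * v
  runs <- logical_runs(ramping_up, gap = 3L)
  if (!nrow(runs))
    stop_cartindent("protocol mismatch: no region with the ramp-rate signature found",
                    "cartindent_segmentation_error")
  rise <- d_med[runs$end] - d_med[runs$start]
  main <- which.max(rise)
  load_start <- runs$start[main]
  load_end <- runs$end[main]          # last in-ramp sample (inclusive)

  # hold: contiguous near-zero-rate region after the ramp. The smoothed rate
  # needs ~window samples to cross the corner, so allow a transition gap
  # before the hold signature appears.
  i <- load_end + 1L
  while (i <= n && abs(rate_slow[i]) >= tol$hold_frac * v && (i - load_end) <= w_slow + 10L)
    i <- i + 1L
  if (i > n || abs(rate_slow[i]) >= tol$hold_frac * v)
    stop_cartindent("protocol mismatch: no hold phase found after the loading ramp",
                    "cartindent_segmentation_error")
  while (i <= n && abs(rate_slow[i]) < tol$hold_frac * v) i <- i + 1L
  hold_end <- i - 1L                  # inclusive

  # unloading: remainder; require a down-ramp signature inside it
  if (hold_end >= n)
    stop_cartindent("protocol mismatch: record ends before the unloading phase",
                    "cartindent_segmentation_error")
  down <- rate[(hold_end + 1L):n] < -(1 - tol$rate_tol) * v &
          rate[(hold_end + 1L):n] > -(1 + tol$rate_tol) * v
  if (!any(down))
    stop_cartindent("protocol mismatch: no unloading ramp signature found",
                    "cartindent_segmentation_error")

  # refine interior boundaries to the piecewise-linear corner
  load_start <- refine_corner(t, d_med, load_start, max(8L, w))
  peak_start <- refine_corner(t, d_med, load_end + 1L, max(8L, w))
  unload_start <- refine_corner(t, d_med, hold_end + 1L, max(8L, w_slow))

  if (load_start <= 1L)
    stop_cartindent("protocol mismatch: no preload phase before the loading ramp",
                    "cartindent_segmentation_error")
  if (unload_start <= peak_start || peak_start <= load_start)
    stop_cartindent("segmentation produced an empty phase", "cartindent_segmentation_error")

  ramp_rise <- d_med[peak_start] - d_med[load_start]
  if (abs(ramp_rise - protocol$ramp_depth) > tol$depth_tol * protocol$ramp_depth)
    stop_cartindent(sprintf(
      "protocol mismatch: loading rise %.1f um vs expected %.1f um (+/- %.0f%%)",
      ramp_rise, protocol$ramp_depth, 100 * tol$depth_tol),
      "cartindent_segmentation_error")

  hold_dur <- t[unload_start - 1L] - t[peak_start]
  if (hold_dur < protocol$hold_duration / 2)
    stop_cartindent(sprintf("hold phase lasts %.2f s, shorter than half the protocol hold of %g s",
                            hold_dur, protocol$hold_duration),
                    "cartindent_segmentation_error")

  structure(list(
    preload = c(1L, load_start),
    loading = c(load_start, peak_start),
    hold = c(peak_start, unload_start),
    unloading = c(unload_start, n + 1L),
    durations = c(preload = t[load_start - 1L] - t[1L],
                  loading = t[peak_start - 1L] - t[load_start],
                  hold = hold_dur,
                  unloading = t[n] - t[unload_start]),
    n = n), class = "phase_segmentation")
}

# Refine a coarse boundary index to the corner between two locally linear
# displacement segments: fit a line on each side (excluding the candidate
# corner sample), intersect, snap to the nearest sample time. Iterated to a
# fixed point so a lagging coarse guess cannot leave corner samples inside a
# side window. Exact on noise-free piecewise-linear trajectories.
refine_corner <- function(t, d, b, halfwin) {
  n <- length(t)
  for (pass in 1:5) {
    li <- max(1L, b - halfwin):max(1L, b - 2L)
    ri <- min(n, b + 1L):min(n, b + halfwin)
    if (length(unique(li)) < 3L || length(unique(ri)) < 3L) return(b)
    cl <- stats::lm.fit(cbind(1, t[li]), d[li])$coefficients
    cr <- stats::lm.fit(cbind(1, t[ri]), d[ri])$coefficients
    if (!all(is.finite(c(cl, cr))) || abs(cl[2] - cr[2]) < 1e-8) return(b)
    tc <- (cr[1] - cl[1]) / (cl[2] - cr[2])
    cand <- which.min(abs(t - tc))
    if (abs(cand - b) > halfwin) return(b)
    if (cand == b) return(as.integer(b))
    b <- as.integer(cand)
  }
  b
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat(sprintf("<phase_segmentation> preload [%d,%d) loading [%d,%d) hold [%d,%d) unloading [%d,%d)\n",
              x$preload[1], x$preload[2], x$loading[1], x$loading[2],
              x$hold[1], x$hold[2], x$unloading[1], x$unloading[2]))
  cat(sprintf("  durations: preload %.2f s, loading %.2f s, hold %.2f s, unloading %.2f s\n",
              x$durations[1], x$durations[2], x$durations[3], x$durations[4]))
  invisible(x)
}

#' Extract one phase as a sub-curve
#'
#' Time is re-zeroed to the phase start. Displacement and load are re-zeroed
#' to their values at the end of the preload phase, so that `x = 0` is the
#' ramp origin beyond the preload position and loads are measured net of the
#' preload baseline. Both zeroings are the package's analysis convention (see
#' the methods vignette) and can be switched off.
#'
#' @param curve An [indentation_curve()].
#' @param seg A `phase_segmentation` for this curve.
#' @param phase One of `"preload"`, `"loading"`, `"hold"`, `"unloading"`.
#' @param rezero_displacement,rezero_load Subtract the end-of-preload
#'   baseline values (defaults `TRUE`).
#' @return An [indentation_curve()] holding the phase samples. Validation is
#'   relaxed to allow short phases (minimum 5 samples).
#' @export
extract_phase <- function(curve, seg, phase = c("loading", "hold", "preload", "unloading"),
                          rezero_displacement = TRUE, rezero_load = TRUE) {
  stopifnot(inherits(curve, "indentation_curve"), inherits(seg, "phase_segmentation"))
  phase <- match.arg(phase)
  rng <- seg[[phase]]
  if (seg$n != length(curve$time))
    stop_cartindent("segmentation does not match this curve", "cartindent_validation_error")
  idx <- seq.int(rng[1], rng[2] - 1L)
  if (length(idx) < 5L)
    stop_cartindent(sprintf("phase '%s' is empty or too short (%d samples)", phase, length(idx)),
                    "cartindent_validation_error")
  base_i <- seg$preload[2] - 1L   # last preload sample
  d0 <- if (rezero_displacement) curve$displacement[base_i] else 0
  p0 <- if (rezero_load) curve$load[base_i] else 0
  out <- list(time = curve$time[idx] - curve$time[idx[1]],
              displacement = curve$displacement[idx] - d0,
              load = curve$load[idx] - p0,
              sample_id = paste0(curve$sample_id, ":", phase),
              sampling_rate_hint = curve$sampling_rate_hint)
  class(out) <- "indentation_curve"
  out
}

#' Segmentation report as JSON
#'
#' @param seg A `phase_segmentation`.
#' @param path Optional output file; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to file).
#' @export
segmentation_report <- function(seg, path = NULL) {
  stopifnot(inherits(seg, "phase_segmentation"))
  obj <- list(preload = seg$preload, loading = seg$loading, hold = seg$hold,
              unloading = seg$unloading,
              durations_s = as.list(seg$durations))
  js <- jsonlite::toJSON(obj, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
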