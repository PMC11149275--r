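#' Construct and validate an indentation curve
#'
#' An `indentation_curve` holds one sampled ramp-hold-unload test record in the
#' canonical units used throughout the package: time in seconds (strictly
#' increasing), indenter displacement in micrometres (positive into the
#' tissue), and compressive load in newtons (positive).
#'
#' @param time Numeric vector of sample times, seconds, strictly increasing.
#' @param displacement Numeric vector, micrometres, same length as `time`.
#' @param load Numeric vector, newtons, same length as `time`.
#' @param sample_id Specimen/test identifier.
#' @param sampling_rate_hint Optional nominal sampling rate in Hz.
#' @return An object of class `indentation_curve`.
#' @examples
#' t <- seq(0, 1, by = 0.01)
#' curve <- indentation_curve(t, 25 * t, 0.001 * t, sample_id = "demo")
#' @export
indentation_curve <- function(time, displacement, load, sample_id = "unknown",
                              sampling_rate_hint = NULL) {
  n <- length(time)
  if (n < 50L)
    stop_cartindent(sprintf("indentation curve needs at least 50 samples, got %d", n),
                    "cartindent_validation_error")
  if (length(displacement) != n || length(load) != n)
    stop_cartindent("time, displacement and load must have equal length",
                    "cartindent_validation_error")
  if (anyNA(time) || any(!is.finite(time)))
    stop_cartindent("non-finite time values", "cartindent_validation_error")
  dt <- diff(time)
  bad <- which(dt <= 0)
  if (length(bad))
    stop_cartindent(sprintf("time not strictly increasing at index %d (t[%d]=%g, t[%d]=%g)",
                            bad[1L] + 1L, bad[1L], time[bad[1L]], bad[1L] + 1L, time[bad[1L] + 1L]),
                    "cartindent_validation_error", index = bad[1L] + 1L)
  if (any(!is.finite(displacement)))
    stop_cartindent("non-finite displacement values", "cartindent_validation_error")
  if (any(!is.finite(load)))
    stop_cartindent("non-finite load values", "cartindent_validation_error")
  structure(list(time = as.numeric(time),
                 displacement = as.numeric(displacement),
                 load = as.numeric(load),
                 sample_id = as.character(sample_id),
                 sampling_rate_hint = sampling_rate_hint),
            class = "indentation_curve")
}

#' @export
print.indentation_curve <- function(x, ...) {
  cat(sprintf("<indentation_curve> %s: %d samples, %.3f s, displacement %.2f..%.2f um, load %.4f..%.4f N\n",
              x$sample_id, length(x$time), diff(range(x$time)),
              min(x$displacement), max(x$displacement), min(x$load), max(x$load)))
  invisible(x)
}

#' @export
length.indentation_curve <- function(x) length(x$time)

#' Specimen geometry for layered-indentation analysis
#'
#' Holds the indenter radius `R`, the cartilage layer thickness `h` (both in
#' micrometres) and Poisson's ratio `nu`. The aspect ratio `alpha = R/h`
#' controls the layered-geometry correction kappa. The default radius follows
#' the flat-ended cylindrical indenter used for the repair-tissue protocol
#' (R = 525 um) and the default Poisson's ratio is 0.4.
#'
#' @param indenter_radius_R Indenter radius, micrometres, > 0.
#' @param thickness_h Layer thickness, micrometres, > 0. No default exists:
#'   thickness must be measured per specimen.
#' @param poisson_nu Poisson's ratio in `[0, 0.5)`. The incompressible bonded
#'   layer (`nu = 0.5`) is singular and refused.
#' @return An object of class `specimen_geometry` with derived field `alpha`.
#' @examples
#' specimen_geometry(thickness_h = 525)  # alpha = 1
#' @export
specimen_geometry <- function(indenter_radius_R = 525, thickness_h, poisson_nu = 0.4) {
  if (missing(thickness_h))
    stop_cartindent("thickness_h is required: cartilage thickness must be measured per specimen (no default exists)",
                    "cartindent_validation_error")
  assert_scalar_num(indenter_radius_R, "indenter_radius_R", lower = 0, lower_open = TRUE)
  assert_scalar_num(thickness_h, "thickness_h", lower = 0, lower_open = TRUE)
  assert_scalar_num(poisson_nu, "poisson_nu", lower = 0, upper = 0.5, upper_open = TRUE)
  structure(list(indenter_radius_R = indenter_radius_R,
                 thickness_h = thickness_h,
                 poisson_nu = poisson_nu,
                 alpha = indenter_radius_R / thickness_h),
            class = "specimen_geometry")
}

#' @export
print.specimen_geometry <- function(x, ...) {
  cat(sprintf("<specimen_geometry> R = %g um, h = %g um, nu = %g (alpha = %.4g)\n",
              x$indenter_radius_R, x$thickness_h, x$poisson_nu, x$alpha))
  invisible(x)
}

#' Indentation protocol specification
#'
#' The strain-controlled ramp-hold-unload protocol: a small compressive
#' preload, a constant-rate ramp to the target depth, a hold at peak
#' displacement for stress relaxation, and a constant-rate withdrawal.
#' Defaults are the repair-tissue protocol: 0.1 N preload, 25 um/s ramp to
#' 50 um, 13 s hold.
#'
#' @param preload_N Preload force, newtons.
#' @param ramp_rate Ramp (and unload) rate, micrometres per second.
#' @param ramp_depth Ramp depth beyond the preload position, micrometres.
#' @param hold_duration Hold duration at peak displacement, seconds.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(preload_N = 0.1, ramp_rate = 25, ramp_depth = 50,
                          hold_duration = 13) {
  assert_scalar_num(preload_N, "preload_N", lower = 0, lower_open = TRUE)
  assert_scalar_num(ramp_rate, "ramp_rate", lower = 0, lower_open = TRUE)
  assert_scalar_num(ramp_depth, "ramp_depth", lower = 0, lower_open = TRUE)
  assert_scalar_num(hold_duration, "hold_duration", lower = 0, lower_open = TRUE)
  structure(list(preload_N = preload_N, ramp_rate = ramp_rate,
                 ramp_depth = ramp_depth, hold_duration = hold_duration),
            class = "protocol_spec")
}

#' Default column/unit mapping for curve files
#'
#' Instrument exports vary; the mapping from file columns and units to the
#' canonical representation is explicit rather than sniffed.
#'
#' @param time,displacement,load Column names in the file header.
#' @param units Named list of source units, converted on read
#'   (time: s/ms/min; displacement: um/mm/m/nm; load: N/mN/kN/uN).
#' @param sep Field separator (`","` or `"\t"`).
#' @return A list usable as the `dialect` argument of [read_curve()].
#' @export
curve_dialect <- function(time = "t_s", displacement = "disp_um", load = "load_N",
                          units = list(time = "s", displacement = "um", load = "N"),
                          sep = ",") {
  list(time = time, displacement = displacement, load = load,
       units = list(time = units$time %||% "s",
                    displacement = units$displacement %||% "um",
                    load = units$load %||% "N"),
       sep = sep)
}

#' Read one indentation curve from a delimited text file
#'
#' @param path File path of a headered CSV/TSV file.
#' @param dialect Column-and-unit mapping, see [curve_dialect()].
#' @param sample_id Identifier for the curve; defaults to the file name.
#' @return A validated [indentation_curve()] in canonical units (s, um, N).
#' @export
read_curve <- function(path, dialect = curve_dialect(),
                       sample_id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path))
    stop_cartindent(sprintf("curve file not found: %s", path), "cartindent_io_error")
  df <- data.table::fread(path, sep = dialect$sep, header = TRUE, data.table = FALSE)
  for (col in c(dialect$time, dialect$displacement, dialect$load))
    if (!col %in% names(df))
      stop_cartindent(sprintf("curve file %s is missing required column '%s' (found: %s)",
                              basename(path), col, paste(names(df), collapse = ", ")),
                      "cartindent_format_error")
  indentation_curve(
    time = df[[dialect$time]] * unit_factor(dialect$units$time, "time"),
    displacement = df[[dialect$displacement]] *
      unit_factor(dialect$units$displacement, "displacement"),
    load = df[[dialect$load]] * unit_factor(dialect$units$load, "load"),
    sample_id = sample_id)
}

#' Write an indentation curve to a delimited text file
#'
#' Values are written with full double precision so that a write/read
#' round trip reproduces the curve to better than 1e-9 relative.
#'
#' @param curve An [indentation_curve()].
#' @param path Output file path.
#' @param dialect Column-and-unit mapping; values are converted from canonical
#'   units into the dialect's declared units before writing.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path, dialect = curve_dialect()) {
  stopifnot(inherits(curve, "indentation_curve"))
  df <- data.frame(
    curve$time / unit_factor(dialect$units$time, "time"),
    curve$displacement / unit_factor(dialect$units$displacement, "displacement"),
    curve$load / unit_factor(dialect$units$load, "load"))
  names(df) <- c(dialect$time, dialect$displacement, dialect$load)
  ok <- tryCatch({
    data.table::fwrite(df, path, sep = dialect$sep)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop_cartindent(sprintf("cannot write curve to %s: %s", path,
                            conditionMessage(ok)), "cartindent_io_error")
  invisible(path)
}

#' Read a specimen table
#'
#' One row per specimen with columns `sample_id`, `R_um`, `h_um`, `nu`,
#' `group`. Missing thickness is a hard error: no thickness default exists.
#'
#' @param path CSV file path.
#' @return A data frame with columns `sample_id`, `group` and a `geometry`
#'   list-column of validated [specimen_geometry()] objects.
#' @export
read_specimen_table <- function(path) {
  if (!file.exists(path))
    stop_cartindent(sprintf("specimen table not found: %s", path), "cartindent_io_error")
  df <- data.table::fread(path, header = TRUE, data.table = FALSE)
  specimen_table(df)
}

#' Validate an in-memory specimen table
#'
#' @param df Data frame with columns `sample_id`, `R_um`, `h_um`, `nu`, `group`.
#' @return As [read_specimen_table()].
#' @export
specimen_table <- function(df) {
  for (col in c("sample_id", "h_um", "group"))
    if (!col %in% names(df))
      stop_cartindent(sprintf("specimen table is missing required column '%s'%s",
                              col,
                              if (col == "h_um") " (cartilage thickness is required; there is no default)" else ""),
                      "cartindent_format_error")
  if (!"R_um" %in% names(df)) df$R_um <- 525
  if (!"nu" %in% names(df)) df$nu <- 0.4
  geoms <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    if (is.na(df$h_um[i]))
      stop_cartindent(sprintf("specimen '%s': thickness h_um is missing; thickness must be measured per specimen",
                              df$sample_id[i]), "cartindent_validation_error")
    geoms[[i]] <- specimen_geometry(df$R_um[i], df$h_um[i], df$nu[i])
  }
  out <- data.frame(sample_id = as.character(df$sample_id),
                    group = as.character(df$group),
                    stringsAsFactors = FALSE)
  out$geometry <- geoms
  out
}

#' Mean contact pressure of the preload
#'
#' The preload force divided by the face area of the flat-ended cylindrical
#' indenter, `P / (pi R^2)`, reported in kPa (0.1 N on a 525 um radius punch
#' is about 115 kPa).
#'
#' @param preload_N Preload force, newtons.
#' @param R_um Indenter radius, micrometres.
#' @return Pressure in kPa.
#' @export
contact_pressure_kPa <- function(preload_N = 0.1, R_um = 525) {
  assert_scalar_num(preload_N, "preload_N", lower = 0, lower_open = TRUE)
  assert_scalar_num(R_um, "R_um", lower = 0, lower_open = TRUE)
  preload_N / (pi * (R_um * 1e-6)^2) / 1000
}
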