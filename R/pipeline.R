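#' Assemble a run configuration
#'
#' All analysis tunables in one auditable place. Defaults follow the
#' repair-tissue protocol and analysis: 0.1 N preload, 25 um/s ramp to
#' 50 um, 13 s hold; upper 35% loading-phase fit; R^2 >= 0.80 acceptance;
#' equilibrium read over the final 10% of the hold; nu = 0.4; Fredholm
#' solver step 0.01.
#'
#' @param ... Overrides of the default fields (see Details).
#' @details Fields: `protocol` ([protocol_spec()]), `upper_fraction`,
#'   `r2_threshold`, `tail_fraction`, `sg_polyorder`, `sg_window` (`NULL`
#'   for the per-phase default), `kappa_step`, `seg_tolerances`,
#'   `curves_dir`, `dialect`, `specimen_table`, `volumes_dir`,
#'   `roi` ([cylinder_roi()]), `threshold` (numeric or `"otsu"`),
#'   `out_dir`, `seed`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(protocol = protocol_spec(), upper_fraction = 0.35,
              r2_threshold = 0.80, tail_fraction = 0.10,
              sg_polyorder = 3, sg_window = NULL,
              kappa_step = 0.01, seg_tolerances = list(),
              curves_dir = NULL, dialect = curve_dialect(),
              specimen_table = NULL, volumes_dir = NULL,
              roi = cylinder_roi(), threshold = "otsu",
              out_dir = NULL, seed = 1)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop_cartindent(sprintf("unknown config field(s): %s", paste(bad, collapse = ", ")),
                    "cartindent_config_error")
  for (fr in c("upper_fraction", "r2_threshold", "tail_fraction"))
    if (!is.null(over[[fr]]))
      assert_scalar_num(over[[fr]], fr, lower = 0, upper = 1,
                        lower_open = TRUE, upper_open = fr != "r2_threshold")
  structure(utils::modifyList(cfg, over), class = "run_config")
}

#' Read a YAML run configuration
#'
#' Scalar fields map directly onto [run_config()]; `protocol:` and `roi:`
#' sub-maps are passed to [protocol_spec()] and [cylinder_roi()], and
#' `dialect:` to [curve_dialect()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$protocol)) y$protocol <- do.call(protocol_spec, y$protocol)
  if (!is.null(y$roi)) y$roi <- do.call(cylinder_roi, y$roi)
  if (!is.null(y$dialect)) y$dialect <- do.call(curve_dialect, y$dialect)
  do.call(run_config, y)
}

config_log <- function(cfg) {
  c(sprintf("protocol: preload %g N, ramp %g um/s to %g um, hold %g s",
            cfg$protocol$preload_N, cfg$protocol$ramp_rate,
            cfg$protocol$ramp_depth, cfg$protocol$hold_duration),
    sprintf("upper_fraction: %g", cfg$upper_fraction),
    sprintf("r2_threshold: %g (strict less-than rejection)", cfg$r2_threshold),
    sprintf("tail_fraction: %g", cfg$tail_fraction),
    sprintf("sg: polyorder %g, window %s", cfg$sg_polyorder,
            if (is.null(cfg$sg_window)) "auto (odd nearest 5% of phase, min 11)"
            else as.character(cfg$sg_window)),
    sprintf("kappa_step: %g", cfg$kappa_step),
    sprintf("seed: %s", cfg$seed))
}

#' Run the indentation analysis end to end
#'
#' For each specimen: segment the curve into protocol phases, smooth the
#' loading-phase load (Savitzky-Golay), fit the upper fraction of the
#' loading curve, apply the R-squared gate, read the equilibrium load from
#' the hold tail, solve the layered correction kappa for the specimen
#' geometry, and convert to tangent and equilibrium moduli. Specimen-level
#' failures never abort the run; they become report rows with reasons.
#' Accepted specimens feed a group summary (mean +/- SD), one-way ANOVA and
#' Tukey HSD per outcome.
#'
#' @param config A `run_config` (or YAML path). Curve files are read from
#'   `config$curves_dir` using `config$dialect`, and the specimen table from
#'   `config$specimen_table`, unless both are supplied in memory.
#' @param curves Optional named list of [indentation_curve()]s keyed by
#'   sample id (overrides `curves_dir`).
#' @param specimens Optional specimen data frame (see [specimen_table()]).
#' @return List with `results` (per-specimen data frame), `stats` (per
#'   outcome: `summary`, `anova`, `tukey`), `rejected` (sample ids with
#'   reasons) and `log`. If `config$out_dir` is set, CSV/JSON reports and a
#'   log file are written there.
#' @export
run_indentation <- function(config = run_config(), curves = NULL, specimens = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  log <- c(sprintf("run_indentation @ %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
           config_log(config))
  if (is.null(specimens)) {
    if (is.null(config$specimen_table))
      stop_cartindent("no specimen table supplied (config$specimen_table or specimens=)",
                      "cartindent_config_error")
    specimens <- read_specimen_table(config$specimen_table)
  } else if (!"geometry" %in% names(specimens)) {
    specimens <- specimen_table(specimens)
  }
  if (is.null(curves)) {
    if (is.null(config$curves_dir))
      stop_cartindent("no curves supplied (config$curves_dir or curves=)",
                      "cartindent_config_error")
    files <- list.files(config$curves_dir, pattern = "\\.(csv|tsv)$", full.names = TRUE)
    curves <- lapply(files, read_curve, dialect = config$dialect)
    names(curves) <- vapply(curves, `[[`, "", "sample_id")
  }
  missing_curves <- setdiff(specimens$sample_id, names(curves))
  if (length(missing_curves))
    log <- c(log, sprintf("WARNING: no curve for specimen(s): %s",
                          paste(missing_curves, collapse = ", ")))

  rows <- vector("list", nrow(specimens))
  for (i in seq_len(nrow(specimens))) {
    sid <- specimens$sample_id[i]
    geom <- specimens$geometry[[i]]
    row <- data.frame(sample_id = sid, group = specimens$group[i],
                      alpha = geom$alpha, nu = geom$poisson_nu,
                      kappa = NA_real_, slope = NA_real_, r_squared = NA_real_,
                      accepted = FALSE, reason = NA_character_,
                      P_eq = NA_real_, x0_eq = NA_real_, dPdt_tail = NA_real_,
                      E_tan = NA_real_, E_eq = NA_real_)
    res <- tryCatch({
      curve <- curves[[sid]]
      if (is.null(curve))
        stop_cartindent(sprintf("no curve for specimen %s", sid), "cartindent_io_error")
      seg <- segment_phases(curve, config$protocol, config$seg_tolerances)
      loading <- extract_phase(curve, seg, "loading")
      hold <- extract_phase(curve, seg, "hold")
      loading_s <- smooth_curve(loading, window_length = config$sg_window,
                                polyorder = config$sg_polyorder)
      fit <- fit_loading_slope(loading_s, config$upper_fraction)
      qc <- qc_gate(fit, config$r2_threshold)
      kap <- solve_kappa(geom$alpha, geom$poisson_nu, step = config$kappa_step)
      eq <- equilibrium_load(hold, config$tail_fraction)
      row$kappa <- kap
      row$slope <- fit$slope
      row$r_squared <- fit$r_squared
      row$P_eq <- eq$P_eq; row$x0_eq <- eq$x0_eq; row$dPdt_tail <- eq$dPdt_tail
      row$E_eq <- equilibrium_modulus(eq$P_eq, eq$x0_eq, geom, kap)
      if (qc$accept) {
        row$E_tan <- tangent_modulus(fit, geom, kap, qc)
        row$accepted <- TRUE
        row$reason <- "ok"
      } else {
        row$reason <- qc$reason
      }
      row
    }, cartindent_error = function(e) {
      row$reason <- conditionMessage(e)
      row
    })
    rows[[i]] <- res
    log <- c(log, sprintf("%s: %s", sid,
                          if (res$accepted) sprintf("accepted (R^2=%.3f, E_tan=%.3f MPa, E_eq=%.3f MPa)",
                                                    res$r_squared, res$E_tan, res$E_eq)
                          else sprintf("REJECTED: %s", res$reason)))
  }
  results <- do.call(rbind, rows)
  accepted <- results[results$accepted, , drop = FALSE]

  stats_out <- list()
  for (outc in c("E_tan", "E_eq")) {
    vals <- accepted[[outc]]
    ok <- is.finite(vals)
    tab <- data.frame(sample_id = accepted$sample_id[ok],
                      group = accepted$group[ok], value = vals[ok])
    piece <- function(fn, what) tryCatch(fn(tab), cartindent_error = function(e) {
      log <<- c(log, sprintf("%s for %s skipped: %s", what, outc, conditionMessage(e)))
      NULL
    })
    stats_out[[outc]] <- list(summary = piece(summarize_groups, "summary"),
                              anova = piece(anova_table, "anova"),
                              tukey = piece(tukey_hsd, "tukey"))
  }

  out <- list(results = results,
              stats = stats_out,
              rejected = results[!results$accepted, c("sample_id", "reason")],
              log = log)
  if (!is.null(config$out_dir)) write_indentation_reports(out, config$out_dir)
  out
}

write_indentation_reports <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(out$results, file.path(out_dir, "modulus_results.csv"), row.names = FALSE)
  for (outc in names(out$stats)) {
    s <- out$stats[[outc]]
    if (is.null(s)) next
    utils::write.csv(s$summary, file.path(out_dir, sprintf("summary_%s.csv", outc)), row.names = FALSE)
    utils::write.csv(s$anova, file.path(out_dir, sprintf("anova_%s.csv", outc)), row.names = FALSE)
    utils::write.csv(s$tukey, file.path(out_dir, sprintf("tukey_%s.csv", outc)), row.names = FALSE)
  }
  jsonlite::write_json(
    list(results = out$results, rejected = out$rejected),
    file.path(out_dir, "indentation_report.json"), dataframe = "rows", digits = NA)
  writeLines(out$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Run the bone-volume analysis
#'
#' Threshold each volume, build the cylindrical ROI mask, and compute BV/TV.
#' Per-specimen failures are isolated and reported.
#'
#' @param config A `run_config` (fields `roi`, `threshold`, `volumes_dir`,
#'   `out_dir`).
#' @param volumes Optional named list of [voxel_volume()]s keyed by sample
#'   id (overrides `volumes_dir`, where `<sample_id>.raw` files are
#'   expected, see [write_volume()]).
#' @param sample_ids Sample ids to process; defaults to the names of
#'   `volumes` or the files found.
#' @return List with `results` (sample_id, threshold, bv, tv, bvtv, status)
#'   and `log`.
#' @export
run_bvtv <- function(config = run_config(), volumes = NULL, sample_ids = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  log <- c(sprintf("run_bvtv @ %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
           sprintf("roi: axis %s, diameter %g mm, depth %g mm (start %g mm)",
                   config$roi$axis, config$roi$diameter, config$roi$depth,
                   config$roi$depth_start),
           sprintf("threshold: %s", if (is.numeric(config$threshold))
             sprintf("fixed %g", config$threshold) else config$threshold))
  if (is.null(volumes)) {
    if (is.null(config$volumes_dir))
      stop_cartindent("no volumes supplied (config$volumes_dir or volumes=)",
                      "cartindent_config_error")
    if (is.null(sample_ids)) {
      files <- list.files(config$volumes_dir, pattern = "\\.raw$")
      sample_ids <- sub("\\.raw$", "", files)
    }
  } else if (is.null(sample_ids)) {
    sample_ids <- names(volumes)
  }
  rows <- lapply(sample_ids, function(sid) {
    row <- data.frame(sample_id = sid, threshold = NA_real_, bv = NA_real_,
                      tv = NA_real_, bvtv = NA_real_, status = "failed")
    tryCatch({
      vol <- if (!is.null(volumes)) volumes[[sid]]
             else read_volume(file.path(config$volumes_dir, paste0(sid, ".raw")))
      if (is.null(vol))
        stop_cartindent(sprintf("no volume for %s", sid), "cartindent_io_error")
      bin <- suppressMessages(apply_threshold(vol, config$threshold))
      mask <- cylinder_mask(vol, config$roi)
      ratio <- bvtv(bin, mask)
      row$threshold <- attr(bin, "threshold")
      row$tv <- sum(mask$values)
      row$bv <- round(ratio * row$tv)
      row$bvtv <- ratio
      row$status <- "ok"
      row
    }, error = function(e) {
      row$status <- paste("failed:", conditionMessage(e))
      row
    })
  })
  results <- do.call(rbind, rows)
  log <- c(log, sprintf("%s: %s (BV/TV=%s)", results$sample_id, results$status,
                        signif(results$bvtv, 6)))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(results, file.path(config$out_dir, "bvtv_results.csv"),
                     row.names = FALSE)
    writeLines(log, file.path(config$out_dir, "bvtv_run.log"))
  }
  list(results = results, log = log)
}
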