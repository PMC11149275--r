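# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cartindent <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "cartindent_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' @noRd
assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              lower_open = FALSE, upper_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_cartindent(sprintf("'%s' must be a finite numeric scalar", name),
                    "cartindent_validation_error")
  lo_ok <- if (lower_open) x > lower else x >= lower
  hi_ok <- if (upper_open) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_cartindent(sprintf(
      "'%s' = %g outside allowed range %s%g, %g%s", name, x,
      if (lower_open) "(" else "[", lower, upper,
      if (upper_open) ")" else "]"), "cartindent_validation_error")
  invisible(x)
}

# Unit conversion factors into canonical units (s, micrometre, newton).
.unit_factors <- list(
  time = c(s = 1, ms = 1e-3, min = 60),
  displacement = c(um = 1, mm = 1e3, m = 1e6, nm = 1e-3),
  load = c(N = 1, mN = 1e-3, kN = 1e3, uN = 1e-6)
)

unit_factor <- function(unit, quantity) {
  tab <- .unit_factors[[quantity]]
  if (is.null(tab) || is.na(match(unit, names(tab))))
    stop_cartindent(sprintf("unknown %s unit '%s' (known: %s)", quantity, unit,
                            paste(names(tab), collapse = ", ")),
                    "cartindent_format_error")
  unname(tab[[unit]])
}

# Contiguous runs of TRUE, optionally bridging gaps of up to `gap` FALSEs.
logical_runs <- function(x, gap = 0L) {
  if (!any(x)) return(data.frame(start = integer(), end = integer()))
  r <- rle(x)
  if (gap > 0L && length(r$lengths) > 2L) {
    # flip short interior FALSE runs sandwiched between TRUE runs
    interior <- which(!r$values & r$lengths <= gap)
    interior <- interior[interior > 1L & interior < length(r$values)]
    if (length(interior)) {
      idx <- inverse.rle(r)
      ends <- cumsum(r$lengths)
      for (k in interior) idx[(ends[k] - r$lengths[k] + 1L):ends[k]] <- TRUE
      r <- rle(idx)
    }
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# trapezoidal weights on a uniform grid of n points with spacing h
trapezoid_weights <- function(n, h) {
  w <- rep(h, n)
  w[c(1L, n)] <- h / 2
  w
}
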