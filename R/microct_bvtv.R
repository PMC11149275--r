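#' Voxel volume container
#'
#' A 3-D scalar grid with physical voxel spacing, used for micro-CT bone
#' volume quantification.
#'
#' @param values 3-D numeric or logical array.
#' @param voxel_size Voxel edge length per axis, mm (scalar recycled to 3).
#' @param origin Physical offset of the grid corner, mm (length 3).
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L || length(values) == 0L)
    stop_cartindent("values must be a non-empty 3-D array", "cartindent_validation_error")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop_cartindent("voxel sizes must be positive", "cartindent_validation_error")
  structure(list(values = values, voxel_size = voxel_size,
                 origin = rep_len(as.numeric(origin), 3L)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, %.4g x %.4g x %.4g mm/voxel\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Cylindrical region of interest
#'
#' Defaults match a 5 mm diameter x 5 mm deep osteochondral defect, the ROI
#' used for subchondral bone volume quantification.
#'
#' @param axis Cylinder axis: 1/2/3 or "x"/"y"/"z".
#' @param center Centre of the cylinder in the plane normal to the axis, mm
#'   (length 2, in the order of the remaining axes). `NULL` centres the ROI
#'   in the grid when the mask is built.
#' @param diameter Cylinder diameter, mm.
#' @param depth Cylinder depth along the axis, mm.
#' @param depth_start Start of the cylinder along the axis, mm.
#' @return An object of class `cylinder_roi`.
#' @export
cylinder_roi <- function(axis = 3, center = NULL, diameter = 5, depth = 5,
                         depth_start = 0) {
  assert_scalar_num(diameter, "diameter", lower = 0, lower_open = TRUE)
  assert_scalar_num(depth, "depth", lower = 0, lower_open = TRUE)
  structure(list(axis = axis, center = center, diameter = diameter,
                 depth = depth, depth_start = depth_start),
            class = "cylinder_roi")
}

axis_index <- function(axis) {
  if (is.character(axis)) match(tolower(axis), c("x", "y", "z")) else as.integer(axis)
}

#' Binarize a grayscale volume
#'
#' Fixed-value mode marks voxels `>= value` as bone. Automatic mode uses
#' Otsu's histogram-based two-class threshold; the threshold actually used
#' is recorded in the `threshold` attribute and reported via a message, so
#' the binarization is auditable.
#'
#' @param volume A [voxel_volume()] with grayscale values.
#' @param method A numeric threshold, or `"otsu"` for the automatic method.
#' @param bins Histogram bins for the automatic method.
#' @return A binary (logical) [voxel_volume()] with attribute `threshold`.
#' @export
apply_threshold <- function(volume, method = "otsu", bins = 256L) {
  stopifnot(inherits(volume, "voxel_volume"))
  v <- volume$values
  if (is.numeric(method)) {
    thr <- method
  } else if (identical(method, "otsu")) {
    rng <- range(v)
    if (rng[1] == rng[2])
      stop_cartindent("automatic thresholding needs a non-constant volume",
                      "cartindent_validation_error")
    thr <- otsu_threshold(as.numeric(v), bins)
  } else {
    stop_cartindent("method must be a numeric threshold or \"otsu\"",
                    "cartindent_parameter_error")
  }
  out <- voxel_volume(array(v >= thr, dim = dim(v)), volume$voxel_size, volume$origin)
  attr(out, "threshold") <- thr
  message(sprintf("apply_threshold: marking voxels >= %.6g as bone", thr))
  out
}

# Otsu's method: threshold maximizing between-class variance of the
# histogram; returns the lower edge of the chosen bin so that `>= thr`
# separates the classes.
otsu_threshold <- function(x, bins = 256L) {
  rng <- range(x)
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  h <- tabulate(findInterval(x, edges, rightmost.closed = TRUE), nbins = bins)
  p <- h / sum(h)
  mids <- (edges[-1] + edges[-(bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[bins]
  between <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  k <- which.max(between)
  edges[k + 1L]   # first bin of the upper class starts here
}

#' Cylindrical voxel mask
#'
#' A voxel is included iff its centre lies inside the cylinder
#' (voxel-centre rule, no partial-volume weighting). Voxel centres are at
#' `origin + (i - 1/2) * voxel_size`.
#'
#' @param volume A [voxel_volume()] (only its grid is used), or an integer
#'   vector of grid dimensions together with `voxel_size`.
#' @param roi A [cylinder_roi()].
#' @param voxel_size Required when `volume` is a bare dimension vector.
#' @return A logical [voxel_volume()] mask.
#' @export
cylinder_mask <- function(volume, roi, voxel_size = NULL) {
  stopifnot(inherits(roi, "cylinder_roi"))
  if (inherits(volume, "voxel_volume")) {
    dims <- dim(volume$values); vs <- volume$voxel_size; org <- volume$origin
  } else {
    dims <- as.integer(volume)
    if (is.null(voxel_size))
      stop_cartindent("voxel_size is required with bare dimensions",
                      "cartindent_validation_error")
    vs <- rep_len(as.numeric(voxel_size), 3L); org <- c(0, 0, 0)
  }
  ax <- axis_index(roi$axis)
  if (is.na(ax) || !ax %in% 1:3)
    stop_cartindent("roi axis must be 1, 2, 3 or \"x\",\"y\",\"z\"",
                    "cartindent_validation_error")
  perp <- setdiff(1:3, ax)
  centers <- lapply(1:3, function(a) org[a] + (seq_len(dims[a]) - 0.5) * vs[a])
  ctr <- roi$center
  if (is.null(ctr))
    ctr <- vapply(perp, function(a) org[a] + dims[a] * vs[a] / 2, numeric(1))
  axial_ok <- centers[[ax]] >= roi$depth_start &
              centers[[ax]] <= roi$depth_start + roi$depth
  r2 <- (roi$diameter / 2)^2
  du <- centers[[perp[1]]] - ctr[1]
  dv <- centers[[perp[2]]] - ctr[2]
  plane <- outer(du^2, dv^2, "+") <= r2   # over (perp1, perp2)
  mask <- array(FALSE, dim = dims)
  # broadcast plane across the axial dimension
  ord <- order(c(perp[1], perp[2], ax))
  full <- outer(plane, axial_ok, "&")     # dims (perp1, perp2, ax)
  mask <- aperm(full, ord)
  if (!any(mask))
    stop_cartindent("cylinder ROI does not intersect the voxel grid",
                    "cartindent_validation_error")
  voxel_volume(mask, vs, org)
}

#' Bone volume fraction within a mask
#'
#' `BV/TV = (bone voxels inside the mask) / (all voxels inside the mask)`.
#'
#' @param binary A binary [voxel_volume()] (see [apply_threshold()]).
#' @param mask A logical [voxel_volume()] of identical shape (see
#'   [cylinder_mask()]).
#' @return Ratio in `[0, 1]`.
#' @export
bvtv <- function(binary, mask) {
  stopifnot(inherits(binary, "voxel_volume"), inherits(mask, "voxel_volume"))
  if (!identical(dim(binary$values), dim(mask$values)))
    stop_cartindent("binary volume and mask have different shapes",
                    "cartindent_validation_error")
  m <- as.logical(mask$values)
  tv <- sum(m)
  if (tv == 0L)
    stop_cartindent("mask is empty", "cartindent_validation_error")
  bv <- sum(as.logical(binary$values)[m])
  bv / tv
}

#' Write / read a voxel volume as raw binary plus a JSON sidecar
#'
#' The grid is written as little-endian doubles in column-major order, with
#' a `<path>.json` sidecar holding the shape, voxel size and origin, so the
#' volume is self-describing and round-trips exactly.
#'
#' @param volume A [voxel_volume()].
#' @param path Data file path; the sidecar is written to `paste0(path, ".json")`.
#' @return `write_volume` returns `path` invisibly; `read_volume` returns
#'   the reconstructed [voxel_volume()].
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(volume$values), con, size = 8, endian = "little")
  jsonlite::write_json(list(shape = dim(volume$values),
                            voxel_size_mm = volume$voxel_size,
                            origin_mm = volume$origin,
                            dtype = "float64le"),
                       paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar))
    stop_cartindent(sprintf("volume %s or its sidecar %s not found", path, sidecar),
                    "cartindent_io_error")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = prod(shape), size = 8, endian = "little")
  voxel_volume(array(vals, dim = shape), meta$voxel_size_mm, meta$origin_mm)
}
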