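#' Planar rectangular sensor array
#'
#' Describes a regular grid of rectangular piezoelectric receive elements in
#' the array plane `z = 0`, with `z` pointing into tissue. Lengths are mm,
#' frequencies MHz.
#'
#' @param nx,ny element counts along x and y.
#' @param pitch centre-to-centre element spacing (mm). Defaults to
#'   `element_width + gap`.
#' @param element_width,element_height element aperture (mm).
#' @param gap inter-element gap (mm), must be `>= 0`.
#' @param center_frequency element centre frequency (MHz).
#' @param fractional_bandwidth -6 dB fractional bandwidth (dimensionless,
#'   e.g. `1.0` for 100%).
#' @param sampling_rate per-channel sampling rate (MHz). Must exceed twice
#'   the upper band edge `center_frequency * (1 + fractional_bandwidth / 2)`.
#' @param center lateral position of the array centre `c(x, y)` (mm).
#'
#' @return An object of class `sensor_array` with element centres (n x 3,
#'   mm), grid dimensions and acquisition metadata.
#' @export
sensor_array <- function(nx, ny, element_width, element_height = element_width,
                         gap = 0, pitch = element_width + gap,
                         center_frequency = 7.8, fractional_bandwidth = 1.0,
                         sampling_rate = 40, center = c(0, 0)) {
  if (nx < 1 || ny < 1) obs_geometry_error("element counts must be >= 1")
  if (gap < 0) obs_geometry_error("inter-element gap must be >= 0")
  if (fractional_bandwidth < 0)
    obs_usage_error("fractional bandwidth must be >= 0")
  f_upper <- center_frequency * (1 + fractional_bandwidth / 2)
  if (sampling_rate <= 2 * f_upper)
    obs_usage_error(sprintf(
      "sampling rate %.3g MHz violates Nyquist for band edge %.3g MHz",
      sampling_rate, f_upper))
  x <- center[1] + (seq_len(nx) - (nx + 1) / 2) * pitch
  y <- center[2] + (seq_len(ny) - (ny + 1) / 2) * pitch
  centers <- cbind(rep(x, times = ny), rep(y, each = nx), 0)
  colnames(centers) <- c("x", "y", "z")
  structure(list(
    element_centers = centers, nx = as.integer(nx), ny = as.integer(ny),
    pitch = pitch, element_width = element_width,
    element_height = element_height, gap = gap,
    center_frequency = center_frequency,
    fractional_bandwidth = fractional_bandwidth,
    sampling_rate = sampling_rate
  ), class = "sensor_array")
}

#' The 36-element wearable device array
#'
#' 6 x 6 grid of square elements of area 2.28 mm^2 separated by 0.15 mm
#' gaps, 7.8 MHz centre frequency, 100% fractional bandwidth.
#'
#' @param sampling_rate per-channel sampling rate (MHz).
#' @return A [sensor_array()].
#' @export
obs_array <- function(sampling_rate = 40) {
  side <- sqrt(2.28)
  sensor_array(6, 6, element_width = side, gap = 0.15,
               center_frequency = 7.8, fractional_bandwidth = 1.0,
               sampling_rate = sampling_rate)
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array> %d x %d elements, pitch %.3f mm, fc %.2f MHz, bw %.0f%%, fs %.1f MHz\n",
              x$nx, x$ny, x$pitch, x$center_frequency,
              100 * x$fractional_bandwidth, x$sampling_rate))
  invisible(x)
}

#' Layered acoustic medium
#'
#' Ordered stack of plane-parallel layers below the array plane. The last
#' layer may be half-infinite (`Inf` thickness).
#'
#' @param thickness layer thicknesses (mm); all positive, only the last may
#'   be `Inf`.
#' @param sound_speed per-layer sound speed (m/s).
#' @return An object of class `layered_medium` with `$boundaries` (depths of
#'   layer tops, mm) and `$c_mm_us` (speeds in mm/us).
#' @export
layered_medium <- function(thickness, sound_speed) {
  if (length(thickness) != length(sound_speed) || length(thickness) < 1)
    obs_usage_error("thickness and sound_speed must be equal-length, length >= 1")
  L <- length(thickness)
  if (any(thickness <= 0)) obs_usage_error("all layer thicknesses must be > 0")
  if (any(!is.finite(thickness[-L])))
    obs_usage_error("only the last layer may be half-infinite")
  if (any(sound_speed <= 0) || any(!is.finite(sound_speed)))
    obs_usage_error("sound speeds must be positive and finite")
  tops <- cumsum(c(0, thickness[-L]))
  structure(list(
    thickness = thickness, sound_speed = sound_speed,
    c_mm_us = mm_per_us(sound_speed), L = L,
    boundaries = tops, z_bottom = tops + thickness
  ), class = "layered_medium")
}

#' @export
print.layered_medium <- function(x, ...) {
  cat(sprintf("<layered_medium> %d layer(s)\n", x$L))
  for (l in seq_len(x$L))
    cat(sprintf("  layer %d: z in [%.2f, %s] mm, c = %.0f m/s\n", l,
                x$boundaries[l],
                if (is.finite(x$z_bottom[l])) sprintf("%.2f", x$z_bottom[l]) else "Inf",
                x$sound_speed[l]))
  invisible(x)
}

# layer index containing depth z (> 0)
layer_of <- function(medium, z) {
  findInterval(z, medium$boundaries, left.open = FALSE, rightmost.closed = FALSE)
}

#' Multi-channel time-series container
#'
#' Raw pressure traces `p(x, y, z = 0, t)` on the element grid.
#'
#' @param samples numeric array `(nx, ny, nt)` of pressure samples.
#' @param dt sample interval (us), `> 0`.
#' @param t0 time of the first sample (us).
#' @param geometry the [sensor_array()] the data were recorded on.
#' @return Object of class `channel_data`.
#' @export
channel_data <- function(samples, dt, geometry, t0 = 0) {
  if (!is.array(samples) || length(dim(samples)) != 3)
    obs_format_error("samples must be a 3D array (element_x, element_y, time)")
  if (!all(is.finite(samples))) obs_validation_error("samples contain non-finite values")
  stopifnot_scalar_pos(dt, "dt")
  d <- dim(samples)
  if (d[1] != geometry$nx || d[2] != geometry$ny)
    obs_geometry_error(sprintf(
      "sample grid %d x %d does not match declared element grid %d x %d",
      d[1], d[2], geometry$nx, geometry$ny))
  structure(list(samples = samples, dt = dt, t0 = t0, geometry = geometry,
                 nt = d[3]), class = "channel_data")
}

#' @export
print.channel_data <- function(x, ...) {
  cat(sprintf("<channel_data> %d x %d elements, %d samples @ dt = %.4f us (t0 = %.3f us)\n",
              dim(x$samples)[1], dim(x$samples)[2], x$nt, x$dt, x$t0))
  invisible(x)
}

#' Reconstruction voxel grid
#'
#' @param nx,ny,nz voxel counts (each `>= 2`).
#' @param spacing voxel spacing `c(dx, dy, dz)` in mm.
#' @param origin position of the first voxel centre, mm.
#' @return Object of class `recon_grid` with axis vectors `$x`, `$y`, `$z`.
#' @export
recon_grid <- function(nx, ny, nz, spacing, origin = c(0, 0, 0)) {
  if (any(c(nx, ny, nz) < 2)) obs_usage_error("voxel counts must be >= 2")
  spacing <- rep_len(as.numeric(spacing), 3)
  if (any(spacing <= 0)) obs_usage_error("voxel spacing must be positive")
  structure(list(
    nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
    spacing = spacing, origin = as.numeric(origin),
    x = origin[1] + (seq_len(nx) - 1) * spacing[1],
    y = origin[2] + (seq_len(ny) - 1) * spacing[2],
    z = origin[3] + (seq_len(nz) - 1) * spacing[3]
  ), class = "recon_grid")
}

#' Reconstructed volume container
#'
#' @param voxels real 3D array of source amplitude `S(x, y, z)`.
#' @param origin first voxel centre (mm).
#' @param spacing voxel spacing `c(dx, dy, dz)` (mm).
#' @param layer_boundaries depths of medium interfaces (mm), optional.
#' @return Object of class `recon_volume` with axis vectors.
#' @export
recon_volume <- function(voxels, origin, spacing, layer_boundaries = numeric()) {
  if (!is.array(voxels) || length(dim(voxels)) != 3)
    obs_usage_error("voxels must be a 3D array")
  if (is.complex(voxels)) obs_usage_error("voxels must be real-valued")
  if (!all(is.finite(voxels))) obs_validation_error("voxels contain non-finite values")
  spacing <- rep_len(as.numeric(spacing), 3)
  if (any(spacing <= 0)) obs_usage_error("voxel spacing must be positive")
  d <- dim(voxels)
  structure(list(
    voxels = voxels, origin = as.numeric(origin), spacing = spacing,
    layer_boundaries = layer_boundaries,
    x = origin[1] + (seq_len(d[1]) - 1) * spacing[1],
    y = origin[2] + (seq_len(d[2]) - 1) * spacing[2],
    z = origin[3] + (seq_len(d[3]) - 1) * spacing[3]
  ), class = "recon_volume")
}

#' @export
print.recon_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<recon_volume> %d x %d x %d voxels, spacing (%.3f, %.3f, %.3f) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Register array geometry from tracked surface coordinates
#'
#' Fits a least-squares reference plane through tracked skin-surface marker
#' coordinates (e.g. from a magnetic tracking pen) and reports each point's
#' out-of-plane displacement, used by [pre_migrate()] to redatum traces
#' recorded on a gently curved array.
#'
#' @param marker_coords numeric matrix (n x 3) of tracked positions, mm;
#'   `n >= 3`, not collinear.
#' @return Object of class `array_registration`: `$delta_z` signed
#'   out-of-plane displacement per point (mm), `$centers_local` coordinates
#'   in the fitted plane frame, `$normal`, `$centroid`, `$max_residual`.
#' @export
register_array_geometry <- function(marker_coords) {
  p <- as.matrix(marker_coords)
  if (ncol(p) != 3 || nrow(p) < 3)
    obs_geometry_error("need at least 3 points with 3 coordinates each")
  ctr <- colMeans(p)
  q <- sweep(p, 2, ctr)
  sv <- svd(q)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    obs_geometry_error("marker points are collinear or degenerate; cannot fit a plane")
  # in-plane axes: first two right singular vectors; normal: third
  normal <- sv$v[, 3]
  # orient the normal toward +z (into tissue) when possible
  if (normal[3] < 0) normal <- -normal
  e1 <- sv$v[, 1]; e2 <- sv$v[, 2]
  local <- cbind(q %*% e1, q %*% e2, q %*% normal)
  colnames(local) <- c("u", "v", "dz")
  structure(list(
    centers_local = local, delta_z = as.numeric(local[, 3]),
    normal = normal, centroid = ctr,
    max_residual = max(abs(local[, 3])),
    rms_residual = sqrt(mean(local[, 3]^2))
  ), class = "array_registration")
}

#' @export
print.array_registration <- function(x, ...) {
  cat(sprintf("<array_registration> %d points, max out-of-plane %.4f mm (rms %.4f mm)\n",
              nrow(x$centers_local), x$max_residual, x$rms_residual))
  invisible(x)
}
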