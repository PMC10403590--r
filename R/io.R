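#' Write a channel-data container
#'
#' Serializes a [channel_data()] record to the package's native single-file
#' container: a versioned, schema-validated list holding the sample cube,
#' the element geometry, and the acquisition attributes (`t0`, `dt`, `fc`,
#' `bw`, `fs`). The round trip through [read_channel_data()] is bit-exact.
#'
#' @param data a [channel_data()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_channel_data <- function(data, path) {
  if (!inherits(data, "channel_data"))
    obs_usage_error("'data' must be a channel_data object")
  g <- data$geometry
  payload <- list(
    format = "obscope-channel", version = 1L,
    channels = data$samples,
    geometry = list(
      centers = g$element_centers, nx = g$nx, ny = g$ny, pitch = g$pitch,
      element_width = g$element_width, element_height = g$element_height,
      gap = g$gap),
    attrs = list(t0 = data$t0, dt = data$dt, fc = g$center_frequency,
                 bw = g$fractional_bandwidth, fs = g$sampling_rate))
  saveRDS(payload, path)
  invisible(path)
}

#' Read a channel-data container
#'
#' Validates the container schema and rebuilds the [channel_data()] object.
#' A missing dataset or attribute raises a format error naming the missing
#' key; a mismatch between stored traces and the declared element grid
#' raises a geometry error.
#'
#' @param path file written by [write_channel_data()].
#' @return A [channel_data()] object.
#' @export
read_channel_data <- function(path) {
  if (!file.exists(path)) obs_format_error(sprintf("file not found: %s", path))
  payload <- tryCatch(readRDS(path),
                      error = function(e) obs_format_error(
                        sprintf("not a readable container: %s", conditionMessage(e))))
  if (!is.list(payload) || !identical(payload$format, "obscope-channel"))
    obs_format_error("missing or wrong 'format' marker; not an obscope channel container")
  for (key in c("channels", "geometry", "attrs"))
    if (is.null(payload[[key]]))
      obs_format_error(sprintf("container is missing required dataset '%s'", key))
  for (key in c("nx", "ny", "pitch", "element_width", "element_height", "gap"))
    if (is.null(payload$geometry[[key]]))
      obs_format_error(sprintf("container is missing geometry field '%s'", key))
  for (key in c("t0", "dt", "fc", "bw", "fs"))
    if (is.null(payload$attrs[[key]]))
      obs_format_error(sprintf("container is missing attribute '%s'", key))
  a <- payload$attrs; g <- payload$geometry
  d <- dim(payload$channels)
  if (is.null(d) || length(d) != 3)
    obs_format_error("'channels' must be a 3D array (element_x, element_y, time)")
  if (d[1] != g$nx || d[2] != g$ny)
    obs_geometry_error(sprintf(
      "container holds %d traces but declares a %d x %d grid",
      d[1] * d[2], g$nx, g$ny))
  arr <- sensor_array(g$nx, g$ny, element_width = g$element_width,
                      element_height = g$element_height, gap = g$gap,
                      pitch = g$pitch, center_frequency = a$fc,
                      fractional_bandwidth = a$bw, sampling_rate = a$fs)
  channel_data(payload$channels, dt = a$dt, geometry = arr, t0 = a$t0)
}

#' Export a reconstructed volume
#'
#' Writes a [recon_volume()] either as a multi-slice 32-bit float TIFF stack
#' (one image per z slice, for slice-wise inspection; values are min-max
#' scaled to \[0, 1\] as TIFF float storage outside that range is undefined)
#' or as a NIfTI file carrying the raw values with the voxel spacing encoded
#' in the header (for spacing-aware viewers).
#'
#' @param volume a [recon_volume()].
#' @param path output file path.
#' @param format `"tiff_stack"` or `"nifti"`.
#' @return `path`, invisibly.
#' @export
save_volume <- function(volume, path, format = c("tiff_stack", "nifti")) {
  if (!inherits(volume, "recon_volume"))
    obs_usage_error("'volume' must be a recon_volume object")
  format <- tryCatch(match.arg(format),
                     error = function(e) obs_usage_error(
                       sprintf("unsupported volume format '%s'", format[1])))
  d <- dim(volume$voxels)
  if (any(d == 0)) obs_usage_error("cannot export a zero-size volume")
  if (format == "tiff_stack") {
    v <- volume$voxels
    rg <- range(v)
    if (rg[1] < 0 || rg[2] > 1)
      v <- (v - rg[1]) / max(rg[2] - rg[1], .Machine$double.eps)
    slices <- lapply(seq_len(d[3]), function(k) v[, , k])
    tiff::writeTIFF(slices, path, bits.per.sample = 32L)
  } else {
    img <- RNifti::asNifti(volume$voxels)
    RNifti::pixdim(img) <- volume$spacing
    RNifti::writeNifti(img, path)
  }
  invisible(path)
}
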