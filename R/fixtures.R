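#' Layered-medium simulation fixture for the reconstruction comparison
#'
#' Packaged synthetic study reproducing the layered-medium numerical
#' comparison between the Fourier-domain (PS-NUFFT) reconstruction and the
#' delay-and-sum baseline: a dense 32 x 32 simulation grid spanning the
#' ~10 mm device footprint at the device's 7.8 MHz / 100% bandwidth, a
#' two-layer medium (1 mm device standoff — PDMS encapsulation plus
#' coupling — at 1030 m/s over soft tissue at 1540 m/s), a point target at
#' lateral position x = 3.5 mm and 5 mm depth,
#' a second point and a short vessel tube as distributed structure, and
#' additive channel noise at 20 dB peak SNR. Coordinates are device-framed:
#' the origin sits at the array corner, so the footprint spans
#' \[0, 9.92\] mm and the array centre is at 4.96 mm.
#'
#' The comparison arm mirrors the traditional time-domain beamformer, which
#' treats the skin as a homogeneous medium: [fixture_das()] runs
#' [reconstruct_das()] against a single-layer 1540 m/s medium model, while
#' the data are simulated in the true two-layer medium.
#'
#' @name fig_fixture
NULL

#' @rdname fig_fixture
#' @export
fixture_medium <- function() layered_medium(c(1, Inf), c(1030, 1540))

#' @rdname fig_fixture
#' @param sampling_rate MHz.
#' @export
fixture_array <- function(sampling_rate = 40) {
  sensor_array(32, 32, element_width = 0.2, gap = 0.12, pitch = 0.32,
               center_frequency = 7.8, fractional_bandwidth = 1.0,
               sampling_rate = sampling_rate, center = c(4.96, 4.96))
}

#' @rdname fig_fixture
#' @export
fixture_phantom <- function() {
  make_phantom(
    points = rbind(c(3.5, 4.96, 5, 1.0),
                   c(7.0, 4.96, 5, 1.0)),
    vessels = list(list(axis = rbind(c(6.5, 2.5, 6.5), c(6.5, 7.5, 6.5)),
                        radius = 0.4, amplitude = 0.6)))
}

#' @rdname fig_fixture
#' @param seed RNG seed for the channel noise.
#' @param snr_db per-channel peak signal-to-noise ratio (dB).
#' @export
fixture_channels <- function(seed = 1, snr_db = 20) {
  arr <- fixture_array()
  med <- fixture_medium()
  ph <- fixture_phantom()
  clean <- simulate_channels(ph, arr, med, nt = 512)
  sdn <- max(abs(clean$samples)) * 10^(-snr_db / 20)
  noisy <- simulate_channels(ph, arr, med, nt = 512, noise_sd = sdn, seed = seed)
  noisy
}

#' @rdname fig_fixture
#' @param volume a [recon_volume()] on which to place the ROIs.
#' @details `fixture_rois()` places a 0.6 mm signal cube centred on the
#'   point target at (3.5, 4.96, 5) mm and a 2 mm background cube at
#'   (2.5, 2.0, 8) mm, clear of all fixture structures.
#' @export
fixture_rois <- function(volume) {
  sig <- box_mask(volume, c(3.5, 4.96, 5), 0.3)
  bg <- box_mask(volume, c(2.5, 2.0, 8), 1)
  roi_spec(sig, bg)
}

#' @rdname fig_fixture
#' @details `fixture_resolution()` measures the -6 dB width of the
#'   depth-projected lateral profile ([mip_lateral_profile()]) through the
#'   x = 3.5 mm target, windowed to x in \[1.5, 5.5\] mm so neighbouring
#'   structures do not enter the cut.
#' @export
fixture_resolution <- function(volume) {
  pr <- mip_lateral_profile(volume, 4.96, c(3.5, 8))
  keep <- pr$axis >= 1.5 & pr$axis <= 5.5
  profile_fwhm(pr$profile[keep], pr$axis[keep])
}

#' @rdname fig_fixture
#' @param data [channel_data()] from [fixture_channels()].
#' @param grid optional [recon_grid()]; defaults to 64 x 64 x 150 voxels
#'   over the footprint and 12 mm depth.
#' @details `fixture_das()` is the traditional comparison arm: DAS run under
#'   the homogeneous-skin assumption (single 1540 m/s layer), the path model
#'   the Fourier-domain method is benchmarked against.
#' @export
fixture_das <- function(data, grid = NULL) {
  if (is.null(grid))
    grid <- recon_grid(64, 64, 150, spacing = c(9.92 / 64, 9.92 / 64, 0.08),
                       origin = c(9.92 / 128, 9.92 / 128, 0.08))
  reconstruct_das(data, layered_medium(Inf, 1540), grid, das_config())
}
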