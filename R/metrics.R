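#' Signal/background region-of-interest specification
#'
#' @param signal,background logical masks (same shape as the target volume)
#'   or integer index vectors; must be non-empty and disjoint.
#' @return A `roi_spec` list.
#' @export
roi_spec <- function(signal, background) {
  sig <- if (is.logical(signal)) which(signal) else as.integer(signal)
  bg <- if (is.logical(background)) which(background) else as.integer(background)
  if (!length(sig) || !length(bg)) obs_usage_error("ROI masks must be non-empty")
  if (length(intersect(sig, bg))) obs_usage_error("ROI masks must be disjoint")
  structure(list(signal = sig, background = bg), class = "roi_spec")
}

# box mask builder over a recon_volume's axes
box_mask <- function(volume, center, halfwidth) {
  hw <- rep_len(halfwidth, 3)
  inx <- abs(volume$x - center[1]) <= hw[1]
  iny <- abs(volume$y - center[2]) <= hw[2]
  inz <- abs(volume$z - center[3]) <= hw[3]
  array(outer(outer(inx, iny, "&"), inz, "&"), dim = dim(volume$voxels))
}

#' -6 dB full width of an amplitude profile
#'
#' Width between the sub-sample (linearly interpolated) crossings of
#' `max * 10^(threshold_db / 20)` on either side of the unique global
#' maximum. With the default -6 dB this is the full width at half maximum
#' of the amplitude profile.
#'
#' @param profile 1D amplitude array with a unique interior global maximum.
#' @param axis positions of the samples (mm), strictly increasing.
#' @param threshold_db amplitude threshold in dB (default -6).
#' @return width in mm.
#' @export
profile_fwhm <- function(profile, axis, threshold_db = -6) {
  n <- length(profile)
  if (length(axis) != n) obs_usage_error("profile and axis lengths differ")
  imax <- which(profile == max(profile))
  if (length(imax) != 1 || imax == 1 || imax == n)
    obs_measure_error("profile needs a unique interior global maximum")
  thr <- max(profile) * 10^(threshold_db / 20)
  cross <- function(idx_seq) {
    for (i in idx_seq) {
      a <- profile[i]; b <- profile[i + 1]
      lo <- min(a, b); hi <- max(a, b)
      if (lo <= thr && hi >= thr && a != b) {
        f <- (thr - a) / (b - a)
        return(axis[i] + f * (axis[i + 1] - axis[i]))
      }
    }
    NA_real_
  }
  left <- cross(rev(seq_len(imax - 1)))
  right <- cross(imax:(n - 1))
  if (is.na(left) || is.na(right))
    obs_measure_error("profile does not cross the threshold on both sides")
  right - left
}

#' Lateral amplitude profile through the volume maximum
#'
#' Extracts the |S| profile along x at the (y, z) location of the global
#' maximum (or a supplied point), the "Line-A"-style cut used for
#' resolution measurements.
#'
#' @param volume a [recon_volume()].
#' @param at optional `c(y, z)` (mm) through which to cut; default: through
#'   the global maximum of |S|.
#' @return list with `$axis` (x positions, mm) and `$profile` (|S|).
#' @export
lateral_profile <- function(volume, at = NULL) {
  v <- abs(volume$voxels)
  if (is.null(at)) {
    w <- which(v == max(v), arr.ind = TRUE)[1, ]
    iy <- w[2]; iz <- w[3]
  } else {
    iy <- which.min(abs(volume$y - at[1]))
    iz <- which.min(abs(volume$z - at[2]))
  }
  list(axis = volume$x, profile = v[, iy, iz])
}

#' Depth-projected lateral profile through a target
#'
#' Lateral amplitude profile robust to axial mislocation of a reconstructed
#' target: |S| is maximum-intensity projected over a depth window at the
#' target's y position, then read along x. A defocused or axially displaced
#' response still projects onto its full lateral support, so the -6 dB width
#' of this profile measures the lateral size of the rendered target.
#'
#' @param volume a [recon_volume()].
#' @param y lateral y position of the cut (mm).
#' @param z_range `c(zmin, zmax)` depth window (mm).
#' @return list with `$axis` (x, mm) and `$profile`.
#' @export
mip_lateral_profile <- function(volume, y, z_range) {
  iy <- which.min(abs(volume$y - y))
  zz <- volume$z >= z_range[1] & volume$z <= z_range[2]
  if (!any(zz)) obs_usage_error("depth window contains no slices")
  list(axis = volume$x,
       profile = apply(abs(volume$voxels[, iy, zz, drop = FALSE]), 1, max))
}

#' Contrast-to-noise ratio (dB)
#'
#' `20 log10(|mean(signal) - mean(background)| / sd(background))`.
#'
#' @param volume a [recon_volume()] (its |S| values are used).
#' @param rois a [roi_spec()].
#' @return CNR in dB.
#' @export
cnr <- function(volume, rois) {
  v <- abs(volume$voxels)
  s <- v[rois$signal]; b <- v[rois$background]
  sdb <- sd(b)
  if (!is.finite(sdb) || sdb <= 0)
    obs_measure_error("background variance is zero; CNR undefined")
  val <- 20 * log10(abs(mean(s) - mean(b)) / sdb)
  if (!is.finite(val)) obs_measure_error("CNR undefined for identical ROI statistics")
  val
}

#' Generalized contrast-to-noise ratio
#'
#' One minus the overlap of the unit-mass amplitude histograms of the two
#' ROIs over shared bin edges; bounded in \[0, 1\] and invariant to any
#' monotone amplitude remapping applied jointly to both ROIs.
#'
#' @param volume a [recon_volume()].
#' @param rois a [roi_spec()].
#' @param bins number of shared histogram bins (default 100).
#' @return gCNR in \[0, 1\].
#' @export
gcnr <- function(volume, rois, bins = 100L) {
  v <- abs(volume$voxels)
  s <- v[rois$signal]; b <- v[rois$background]
  if (!length(s) || !length(b)) obs_usage_error("empty ROI")
  if (length(s) < bins || length(b) < bins)
    warning("fewer ROI samples than histogram bins; gCNR estimate is coarse")
  edges <- seq(min(s, b), max(s, b), length.out = bins + 1)
  if (edges[1] == edges[bins + 1]) return(0)  # identical constant ROIs overlap fully
  hs <- tabulate(pmin(pmax(findInterval(s, edges, rightmost.closed = TRUE), 1), bins),
                 nbins = bins) / length(s)
  hb <- tabulate(pmin(pmax(findInterval(b, edges, rightmost.closed = TRUE), 1), bins),
                 nbins = bins) / length(b)
  1 - sum(pmin(hs, hb))
}
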