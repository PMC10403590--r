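#' Receive sensitivity field of a rectangular element
#'
#' Evaluates the reciprocal transmit field of a rectangular aperture at a
#' parallel plane: the discretized Rayleigh surface integral of
#' `exp(i k r) / r` over the element face at a single frequency. The
#' element is discretized with at least `sub_per_wavelength` sub-elements
#' per wavelength along each edge.
#'
#' @param width,height element aperture (mm); must be positive (a vanishing
#'   aperture degenerates to an isotropic point receiver — pass
#'   `width = height = 0` explicitly for that limit).
#' @param depth evaluation plane depth (mm), > 0.
#' @param frequency evaluation frequency (MHz).
#' @param c sound speed (m/s).
#' @param extent lateral half-extent of the map (mm).
#' @param spacing map pixel spacing (mm).
#' @param sub_per_wavelength aperture discretization density.
#' @return Object of class `beam_pattern`: `$map` (|field|, nx x ny),
#'   axes `$x`, `$y`, `$depth`, `$frequency`, `$spacing`.
#' @export
element_receive_pattern <- function(width, height = width, depth = 1,
                                    frequency = 7.8, c = 1540,
                                    extent = 3, spacing = 0.05,
                                    sub_per_wavelength = 20) {
  if (depth <= 0) obs_usage_error("evaluation depth must be > 0")
  if (width < 0 || height < 0) obs_usage_error("aperture must be >= 0")
  ct <- mm_per_us(c)
  k <- 2 * pi * frequency / ct  # rad/mm
  lambda <- ct / frequency
  xh <- seq(0, extent, by = spacing)  # quarter map; element is symmetric
  if (width == 0 || height == 0) {
    sx <- 0; sy <- 0
  } else {
    nsx <- max(2L, ceiling(width / (lambda / sub_per_wavelength)))
    nsy <- max(2L, ceiling(height / (lambda / sub_per_wavelength)))
    sx <- (seq_len(nsx) - (nsx + 1) / 2) * (width / nsx)
    sy <- (seq_len(nsy) - (nsy + 1) / 2) * (height / nsy)
  }
  q <- rayleigh_quarter_cpp(xh, xh, depth, k, sx, sy)
  n <- length(xh)
  full <- matrix(0i, 2 * n - 1, 2 * n - 1)
  full[n:(2 * n - 1), n:(2 * n - 1)] <- q
  full[n:1, n:(2 * n - 1)] <- q
  full[n:(2 * n - 1), n:1] <- q
  full[n:1, n:1] <- q
  ax <- c(-rev(xh[-1]), xh)
  structure(list(map = Mod(full), field = full, x = ax, y = ax, depth = depth,
                 frequency = frequency, spacing = spacing),
            class = "beam_pattern")
}

#' @export
print.beam_pattern <- function(x, ...) {
  cat(sprintf("<beam_pattern> %d x %d @ %.3f mm, depth %.2f mm, %.2f MHz\n",
              nrow(x$map), ncol(x$map), x$spacing, x$depth, x$frequency))
  invisible(x)
}

#' Area of the receive field above a sensitivity threshold
#'
#' Summed pixel area where the field magnitude is within `|threshold_db|`
#' of the map maximum. The dB level is taken on intensity
#' (`10^(threshold_db / 20)` on amplitude), matching the effective
#' spatial-response convention used for the element characterization.
#'
#' @param pattern a `beam_pattern` (or the array-AFOV map).
#' @param threshold_db threshold (default -12 dB).
#' @return area in mm^2.
#' @export
area_above_threshold <- function(pattern, threshold_db = -12) {
  m <- pattern$map
  if (max(m) <= 0) obs_usage_error("pattern has no positive values")
  thr <- max(m) * 10^(threshold_db / 20)
  sum(m >= thr) * pattern$spacing^2
}

#' Superimposed array receive field and AFOV statistics
#'
#' Computes a single-element sensitivity field once and superimposes it
#' translated to every element centre (elements are identical and the
#' medium homogeneous). With `superposition = "coherent"` (default) the
#' complex fields are summed before taking the magnitude — the array
#' treated as one aperture, which is how the device's field-of-view maps
#' are characterized; `"incoherent"` sums per-element magnitudes (separate
#' receive channels). Statistics are taken over the effective AFOV mask —
#' pixels within -12 dB of the array-map maximum: the mean-versus-max level
#' (dB) and the standard deviation of the level (dB).
#'
#' @param array a [sensor_array()].
#' @param depth evaluation depth (mm).
#' @param c sound speed (m/s).
#' @param margin lateral margin beyond the element centres (mm).
#' @param mask_db effective-AFOV threshold (dB, default -12).
#' @param superposition `"coherent"` or `"incoherent"`.
#' @param sub_per_wavelength aperture discretization density.
#' @return list with `$map` (a `beam_pattern` over the array),
#'   `$mean_vs_max_db`, `$sd_db`, `$effective_area_mm2`.
#' @export
array_afov <- function(array, depth = 1, c = 1540, margin = 2,
                       mask_db = -12,
                       superposition = c("coherent", "incoherent"),
                       sub_per_wavelength = 8) {
  superposition <- match.arg(superposition)
  px <- array$pitch
  nsub <- 32L
  spacing <- px / nsub  # element centres land on the pixel lattice
  half_span <- (max(array$nx, array$ny) - 1) / 2 * px
  ext_elem <- margin + array$element_width  # single-element map reach
  single <- element_receive_pattern(array$element_width, array$element_height,
                                    depth = depth, frequency = array$center_frequency,
                                    c = c, extent = half_span + ext_elem,
                                    spacing = spacing,
                                    sub_per_wavelength = sub_per_wavelength)
  n <- length(single$x)
  base <- if (superposition == "coherent") single$field else single$map
  total <- matrix(if (is.complex(base)) 0i else 0, n, n)
  ctr <- colMeans(array$element_centers[, 1:2, drop = FALSE])
  for (e in seq_len(nrow(array$element_centers))) {
    sxy <- (array$element_centers[e, 1:2] - ctr) / spacing
    sx <- round(sxy[1]); sy <- round(sxy[2])
    xs <- seq_len(n) - sx; ys <- seq_len(n) - sy
    okx <- xs >= 1 & xs <= n; oky <- ys >= 1 & ys <= n
    total[okx, oky] <- total[okx, oky] + base[xs[okx], ys[oky]]
  }
  total <- Mod(total)
  mask <- total >= max(total) * 10^(mask_db / 20)
  lev <- 20 * log10(total[mask] / max(total))
  stats <- list(mean_vs_max_db = 20 * log10(mean(total[mask]) / max(total)),
                sd_db = sd(lev),
                effective_area_mm2 = sum(mask) * spacing^2)
  map <- structure(list(map = total, x = single$x, y = single$y, depth = depth,
                        frequency = array$center_frequency, spacing = spacing),
                   class = "beam_pattern")
  c(list(map = map), stats)
}

#' Axial resolution from the bandwidth criterion
#'
#' Pulse-length criterion: axial resolution = `criterion * c / B` with `B`
#' the absolute -6 dB bandwidth (`center_frequency * fractional_bandwidth`).
#' The default criterion constant 1 corresponds to the two-way half-pulse
#' convention used for the device characterization.
#'
#' @param center_frequency MHz.
#' @param fractional_bandwidth dimensionless (> 0).
#' @param c sound speed (m/s).
#' @param criterion criterion constant (default 1).
#' @return axial resolution in um.
#' @export
axial_resolution <- function(center_frequency, fractional_bandwidth, c = 1500,
                             criterion = 1) {
  if (fractional_bandwidth <= 0) obs_usage_error("bandwidth must be > 0")
  bw_abs <- center_frequency * fractional_bandwidth  # MHz
  1000 * criterion * mm_per_us(c) / bw_abs
}
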