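#' Non-uniform spectral resampling configuration
#'
#' Controls the windowed-sinc interpolation that maps the temporal-frequency
#' axis onto a uniform depth-wavenumber grid.
#'
#' @param kernel_halfwidth half-width of the windowed-sinc kernel in
#'   frequency samples (>= 1; default 6).
#' @param downsample integer down-sampling factor applied to the output kz
#'   grid (>= 1; default 1, i.e. none).
#' @param evanescent_policy handling of non-propagating components; only
#'   `"zero"` is supported (exponential growth would amplify noise).
#' @param pad_time temporal zero-padding factor before the forward transform
#'   (suppresses wrap-around).
#' @return A `nufft_config` list.
#' @export
nufft_config <- function(kernel_halfwidth = 6L, downsample = 1L,
                         evanescent_policy = "zero", pad_time = 2) {
  if (kernel_halfwidth < 1) obs_usage_error("kernel_halfwidth must be >= 1")
  if (downsample < 1) obs_usage_error("downsample factor must be >= 1")
  if (!identical(evanescent_policy, "zero"))
    obs_usage_error("only the 'zero' evanescent policy is supported")
  structure(list(kernel_halfwidth = as.integer(kernel_halfwidth),
                 downsample = as.integer(downsample),
                 evanescent_policy = "zero", pad_time = pad_time),
            class = "nufft_config")
}

# spectral field container (internal constructor)
spectral_field <- function(values, kx, ky, waxis, domain, z_ref, dx, dy) {
  structure(list(values = values, kx = kx, ky = ky, waxis = waxis,
                 domain = domain, z_ref = z_ref, dx = dx, dy = dy),
            class = "spectral_field")
}

#' @export
print.spectral_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<spectral_field> %d x %d x %d, domain '%s', reference depth %.2f mm\n",
              d[1], d[2], d[3], x$domain, x$z_ref))
  invisible(x)
}

#' Forward 3D spectral transform of channel data
#'
#' Transforms the recorded pressure `p(x, y, z = 0, t)` into the
#' wavenumber-frequency domain `P(kx, ky, z = 0, omega)` using spatial
#' kernels `exp(-i kx x) exp(-i ky y)` and the temporal kernel
#' `exp(+i omega t)`. Time is zero-padded by `pad_time` before the
#' transform. The constant normalisation of the continuous transform is
#' absorbed into the inverse; only relative amplitudes are carried.
#'
#' @param data a [channel_data()] record on a uniform element grid.
#' @param cfg a [nufft_config()].
#' @return A `spectral_field` in the omega domain at `z_ref = 0`.
#' @export
forward_spectrum <- function(data, cfg = nufft_config()) {
  g <- data$geometry
  # uniform-grid precondition: centres must form the regular pitch lattice
  ec <- g$element_centers
  px <- unique(round(diff(sort(unique(ec[, 1]))), 9))
  py <- unique(round(diff(sort(unique(ec[, 2]))), 9))
  if ((length(px) > 1) || (length(py) > 1) || any(abs(ec[, 3]) > 1e-9))
    obs_error(paste("element grid is non-uniform or non-planar;",
                    "run pre_migrate() / registration first"),
              "obscope_precondition_error")
  d <- dim(data$samples)
  nt2 <- max(nextn(ceiling(d[3] * cfg$pad_time), c(2, 3, 5)), d[3])
  p <- array(0, dim = c(d[1], d[2], nt2))
  p[, , seq_len(d[3])] <- data$samples
  # temporal kernel exp(+i w t): index-reverse the time axis, then fft
  rev_idx <- c(1L, if (nt2 > 1) nt2:2L)
  P <- fft(p[, , rev_idx])
  kx <- 2 * pi * fft_freq(d[1], g$pitch)
  ky <- 2 * pi * fft_freq(d[2], g$pitch)
  omega <- 2 * pi * fft_freq(nt2, data$dt)
  if (data$t0 != 0) {
    ph <- exp(1i * omega * data$t0)
    P <- P * array(rep(ph, each = d[1] * d[2]), dim = dim(P))
  }
  spectral_field(P, kx, ky, omega, domain = "omega", z_ref = 0,
                 dx = g$pitch, dy = g$pitch)
}

#' Phase-shift wavefield extrapolation through the layer stack
#'
#' Propagates the recorded angular spectrum from the array plane down to the
#' top of `target_layer` by multiplying, for each traversed layer, the
#' phase factor `exp(-i sign(omega) kz_l d_l)` with
#' `kz_l = sqrt((omega/c_l)^2 - kx^2 - ky^2)` evaluated with that layer's
#' sound speed. Evanescent components (`(omega/c_l)^2 < kx^2 + ky^2`) are
#' zeroed. The field's reference depth advances to the summed thickness.
#'
#' @param spec a `spectral_field` in the omega domain.
#' @param medium a [layered_medium()].
#' @param target_layer index of the layer whose top boundary to extrapolate
#'   onto (1 = array plane, i.e. identity).
#' @return A `spectral_field` in the omega domain at the new reference depth.
#' @export
extrapolate_layers <- function(spec, medium, target_layer) {
  if (spec$domain != "omega")
    obs_usage_error("extrapolation operates on the omega-domain field")
  if (target_layer < 1 || target_layer > medium$L)
    obs_usage_error("target_layer out of range")
  if (target_layer == 1) return(spec)
  d <- dim(spec$values)
  krho2 <- array(outer(spec$kx^2, spec$ky^2, "+"), dim = d)
  womega <- array(rep(spec$waxis, each = d[1] * d[2]), dim = d)
  P <- spec$values
  for (l in seq_len(target_layer - 1)) {
    cl <- medium$c_mm_us[l]
    kz2 <- (womega / cl)^2 - krho2
    prop <- kz2 > 0
    kz <- sqrt(pmax(kz2, 0))
    P <- P * prop * exp(-1i * sign(womega) * kz * medium$thickness[l])
  }
  spectral_field(P, spec$kx, spec$ky, spec$waxis, domain = "omega",
                 z_ref = medium$boundaries[target_layer],
                 dx = spec$dx, dy = spec$dy)
}

#' Non-uniform (Stolt) spectral resampling onto a uniform kz grid
#'
#' Implements the dispersion-relation change of variables
#' `omega(kx, ky, kz) = c sqrt(kx^2 + ky^2 + kz^2)` (with the sign pairing
#' required by the `exp(+i omega t)` analysis convention) scaled by the
#' Jacobian `c kz / sqrt(kx^2 + ky^2 + kz^2)`. Samples of the omega-domain
#' field at the mapped, non-uniform frequencies are obtained with a
#' windowed-sinc interpolation basis; output lands on a uniform kz grid
#' ready for an inverse FFT.
#'
#' @param spec a `spectral_field` in the omega domain.
#' @param c_layer sound speed of the target layer (m/s).
#' @param nz,dz depth sample count and spacing (mm) defining the kz grid.
#' @param cfg a [nufft_config()].
#' @return A `spectral_field` in the kz domain (dimensions nx x ny x
#'   nz/downsample).
#' @export
stolt_resample <- function(spec, c_layer, nz, dz, cfg = nufft_config()) {
  if (spec$domain != "omega")
    obs_usage_error("stolt_resample expects an omega-domain field")
  ct <- mm_per_us(c_layer)
  d <- dim(spec$values)
  nw <- d[3]
  dw <- spec$waxis[2] - spec$waxis[1]
  if (cfg$downsample > 1) {
    if (nz %% cfg$downsample != 0)
      obs_config_error("nz must be divisible by the down-sampling factor")
    nz <- nz %/% cfg$downsample
    dz <- dz * cfg$downsample
  }
  kz <- 2 * pi * fft_freq(nz, dz)
  # check the omega band can resolve the kz grid at all
  if (ct * min(abs(kz[kz != 0])) > max(abs(spec$waxis)))
    obs_config_error("kz grid is not resolvable from the omega band")
  J <- cfg$kernel_halfwidth
  vals <- stolt_gather_cpp(as.vector(spec$values), d[1], d[2], nw,
                           spec$kx, spec$ky, kz, ct, dw, J)
  out <- array(vals, dim = c(d[1], d[2], nz))
  spectral_field(out, spec$kx, spec$ky, kz, domain = "kz",
                 z_ref = spec$z_ref, dx = spec$dx, dy = spec$dy)
}

#' Inverse transform of the resampled spectrum to image space
#'
#' Applies the inverse 3D FFT (kernels `exp(+i k r)`) to the uniform
#' `(kx, ky, kz)` spectrum and keeps the depth slab of the current layer.
#' Lateral resolution of the rendered grid can be refined by zero-padding
#' the `(kx, ky)` spectrum (`upsample`), which sinc-interpolates the image
#' without adding information.
#'
#' @param spec a `spectral_field` in the kz domain.
#' @param layer_bounds `c(z_top, z_bottom)` absolute depths (mm) of the slab
#'   to keep; must have positive extent.
#' @param upsample integer lateral zero-padding factor (>= 1).
#' @param include_upper keep a depth sample falling exactly on the lower
#'   boundary (set `FALSE` for non-final layers so adjacent slabs do not
#'   duplicate the interface slice).
#' @return A [recon_volume()] covering the requested slab.
#' @export
invert_to_volume <- function(spec, layer_bounds, upsample = 1L,
                             include_upper = TRUE) {
  if (spec$domain != "kz")
    obs_usage_error("invert_to_volume expects a kz-domain field")
  if (diff(layer_bounds) <= 0) obs_usage_error("empty layer interval")
  d <- dim(spec$values)
  u <- as.integer(upsample)
  P <- spec$values
  if (u > 1) {
    big <- array(0i, dim = c(d[1] * u, d[2] * u, d[3]))
    # copy fft-ordered quadrants (split at the Nyquist fold)
    hx <- ceiling(d[1] / 2); hy <- ceiling(d[2] / 2)
    sx <- c(seq_len(hx), d[1] * u - (d[1] - hx) + seq_len(d[1] - hx))
    sy <- c(seq_len(hy), d[2] * u - (d[2] - hy) + seq_len(d[2] - hy))
    big[sx, sy, ] <- P[c(seq_len(hx), hx + seq_len(d[1] - hx)),
                       c(seq_len(hy), hy + seq_len(d[2] - hy)), ]
    P <- big * u * u
  }
  S <- Re(fft(P, inverse = TRUE)) / length(P)
  dzv <- 2 * pi / (length(spec$waxis) * abs(spec$waxis[2] - spec$waxis[1]))
  dxv <- spec$dx / u; dyv <- spec$dy / u
  z <- spec$z_ref + (seq_len(dim(S)[3]) - 1) * dzv
  keep <- which(z >= layer_bounds[1] - 1e-9 &
                  (if (include_upper) z <= layer_bounds[2] + 1e-9
                   else z < layer_bounds[2] - 1e-9))
  if (!length(keep)) obs_usage_error("layer interval contains no depth samples")
  recon_volume(S[, , keep, drop = FALSE],
               origin = c(x0_of(spec), y0_of(spec), z[keep[1]]),
               spacing = c(dxv, dyv, dzv))
}

# physical coordinate of the first lateral sample: the transform is indexed
# from the first element, so the image origin coincides with it
x0_of <- function(spec) attr(spec, "x0") %||% 0
y0_of <- function(spec) attr(spec, "y0") %||% 0
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Phase-shift NUFFT volumetric reconstruction for layered media
#'
#' Composes the four stages — forward spectral transform, per-layer
#' phase-shift extrapolation, Jacobian-weighted non-uniform resampling onto
#' a uniform kz grid, and inverse FFT — and concatenates the per-layer
#' slabs into one volume. Total cost is O(L n^3 log(n^3)).
#'
#' @param data a [channel_data()] record (planar uniform grid; apply
#'   [pre_migrate()] first for curved arrays).
#' @param medium a [layered_medium()].
#' @param nz,dz depth sample count and spacing (mm); `nz * dz` must cover
#'   the echo depth range of interest.
#' @param upsample lateral spectral zero-padding factor for rendering.
#' @param cfg a [nufft_config()].
#' @param zmax deepest depth to keep (mm); defaults to `nz * dz`.
#' @return A [recon_volume()] spanning depth `(0, zmax]`.
#' @export
reconstruct_psnufft <- function(data, medium, nz, dz, upsample = 1L,
                                cfg = nufft_config(), zmax = nz * dz) {
  spec0 <- forward_spectrum(data, cfg)
  g <- data$geometry
  x0 <- min(g$element_centers[, 1]); y0 <- min(g$element_centers[, 2])
  slabs <- vector("list", medium$L)
  for (l in seq_len(medium$L)) {
    spec_l <- extrapolate_layers(spec0, medium, l)
    speck <- stolt_resample(spec_l, medium$sound_speed[l], nz, dz, cfg)
    attr(speck, "x0") <- x0; attr(speck, "y0") <- y0
    zb <- c(medium$boundaries[l],
            if (l < medium$L) medium$z_bottom[l] else zmax)
    if (zb[1] >= zmax) break
    zb[2] <- min(zb[2], zmax)
    slabs[[l]] <- invert_to_volume(speck, zb, upsample = upsample,
                                   include_upper = (l == medium$L))
  }
  slabs <- Filter(Negate(is.null), slabs)
  vox <- do.call(abind3, lapply(slabs, function(s) s$voxels))
  first <- slabs[[1]]
  recon_volume(vox, origin = first$origin, spacing = first$spacing,
               layer_boundaries = medium$boundaries)
}

# bind 3D arrays along the third dimension
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  array(unlist(lapply(parts, as.numeric), use.names = FALSE),
        dim = c(d[1], d[2], sum(vapply(parts, function(p) dim(p)[3], 1L))))
}

#' Redatum traces from a gently curved array to the reference plane
#'
#' Applies a per-element time shift `dt = delta_z / c1` (exact for
#' band-limited signals, implemented as a spectral phase ramp) so that
#' traces recorded at out-of-plane offsets `delta_z` behave as if recorded
#' on the fitted reference plane. Valid for small bending-induced offsets;
#' a warning is issued above `warn_bound`.
#'
#' @param data a [channel_data()] record.
#' @param delta_z per-element out-of-plane displacement (mm), positive
#'   toward the tissue; e.g. `register_array_geometry(...)$delta_z`.
#' @param c_first_layer sound speed of the first layer (m/s).
#' @param warn_bound largest |delta_z| (mm) considered small; defaults to
#'   10% of the aperture diagonal.
#' @return A [channel_data()] record on the reference plane.
#' @export
pre_migrate <- function(data, delta_z, c_first_layer, warn_bound = NULL) {
  g <- data$geometry
  nel <- g$nx * g$ny
  delta_z <- rep_len(as.numeric(delta_z), nel)
  if (is.null(warn_bound)) {
    ap <- sqrt((diff(range(g$element_centers[, 1])))^2 +
               (diff(range(g$element_centers[, 2])))^2)
    warn_bound <- 0.1 * max(ap, 1e-6)
  }
  if (max(abs(delta_z)) > warn_bound)
    warning(sprintf("max |delta_z| = %.3f mm exceeds the small-offset bound %.3f mm; redatuming is approximate",
                    max(abs(delta_z)), warn_bound))
  if (all(delta_z == 0)) return(data)
  shift <- delta_z / mm_per_us(c_first_layer)  # us, delay applied per trace
  nt <- data$nt
  m <- t(matrix(data$samples, nrow = nel, ncol = nt))  # nt x nel
  f <- fft_freq(nt, data$dt)
  spec <- mvfft(m)
  ramp <- exp(-2i * pi * outer(f, shift))
  out <- Re(mvfft(spec * ramp, inverse = TRUE)) / nt
  channel_data(array(t(out), dim = dim(data$samples)), dt = data$dt,
               geometry = g, t0 = data$t0)
}
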