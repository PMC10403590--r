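#' Acoustic-source phantom
#'
#' Declarative phantom made of point absorbers and cylindrical vessel tubes
#' (polyline axis + radius). Used by the forward simulator as ground truth.
#'
#' @param points numeric matrix (n x 4): columns `x, y, z` (mm) and
#'   `amplitude` (a.u., >= 0). `NULL` for none.
#' @param vessels list of vessels, each a list with `axis` (m x 3 polyline,
#'   mm), `radius` (mm) and `amplitude` (a.u.). `NULL` for none.
#' @param extent optional bounding box `c(xmin, xmax, ymin, ymax, zmin, zmax)`
#'   (mm); geometry outside it raises a validation error.
#' @return Object of class `phantom`.
#' @export
make_phantom <- function(points = NULL, vessels = NULL, extent = NULL) {
  if (!is.null(points)) {
    points <- matrix(as.numeric(points), ncol = 4)
    colnames(points) <- c("x", "y", "z", "amplitude")
    if (any(points[, 4] < 0)) obs_validation_error("point amplitudes must be >= 0")
  }
  if (!is.null(vessels)) {
    for (v in vessels) {
      if (is.null(v$axis) || is.null(v$radius) || is.null(v$amplitude))
        obs_usage_error("each vessel needs 'axis', 'radius' and 'amplitude'")
      if (v$radius <= 0) obs_validation_error("vessel radius must be > 0")
      if (v$amplitude < 0) obs_validation_error("vessel amplitude must be >= 0")
    }
  }
  if (!is.null(extent)) {
    chk <- function(xyz, what) {
      if (any(xyz[, 1] < extent[1] | xyz[, 1] > extent[2] |
              xyz[, 2] < extent[3] | xyz[, 2] > extent[4] |
              xyz[, 3] < extent[5] | xyz[, 3] > extent[6]))
        obs_validation_error(sprintf("%s outside the declared volume", what))
    }
    if (!is.null(points) && nrow(points)) chk(points[, 1:3, drop = FALSE], "point source")
    if (!is.null(vessels)) for (v in vessels) chk(v$axis, "vessel polyline")
  }
  structure(list(points = points, vessels = vessels, extent = extent),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d point source(s), %d vessel(s)\n",
              if (is.null(x$points)) 0 else nrow(x$points),
              length(x$vessels)))
  invisible(x)
}

#' Rasterize a phantom onto a voxel grid
#'
#' Points deposit their amplitude in the containing voxel; vessel tubes mark
#' every voxel whose centre lies within `radius` of the axis polyline.
#'
#' @param phantom a [make_phantom()] object.
#' @param grid a [recon_grid()].
#' @return A [recon_volume()] of source amplitude.
#' @export
rasterize_phantom <- function(phantom, grid) {
  vol <- array(0, dim = c(grid$nx, grid$ny, grid$nz))
  snap <- function(v, axis) round((v - axis[1]) / (axis[2] - axis[1])) + 1
  if (!is.null(phantom$points) && nrow(phantom$points)) {
    for (i in seq_len(nrow(phantom$points))) {
      p <- phantom$points[i, ]
      ix <- snap(p[1], grid$x); iy <- snap(p[2], grid$y); iz <- snap(p[3], grid$z)
      if (ix >= 1 && ix <= grid$nx && iy >= 1 && iy <= grid$ny &&
          iz >= 1 && iz <= grid$nz)
        vol[ix, iy, iz] <- vol[ix, iy, iz] + p[4]
    }
  }
  for (v in phantom$vessels) {
    xyz <- cbind(rep(grid$x, times = grid$ny * grid$nz),
                 rep(rep(grid$y, each = grid$nx), times = grid$nz),
                 rep(grid$z, each = grid$nx * grid$ny))
    d2 <- rep(Inf, nrow(xyz))
    ax <- v$axis
    for (s in seq_len(nrow(ax) - 1)) {
      a <- ax[s, ]; b <- ax[s + 1, ]
      ab <- b - a; L2 <- sum(ab^2)
      t <- pmin(1, pmax(0, (sweep(xyz, 2, a) %*% ab) / L2))
      proj <- outer(as.numeric(t), ab) + matrix(a, nrow(xyz), 3, byrow = TRUE)
      d2 <- pmin(d2, rowSums((xyz - proj)^2))
    }
    vol <- vol + v$amplitude * array(d2 <= v$radius^2, dim = dim(vol))
  }
  recon_volume(vol, grid$origin, grid$spacing)
}

# convert a phantom to discrete point sources for the forward model;
# vessels are sampled on an internal lattice with amplitude per cell volume
phantom_sources <- function(phantom, lattice = 0.3) {
  src <- if (!is.null(phantom$points) && nrow(phantom$points))
    phantom$points else matrix(numeric(), ncol = 4)
  for (v in phantom$vessels) {
    ax <- v$axis
    lo <- apply(ax, 2, min) - v$radius; hi <- apply(ax, 2, max) + v$radius
    gx <- seq(lo[1], hi[1], by = lattice); gy <- seq(lo[2], hi[2], by = lattice)
    gz <- seq(lo[3], hi[3], by = lattice)
    pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
    keep <- rep(FALSE, nrow(pts))
    for (s in seq_len(nrow(ax) - 1)) {
      a <- ax[s, ]; b <- ax[s + 1, ]
      ab <- b - a; L2 <- sum(ab^2)
      t <- pmin(1, pmax(0, (sweep(pts, 2, a) %*% ab) / L2))
      proj <- outer(as.numeric(t), ab) + matrix(a, nrow(pts), 3, byrow = TRUE)
      keep <- keep | rowSums((pts - proj)^2) <= v$radius^2
    }
    if (any(keep))
      src <- rbind(src, cbind(pts[keep, , drop = FALSE],
                              v$amplitude * lattice^3))
  }
  src
}

#' Band-limited receive pulse model
#'
#' `gaussian_derivative` (default): time derivative of a Gaussian-windowed
#' carrier at the centre frequency; the Gaussian envelope is sized so the
#' -6 dB fractional bandwidth of the spectral envelope matches
#' `fractional_bandwidth`. `n_shape_bandlimited`: plain derivative-of-Gaussian
#' (bipolar N-shape surrogate) whose spectral peak sits at the centre
#' frequency; its bandwidth is intrinsic to the shape.
#'
#' @param center_frequency MHz.
#' @param fractional_bandwidth -6 dB fractional bandwidth (> 0).
#' @param shape `"gaussian_derivative"` or `"n_shape_bandlimited"`.
#' @return Object of class `pulse_model`; call it on a time vector (us)
#'   via [pulse_eval()].
#' @export
pulse_model <- function(center_frequency = 7.8, fractional_bandwidth = 1.0,
                        shape = c("gaussian_derivative", "n_shape_bandlimited")) {
  shape <- match.arg(shape)
  if (fractional_bandwidth <= 0) obs_usage_error("bandwidth must be > 0")
  structure(list(center_frequency = center_frequency,
                 fractional_bandwidth = fractional_bandwidth, shape = shape),
            class = "pulse_model")
}

#' Evaluate a pulse model on a time axis
#' @param pulse a [pulse_model()].
#' @param t time offsets from the arrival (us).
#' @return numeric vector of pulse amplitude.
#' @export
pulse_eval <- function(pulse, t) {
  fc <- pulse$center_frequency
  if (pulse$shape == "gaussian_derivative") {
    # envelope sigma from the -6 dB full width bw*fc of the spectral Gaussian
    sig <- sqrt(2 * log(2)) / (pi * pulse$fractional_bandwidth * fc)
    env <- exp(-t^2 / (2 * sig^2))
    # d/dt [env * sin(2 pi fc t)], normalized to unit peak scale
    w <- 2 * pi * fc
    (env * (w * cos(w * t)) - (t / sig^2) * env * sin(w * t)) / w
  } else {
    sig <- 1 / (2 * pi * fc)
    -(t / sig) * exp(-t^2 / (2 * sig^2)) * exp(0.5)
  }
}

#' Simulate channel data for a phantom (forward oracle)
#'
#' Independent point-absorber forward model: every source contributes a
#' band-limited pulse at the refraction-correct (Fermat) layered travel time
#' with 1/r geometric spreading. Elements are ideal points (no directivity),
#' layers are lossless and density-matched. Additive white Gaussian noise is
#' applied after the coherent sum; results are bit-deterministic for a fixed
#' seed.
#'
#' @param phantom a [make_phantom()] object; all sources must lie below the
#'   array plane.
#' @param array a [sensor_array()].
#' @param medium a [layered_medium()].
#' @param pulse a [pulse_model()]; defaults to the array's fc/bandwidth.
#' @param nt number of time samples.
#' @param noise_sd additive Gaussian noise s.d. (a.u.).
#' @param seed RNG seed for the noise (NULL: no seeding).
#' @param t0 time of first sample (us).
#' @return A [channel_data()] record.
#' @export
simulate_channels <- function(phantom, array, medium, pulse = NULL,
                              nt = 512, noise_sd = 0, seed = NULL, t0 = 0) {
  if (is.null(pulse))
    pulse <- pulse_model(array$center_frequency, array$fractional_bandwidth)
  src <- phantom_sources(phantom)
  if (nrow(src) && any(src[, 3] <= 0))
    obs_validation_error("sources must lie below the array plane (z > 0)")
  dt <- 1 / array$sampling_rate
  tgrid <- t0 + (seq_len(nt) - 1) * dt
  nel <- array$nx * array$ny
  sig <- matrix(0, nel, nt)
  ec <- array$element_centers
  for (i in seq_len(nrow(src))) {
    p <- src[i, ]
    dxy <- cbind(ec[, 1] - p[1], ec[, 2] - p[2])
    rho <- sqrt(rowSums(dxy^2))
    r <- sqrt(rho^2 + p[3]^2)
    tau <- vapply(rho, function(rr) tt_rho_z(rr, p[3], medium, "refracted"),
                  numeric(1))
    amp <- p[4] / pmax(r, 0.1)
    sig <- sig + amp * pulse_eval(pulse, outer(-tau, tgrid, "+"))
  }
  if (noise_sd > 0) {
    noise <- with_seed(seed, rnorm(nel * nt, sd = noise_sd))
    sig <- sig + matrix(noise, nel, nt)
  }
  channel_data(array(sig, dim = c(array$nx, array$ny, nt)), dt = dt,
               geometry = array, t0 = t0)
}
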