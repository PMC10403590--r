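#' Optical properties of the transport medium
#'
#' @param mua absorption coefficient (1/cm).
#' @param mus scattering coefficient (1/cm).
#' @param g Henyey-Greenstein anisotropy, in (-1, 1). Default 0.9 (typical
#'   dermis; assumption, exposed here).
#' @param n refractive index. Default 1.4 (typical dermis; assumption).
#' @return An `optical_medium` list (coefficients also stored per mm).
#' @export
optical_medium <- function(mua, mus, g = 0.9, n = 1.4) {
  if (mua < 0 || mus < 0) obs_usage_error("mua and mus must be >= 0")
  if (abs(g) >= 1) obs_usage_error("anisotropy g must be in (-1, 1)")
  structure(list(mua = mua, mus = mus, g = g, n = n,
                 mua_mm = mua / 10, mus_mm = mus / 10), class = "optical_medium")
}

#' Dermis optical parameters at 532 nm
#'
#' Scattering 357 1/cm, absorption 0.46 1/cm.
#' @return An [optical_medium()].
#' @export
dermis_optics_532 <- function() optical_medium(mua = 0.46, mus = 357)

#' Skin illumination geometry
#'
#' Three delivery schemes for a wearable footprint: `lens_grid` — a square
#' grid of focused spots (the micro-lens array scheme, default 5 x 5 at the
#' inter-element pitch); `center_window` — a single central clear window;
#' `side` — an oblique collimated strip entering from one edge.
#'
#' @param kind geometry kind.
#' @param ... kind-specific parameters with defaults:
#'   `lens_grid`: `grid_n = 5`, `pitch = 1.66` (mm), `spot_radius = 0.25`
#'   (mm at skin entry), `focal_depth = 0.5` (mm);
#'   `center_window`: `window = 3.32` (mm side of the square window);
#'   `side`: `strip_width = 1` (mm), `angle_deg = 45`, `footprint = 9.96`
#'   (mm; also the lateral extent used for the other kinds).
#' @return An `illumination_geometry` list.
#' @export
illumination_geometry <- function(kind = c("lens_grid", "center_window", "side"),
                                  ...) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) obs_usage_error(
                     sprintf("unknown illumination kind '%s'", kind[1])))
  defaults <- switch(kind,
    lens_grid = list(grid_n = 5, pitch = 1.66, spot_radius = 0.25,
                     focal_depth = 0.5, footprint = 9.96),
    center_window = list(window = 3.32, footprint = 9.96),
    side = list(strip_width = 1, angle_deg = 45, footprint = 9.96))
  p <- utils::modifyList(defaults, list(...))
  if (any(unlist(p) <= 0)) obs_usage_error("geometry parameters must be positive")
  structure(c(list(kind = kind), p), class = "illumination_geometry")
}

# sample photon launch positions/directions for a geometry (seeded by caller)
launch_photons <- function(geom, n) {
  half <- geom$footprint / 2
  if (geom$kind == "lens_grid") {
    gx <- (seq_len(geom$grid_n) - (geom$grid_n + 1) / 2) * geom$pitch
    cx <- sample(gx, n, replace = TRUE)
    cy <- sample(gx, n, replace = TRUE)
    # converging beam: Gaussian entry spot aimed at a focus below the centre
    x <- cx + rnorm(n, sd = geom$spot_radius)
    y <- cy + rnorm(n, sd = geom$spot_radius)
    dx <- cx - x; dy <- cy - y; dz <- rep(geom$focal_depth, n)
    nr <- sqrt(dx^2 + dy^2 + dz^2)
    list(pos = cbind(x, y, 0), dir = cbind(dx / nr, dy / nr, dz / nr))
  } else if (geom$kind == "center_window") {
    x <- runif(n, -geom$window / 2, geom$window / 2)
    y <- runif(n, -geom$window / 2, geom$window / 2)
    list(pos = cbind(x, y, 0), dir = cbind(0, 0, 1)[rep(1, n), ])
  } else {
    # oblique strip along the -x edge, launched inward at angle_deg from vertical
    a <- geom$angle_deg * pi / 180
    x <- runif(n, -half, -half + geom$strip_width)
    y <- runif(n, -half, half)
    list(pos = cbind(x, y, 0),
         dir = cbind(sin(a), 0, cos(a))[rep(1, n), ])
  }
}

#' Monte Carlo light-fluence simulation
#'
#' Standard photon random walk in a homogeneous scattering half-space:
#' exponential step sampling with `mut = mua + mus`, Henyey-Greenstein
#' scattering, absorption-weight deposition at interaction sites, and
#' Russian-roulette termination. Deposited weight is scored on a voxel
#' grid; photons leaving the simulation box are terminated and their weight
#' counted as escaped. Deterministic for a fixed seed.
#'
#' @param geom an [illumination_geometry()].
#' @param medium an [optical_medium()]; `mua + mus` must be positive.
#' @param n_photons number of photon packets (>= 1e4 recommended; a warning
#'   is issued below).
#' @param seed RNG seed (launch sampling and propagation).
#' @param voxel voxel size (mm).
#' @param lateral_halfwidth scored lateral half-extent (mm).
#' @param depth scored depth extent (mm); the simulation box is larger so
#'   photons can re-enter the scored region.
#' @return Object of class `fluence_map`: `$fluence` voxel array of deposited
#'   weight per voxel volume per absorption coefficient, axes `$x`, `$y`,
#'   `$z`, plus `$absorbed`, `$escaped`, `$n_photons`, `$seed`.
#' @export
mc_fluence <- function(geom, medium, n_photons = 1e6, seed = 1,
                       voxel = 0.1, lateral_halfwidth = 7, depth = 3) {
  if (medium$mua_mm + medium$mus_mm <= 0)
    obs_config_error("mua + mus must be positive for an unbounded medium")
  n_photons <- as.integer(n_photons)
  if (n_photons < 1e4) warning("fewer than 1e4 photons; fluence will be noisy")
  lp <- with_seed(seed, launch_photons(geom, n_photons))
  nx <- 2 * ceiling(lateral_halfwidth / voxel)
  nz <- ceiling(depth / voxel)
  x0 <- -nx / 2 * voxel
  res <- mc_fluence_cpp(lp$pos, lp$dir, medium$mua_mm, medium$mus_mm, medium$g,
                        x0, voxel, nx, x0, voxel, nx, 0, voxel, nz,
                        lateral_halfwidth + 5, depth + 8,
                        as.integer(seed) + 1L)
  A <- array(res$A, dim = c(nx, nx, nz))
  denom <- max(medium$mua_mm, .Machine$double.eps) * voxel^3
  structure(list(
    fluence = A / denom,
    x = x0 + (seq_len(nx) - 0.5) * voxel,
    y = x0 + (seq_len(nx) - 0.5) * voxel,
    z = (seq_len(nz) - 0.5) * voxel,
    voxel = voxel, n_photons = n_photons, seed = seed,
    absorbed = res$absorbed, escaped = res$escaped
  ), class = "fluence_map")
}

#' @export
print.fluence_map <- function(x, ...) {
  cat(sprintf("<fluence_map> %d x %d x %d voxels @ %.2f mm, %d photons (seed %d)\n",
              dim(x$fluence)[1], dim(x$fluence)[2], dim(x$fluence)[3],
              x$voxel, x$n_photons, x$seed))
  invisible(x)
}

#' Effective illumination area fraction at depth
#'
#' The blind region at a depth is where the light intensity drops more than
#' `|threshold_db|` below the slice maximum (intensity convention: factor
#' `10^(threshold_db / 10)`). The effective fraction is the complement,
#' evaluated over a lateral region of interest (default: the device
#' footprint).
#'
#' @param map a [mc_fluence()] result.
#' @param depth slice depth (mm), within the scored grid.
#' @param threshold_db intensity threshold (default -20 dB).
#' @param roi_halfwidth lateral ROI half-extent (mm); default 4.98 (the
#'   device footprint).
#' @return fraction in \[0, 1\].
#' @export
effective_area_fraction <- function(map, depth, threshold_db = -20,
                                    roi_halfwidth = 4.98) {
  iz <- which.min(abs(map$z - depth))
  if (abs(map$z[iz] - depth) > map$voxel)
    obs_usage_error("requested depth lies outside the scored grid")
  sl <- map$fluence[, , iz]
  inx <- abs(map$x) <= roi_halfwidth
  iny <- abs(map$y) <= roi_halfwidth
  sl <- sl[inx, iny]
  mx <- max(sl)
  if (mx <= 0) obs_measure_error("all-zero fluence slice; cannot assess coverage")
  mean(sl >= mx * 10^(threshold_db / 10))
}
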