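#' Delay-and-sum configuration
#'
#' @param ray_model `"refracted"` (Fermat-optimal path through the layer
#'   stack) or `"straight"` (straight segment with per-layer slowness — the
#'   traditional beamformer's path model, which ignores refraction at the
#'   interfaces).
#' @param apodization `"none"` or `"hann"` (separable Hann taper over the
#'   element grid).
#' @param envelope `"abs_hilbert"` (magnitude of the analytic signal along
#'   depth, the standard resolution-metrology convention) or `"raw"`.
#' @return A `das_config` list.
#' @export
das_config <- function(ray_model = c("refracted", "straight"),
                       apodization = c("none", "hann"),
                       envelope = c("abs_hilbert", "raw")) {
  structure(list(ray_model = match.arg(ray_model),
                 apodization = match.arg(apodization),
                 envelope = match.arg(envelope)), class = "das_config")
}

#' One-way travel time through a layered medium
#'
#' Straight model: time along the straight element-voxel segment with each
#' layer's own slowness. Refracted model: Fermat's least-time path, found by
#' bounded minimization over the interface crossing radii (1D for a voxel in
#' layer 2; nested coordinate descent deeper).
#'
#' @param element_pos length-3 position of the element (mm), `z = 0`.
#' @param voxel_pos length-3 position of the image point (mm), `z > 0`.
#' @param medium a [layered_medium()].
#' @param ray_model `"refracted"` or `"straight"`.
#' @return travel time in us.
#' @export
travel_time <- function(element_pos, voxel_pos, medium,
                        ray_model = c("refracted", "straight")) {
  ray_model <- match.arg(ray_model)
  z <- voxel_pos[3] - element_pos[3]
  if (z <= 0) obs_domain_error("image point must lie below the array plane (z > 0)")
  rho <- sqrt((voxel_pos[1] - element_pos[1])^2 + (voxel_pos[2] - element_pos[2])^2)
  tt_rho_z(rho, z, medium, ray_model)
}

# travel time as a function of horizontal offset rho and depth z (both mm)
tt_rho_z <- function(rho, z, medium, ray_model) {
  m <- max(1L, layer_of(medium, z))
  cs <- medium$c_mm_us
  if (m == 1L) return(sqrt(rho^2 + z^2) / cs[1])
  tops <- medium$boundaries
  dz <- c(diff(tops[seq_len(m)]), z - tops[m])  # per-layer vertical extents
  if (ray_model == "straight") {
    len <- sqrt(rho^2 + z^2)
    return(sum(len * (dz / z) / cs[seq_len(m)]))
  }
  if (m == 2L) {
    f <- function(x1) sqrt(x1^2 + dz[1]^2) / cs[1] +
      sqrt((rho - x1)^2 + dz[2]^2) / cs[2]
    if (rho < 1e-12) return(f(0))
    return(optimize(f, c(0, rho), tol = 1e-10)$objective)
  }
  # deeper voxels: coordinate descent on the m-1 crossing radii
  xs <- rho * cumsum(dz[-m]) / z  # straight-line initialisation
  seg_t <- function(xs) {
    r <- c(0, xs, rho); zz <- c(0, cumsum(dz))
    sum(sqrt(diff(r)^2 + diff(zz)^2) / cs[seq_len(m)])
  }
  for (it in 1:40) {
    changed <- 0
    for (j in seq_along(xs)) {
      lo <- if (j == 1) 0 else xs[j - 1]
      hi <- if (j == length(xs)) rho else xs[j + 1]
      if (hi - lo < 1e-12) next
      g <- function(x) { xs2 <- xs; xs2[j] <- x; seg_t(xs2) }
      opt <- optimize(g, c(lo, hi), tol = 1e-10)
      changed <- max(changed, abs(opt$minimum - xs[j]))
      xs[j] <- opt$minimum
    }
    if (changed < 1e-9) break
  }
  seg_t(xs)
}

# lookup table tau[iz, irho] over the voxel z axis and a uniform rho axis
das_tt_table <- function(medium, z_axis, rho_max, drho, ray_model) {
  rho <- seq(0, rho_max + drho, by = drho)
  tab <- matrix(0, nrow = length(z_axis), ncol = length(rho))
  if (ray_model == "straight") {
    cs <- medium$c_mm_us
    for (iz in seq_along(z_axis)) {
      z <- z_axis[iz]
      m <- max(1L, layer_of(medium, z))
      dz <- c(diff(medium$boundaries[seq_len(m)]), z - medium$boundaries[m])
      if (m == 1L) dz <- z
      len <- sqrt(rho^2 + z^2)
      tab[iz, ] <- len * sum((dz / z) / cs[seq_len(m)])
    }
  } else {
    for (iz in seq_along(z_axis))
      for (ir in seq_along(rho))
        tab[iz, ir] <- tt_rho_z(rho[ir], z_axis[iz], medium, "refracted")
  }
  list(tau = tab, rho0 = 0, drho = drho)
}

#' Delay-and-sum volumetric reconstruction
#'
#' Classical time-domain beamformer: for every voxel, channel samples are
#' gathered at the one-way travel-time delays and summed (optionally
#' apodized), then envelope-detected along depth. Cost grows as
#' O(n_voxels x n_elements) — the O(n^5) baseline the Fourier-domain method
#' is compared against.
#'
#' @param data a [channel_data()] record.
#' @param medium a [layered_medium()].
#' @param grid a [recon_grid()] (voxel z must be > 0).
#' @param cfg a [das_config()].
#' @return A [recon_volume()]. Delays falling outside the record contribute
#'   zero; their count is available as `attr(volume, "clipped")`.
#' @export
reconstruct_das <- function(data, medium, grid, cfg = das_config()) {
  if (!inherits(grid, "recon_grid")) obs_usage_error("'grid' must be a recon_grid")
  if (any(grid$z <= 0)) obs_domain_error("all voxel depths must be > 0")
  g <- data$geometry
  ex <- g$element_centers[, 1]; ey <- g$element_centers[, 2]
  rho_max <- sqrt(max(abs(outer(grid$x, ex, "-")))^2 +
                  max(abs(outer(grid$y, ey, "-")))^2) + 1
  drho <- max(min(grid$spacing) / 2, 0.02)
  tt <- das_tt_table(medium, grid$z, rho_max, drho, cfg$ray_model)
  w <- if (cfg$apodization == "hann") {
    wx <- 0.5 - 0.5 * cos(2 * pi * (seq_len(g$nx) - 0.5) / g$nx)
    wy <- 0.5 - 0.5 * cos(2 * pi * (seq_len(g$ny) - 0.5) / g$ny)
    as.numeric(outer(wx, wy))
  } else rep(1, g$nx * g$ny)
  ch <- matrix(data$samples, nrow = g$nx * g$ny, ncol = data$nt)
  res <- das_sum_cpp(ch, ex, ey, w, grid$x, grid$y,
                     tt$tau, tt$rho0, tt$drho, data$t0, data$dt)
  vol <- array(res$volume, dim = c(grid$nx, grid$ny, grid$nz))
  if (cfg$envelope == "abs_hilbert") vol <- envelope_z(vol)
  out <- recon_volume(vol, grid$origin, grid$spacing,
                      layer_boundaries = medium$boundaries)
  attr(out, "clipped") <- res$clipped
  out
}

# magnitude of the analytic signal along the z (depth) dimension
envelope_z <- function(vol) {
  d <- dim(vol)
  n <- d[3]
  m <- matrix(aperm(vol, c(3, 1, 2)), nrow = n)
  spec <- mvfft(m)
  h <- numeric(n)
  if (n %% 2 == 0) { h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  analytic <- mvfft(spec * h, inverse = TRUE) / n
  aperm(array(Mod(analytic), dim = d[c(3, 1, 2)]), c(2, 3, 1))
}
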