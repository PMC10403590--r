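# Independent oracles used across the suite. These deliberately avoid the
# package's own transform code paths.

# brute-force 3D DFT with kernels e^{-i kx x} e^{-i ky y} e^{+i w t},
# computed via explicit per-axis DFT matrices (not fft)
oracle_spectrum <- function(p) {
  d <- dim(p)
  dftmat <- function(n, sign) {
    w <- outer(0:(n - 1), 0:(n - 1))
    exp(sign * 2i * pi * w / n)
  }
  Mx <- dftmat(d[1], -1); My <- dftmat(d[2], -1); Mt <- dftmat(d[3], +1)
  # contract axis 1
  a <- apply(p, c(2, 3), function(v) Mx %*% v)
  a <- array(a, dim = d)
  b <- aperm(apply(a, c(1, 3), function(v) My %*% v), c(2, 1, 3))
  cc <- aperm(apply(b, c(1, 2), function(v) Mt %*% v), c(2, 3, 1))
  cc
}

# naive windowed-sinc non-uniform resampling: direct summation per output
# node, no vectorized gather tricks
oracle_stolt <- function(spec, c_mm_us, kz, J) {
  d <- dim(spec$values)
  nw <- d[3]
  dw <- spec$waxis[2] - spec$waxis[1]
  out <- array(0i, dim = c(d[1], d[2], length(kz)))
  for (ix in seq_len(d[1])) for (iy in seq_len(d[2])) for (iz in seq_along(kz)) {
    kmag <- sqrt(spec$kx[ix]^2 + spec$ky[iy]^2 + kz[iz]^2)
    if (kmag == 0) next
    wmap <- -sign(kz[iz]) * c_mm_us * kmag
    bf <- wmap / dw
    if (abs(bf) > nw / 2 - J - 1) next
    acc <- 0i
    for (b in (round(bf) - J):(round(bf) + J)) {
      u <- bf - b
      s <- if (abs(u) < 1e-12) 1 else sin(pi * u) / (pi * u)
      win <- 0.5 + 0.5 * cos(pi * u / (J + 1))
      acc <- acc + spec$values[ix, iy, (b %% nw) + 1] * s * win
    }
    out[ix, iy, iz] <- acc * c_mm_us * abs(kz[iz]) / kmag
  }
  out
}

# exhaustive Fermat scan over interface crossing radii (two-layer)
oracle_fermat2 <- function(rho, z, d1, c1_mm_us, c2_mm_us, n = 1e4) {
  x <- seq(0, rho, length.out = n)
  min(sqrt(x^2 + d1^2) / c1_mm_us + sqrt((rho - x)^2 + (z - d1)^2) / c2_mm_us)
}

# reference single-layer frequency-wavenumber (Stolt) migration written
# directly from the dispersion relation, independent of the package's
# staged pipeline
oracle_stolt_migration <- function(data, c_m_s, nz, dz) {
  g <- data$geometry
  ct <- c_m_s / 1000
  d <- dim(data$samples)
  nt2 <- 2 * d[3]
  p <- array(0, dim = c(d[1], d[2], nt2))
  p[, , seq_len(d[3])] <- data$samples
  rev_idx <- c(1L, nt2:2L)
  P <- fft(p[, , rev_idx])
  fx <- function(n, dd) { h <- floor((n - 1) / 2); c(0:h, -(n - h - 1):-1) / (n * dd) }
  kx <- 2 * pi * fx(d[1], g$pitch); ky <- 2 * pi * fx(d[2], g$pitch)
  w <- 2 * pi * fx(nt2, data$dt); dwv <- w[2] - w[1]
  kz <- 2 * pi * fx(nz, dz)
  out <- array(0i, dim = c(d[1], d[2], nz))
  for (iz in seq_len(nz)) {
    kmag <- sqrt(outer(kx^2, ky^2, "+") + kz[iz]^2)
    wmap <- -sign(kz[iz]) * ct * kmag
    bi <- round(wmap / dwv)  # nearest-neighbour is enough for a peak-location oracle
    ok <- abs(bi) < nt2 / 2 - 1 & kmag > 0
    bi[!ok] <- 0
    flat <- cbind(rep(seq_len(d[1]), d[2]), rep(seq_len(d[2]), each = d[1]),
                  as.vector(bi %% nt2) + 1)
    vals <- P[flat]
    vals[!as.vector(ok)] <- 0i
    out[, , iz] <- matrix(vals, d[1], d[2]) * ct * abs(kz[iz]) / pmax(kmag, 1e-12)
  }
  Re(fft(out, inverse = TRUE)) / length(out)
}

# small planar test array shared by several files
tiny_array <- function(nx = 6, ny = 6, nt_rate = 40)
  sensor_array(nx, ny, element_width = 1.0, gap = 0.5, sampling_rate = nt_rate)
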