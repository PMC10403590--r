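make_small_data <- function(seed = 1, nx = 8, ny = 8, nt = 32) {
  arr <- sensor_array(nx, ny, element_width = 1.0, gap = 0.5, sampling_rate = 40)
  set.seed(seed)
  channel_data(array(rnorm(nx * ny * nt), c(nx, ny, nt)), dt = 0.025,
               geometry = arr)
}

test_that("forward spectrum matches a brute-force DFT oracle", {
  cd <- make_small_data()
  spec <- forward_spectrum(cd, nufft_config(pad_time = 1))
  ref <- oracle_spectrum(cd$samples)
  expect_lt(max(Mod(spec$values - ref)) / max(Mod(ref)), 1e-10)
})

test_that("a delta sample transforms to flat magnitude with linear phase", {
  arr <- sensor_array(8, 8, element_width = 1, gap = 0.5, sampling_rate = 40)
  p <- array(0, c(8, 8, 16)); p[3, 5, 7] <- 1
  spec <- forward_spectrum(channel_data(p, 0.025, arr), nufft_config(pad_time = 1))
  expect_equal(max(Mod(spec$values)), min(Mod(spec$values)), tolerance = 1e-10)
  # phase along kx at ky = w = 0 advances linearly (modulo 2 pi)
  ph <- Arg(spec$values[, 1, 1])
  steps <- diff(ph[1:4]) %% (2 * pi)
  expect_equal(steps, rep(steps[1], 3), tolerance = 1e-9)
})

test_that("real input yields a Hermitian spectrum in omega", {
  cd <- make_small_data(2)
  spec <- forward_spectrum(cd, nufft_config(pad_time = 1))
  d <- dim(spec$values)
  conj_idx <- function(i, n) c(1, n:2)[i]
  for (pick in list(c(2, 3, 5), c(4, 1, 2), c(7, 8, 16))) {
    a <- spec$values[pick[1], pick[2], pick[3]]
    b <- spec$values[conj_idx(pick[1], d[1]), conj_idx(pick[2], d[2]),
                     conj_idx(pick[3], d[3])]
    expect_equal(a, Conj(b), tolerance = 1e-10)
  }
})

test_that("phase-shift extrapolation obeys closed forms and composition", {
  # 40 samples at dt = 0.025 us puts a bin exactly at +/- 1 MHz
  cd <- make_small_data(3, nt = 40)
  spec <- forward_spectrum(cd, nufft_config(pad_time = 1))

  # zero total thickness: layer 1 target is the identity
  med <- layered_medium(c(1.5, Inf), c(1500, 1500))
  expect_identical(extrapolate_layers(spec, med, 1)$values, spec$values)

  # kx = ky = 0, c = 1500 m/s, d = 1.5 mm, f = 1 MHz: |phase| = w d / c = 2 pi
  ext <- extrapolate_layers(spec, med, 2)
  iw <- which.min(abs(spec$waxis - 2 * pi * 1))  # bin at +1 MHz
  expect_equal(spec$waxis[iw], 2 * pi, tolerance = 1e-12)
  ratio <- ext$values[1, 1, iw] / spec$values[1, 1, iw]
  expect_equal(ratio, 1 + 0i, tolerance = 1e-9)

  # composition: (d1, c) then (d2, c) equals (d1 + d2, c)
  m2 <- layered_medium(c(0.8, 0.7, Inf), c(1440, 1440, 1440))
  m1 <- layered_medium(c(1.5, Inf), c(1440, 1440))
  expect_equal(extrapolate_layers(spec, m2, 3)$values,
               extrapolate_layers(spec, m1, 2)$values, tolerance = 1e-12)
  expect_equal(extrapolate_layers(spec, m2, 3)$z_ref, 1.5)

  expect_error(extrapolate_layers(spec, med, 5), class = "obscope_usage_error")
})

test_that("stolt resampling matches the naive windowed-sinc oracle", {
  cd <- make_small_data(4, nx = 8, ny = 8, nt = 32)
  spec <- forward_spectrum(cd, nufft_config(pad_time = 1))
  cfg <- nufft_config(kernel_halfwidth = 4, pad_time = 1)
  out <- stolt_resample(spec, 1500, nz = 8, dz = 0.4, cfg = cfg)
  kz <- out$waxis
  ref <- oracle_stolt(spec, 1.5, kz, J = 4)
  expect_lt(max(Mod(out$values - ref)) / max(Mod(ref)), 1e-8)
})

test_that("on-axis stolt mapping reduces to omega = c kz with Jacobian c", {
  cd <- make_small_data(5)
  spec <- forward_spectrum(cd, nufft_config(pad_time = 1))
  ct <- 1.5
  nz <- 16; dz <- 2 * pi / (nz * (spec$waxis[2] - spec$waxis[1]) / ct)
  # dz chosen so c kz lands exactly on omega bins: interpolation is identity
  out <- stolt_resample(spec, 1500, nz = nz, dz = dz)
  kz <- out$waxis
  for (iz in c(2, 3, 5)) {
    iw <- which.min(abs(spec$waxis - (-ct * kz[iz])))
    expect_equal(out$values[1, 1, iz], ct * spec$values[1, 1, iw],
                 tolerance = 1e-9)
  }
})

test_that("inverse stage is linear, real for Hermitian input, and slab-aware", {
  # all-zero spectrum -> all-zero volume
  z0 <- spectral0 <- obscope:::spectral_field(array(0i, c(4, 4, 8)),
    kx = 2 * pi * obscope:::fft_freq(4, 1), ky = 2 * pi * obscope:::fft_freq(4, 1),
    waxis = 2 * pi * obscope:::fft_freq(8, 0.5), domain = "kz", z_ref = 0,
    dx = 1, dy = 1)
  vol0 <- invert_to_volume(z0, c(0, 4))
  expect_true(all(vol0$voxels == 0))

  # Hermitian-symmetrized random spectrum -> strictly real volume
  set.seed(9)
  raw <- array(complex(real = rnorm(4 * 4 * 8), imaginary = rnorm(4 * 4 * 8)),
               c(4, 4, 8))
  sym <- raw
  ci <- function(i, n) c(1, n:2)[i]
  for (i in 1:4) for (j in 1:4) for (k in 1:8)
    sym[i, j, k] <- (raw[i, j, k] + Conj(raw[ci(i, 4), ci(j, 4), ci(k, 8)])) / 2
  zh <- z0; zh$values <- sym
  volh <- invert_to_volume(zh, c(0, 4))
  # invert_to_volume takes Re(); verify the imaginary part truly vanished
  full <- fft(sym, inverse = TRUE) / length(sym)
  expect_lt(max(abs(Im(full))), 1e-12 * max(abs(Re(full))))
  expect_error(invert_to_volume(zh, c(2, 2)), class = "obscope_usage_error")
})

test_that("point sources reconstruct at their true position", {
  arr <- sensor_array(16, 16, element_width = 0.4, gap = 0.2, sampling_rate = 40)
  med <- layered_medium(Inf, 1500)
  truth <- c(0.6, -0.9, 5)
  cd <- simulate_channels(make_phantom(points = rbind(c(truth, 1))), arr, med,
                          nt = 512)
  vol <- reconstruct_psnufft(cd, med, nz = 120, dz = 0.1, upsample = 2)
  v <- abs(vol$voxels)
  w <- which(v == max(v), arr.ind = TRUE)[1, ]
  pk <- c(vol$x[w[1]], vol$y[w[2]], vol$z[w[3]])
  expect_lt(abs(pk[1] - truth[1]), vol$spacing[1] + 1e-9)
  expect_lt(abs(pk[2] - truth[2]), vol$spacing[2] + 1e-9)
  expect_lt(abs(pk[3] - truth[3]), vol$spacing[3] + 1e-9)
})

test_that("single-layer reconstruction agrees with a reference Stolt migration", {
  arr <- sensor_array(16, 16, element_width = 0.4, gap = 0.2, sampling_rate = 40)
  med <- layered_medium(Inf, 1500)
  cd <- simulate_channels(make_phantom(points = rbind(c(0.3, 0.3, 4, 1))),
                          arr, med, nt = 256)
  vol <- reconstruct_psnufft(cd, med, nz = 100, dz = 0.1)
  ref <- oracle_stolt_migration(cd, 1500, nz = 100, dz = 0.1)
  wp <- which(abs(vol$voxels) == max(abs(vol$voxels)), arr.ind = TRUE)[1, ]
  wr <- which(abs(ref) == max(abs(ref)), arr.ind = TRUE)[1, ]
  expect_true(all(abs(wp - wr) <= 1))
})

test_that("psnufft round trip localizes across random sources (seeded)", {
  arr <- sensor_array(16, 16, element_width = 0.4, gap = 0.2, sampling_rate = 40)
  med <- layered_medium(Inf, 1500)
  set.seed(77)
  cases <- cbind(runif(20, -2, 2), runif(20, -2, 2), runif(20, 3, 8))
  miss <- 0
  for (i in seq_len(nrow(cases))) {
    truth <- cases[i, ]
    cd <- simulate_channels(make_phantom(points = rbind(c(truth, 1))), arr, med,
                            nt = 512, noise_sd = 0.002, seed = i)  # ~20 dB SNR
    vol <- reconstruct_psnufft(cd, med, nz = 120, dz = 0.1, upsample = 2)
    v <- abs(vol$voxels)
    w <- which(v == max(v), arr.ind = TRUE)[1, ]
    pk <- c(vol$x[w[1]], vol$y[w[2]], vol$z[w[3]])
    if (any(abs(pk - truth) > vol$spacing + 1e-9)) miss <- miss + 1
  }
  expect_equal(miss, 0)
})

test_that("pre-migration redatums traces exactly and is a planar no-op", {
  arr <- sensor_array(4, 4, element_width = 1, gap = 0.5, sampling_rate = 40)
  cd <- simulate_channels(make_phantom(points = rbind(c(0, 0, 5, 1))), arr,
                          layered_medium(Inf, 1500), nt = 256)
  expect_identical(pre_migrate(cd, rep(0, 16), 1500)$samples, cd$samples)

  # uniform 0.75 mm at 1500 m/s: exactly 0.5 us = 20 samples at 40 MHz
  pm <- suppressWarnings(pre_migrate(cd, rep(0.75, 16), 1500))
  a <- cd$samples[2, 2, ]; b <- pm$samples[2, 2, ]
  expect_lt(max(abs(b[21:256] - a[1:236])), 1e-10 * max(abs(a)))
})

test_that("cylinder-bent acquisition is recovered by pre-migration", {
  R <- 40
  arr <- sensor_array(16, 16, element_width = 0.4, gap = 0.2, sampling_rate = 40)
  dz <- R - sqrt(R^2 - arr$element_centers[, 1]^2)
  truth <- c(0.5, -0.5, 6)
  cd <- simulate_channels(make_phantom(points = rbind(c(truth, 1))), arr,
                          layered_medium(Inf, 1500), nt = 512)
  bent <- pre_migrate(cd, -dz, 1500)       # elements bent toward the tissue
  fixed <- pre_migrate(bent, dz, 1500)     # redatum back to the plane
  vol <- reconstruct_psnufft(fixed, layered_medium(Inf, 1500), nz = 150,
                             dz = 0.08, upsample = 4)
  v <- abs(vol$voxels)
  w <- which(v == max(v), arr.ind = TRUE)[1, ]
  pk <- c(vol$x[w[1]], vol$y[w[2]], vol$z[w[3]])
  expect_true(all(abs(pk - truth) <= 2 * vol$spacing + 1e-9))
})

test_that("non-planar or non-uniform geometry is rejected before transform", {
  arr <- tiny_array()
  arr$element_centers[5, 3] <- 0.4  # push one element out of plane
  p <- array(0, c(6, 6, 32))
  cd <- channel_data(p, 0.025, arr)
  expect_error(forward_spectrum(cd), class = "obscope_precondition_error")
})
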