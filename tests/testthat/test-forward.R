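test_that("phantom construction validates geometry and rasterizes tubes", {
  ph <- make_phantom(points = rbind(c(3.5, 0, 5, 1)))
  expect_equal(nrow(ph$points), 1)
  expect_error(make_phantom(points = rbind(c(0, 0, 20, 1)),
                            extent = c(-5, 5, -5, 5, 0, 10)),
               class = "obscope_validation_error")

  # empty phantom -> all-zero channels
  arr <- tiny_array()
  cd0 <- simulate_channels(make_phantom(), arr, layered_medium(Inf, 1500), nt = 64)
  expect_true(all(cd0$samples == 0))

  # Y-shaped tube: voxel volume matches the analytic tube volume to one shell
  gr <- recon_grid(60, 60, 60, spacing = 0.1, origin = c(-3, -3, 0.05))
  ax1 <- rbind(c(0, 0, 0.5), c(0, 0, 2.5))
  ax2 <- rbind(c(0, 0, 2.5), c(1.5, 0, 4.5))
  ax3 <- rbind(c(0, 0, 2.5), c(-1.5, 0, 4.5))
  r <- 0.35
  ph2 <- make_phantom(vessels = list(
    list(axis = ax1, radius = r, amplitude = 1),
    list(axis = ax2, radius = r, amplitude = 1),
    list(axis = ax3, radius = r, amplitude = 1)))
  vol <- rasterize_phantom(ph2, gr)
  vox_volume <- sum(vol$voxels > 0) * prod(gr$spacing)
  seg_len <- c(2, sqrt(1.5^2 + 2^2), sqrt(1.5^2 + 2^2))
  analytic <- pi * r^2 * sum(seg_len)
  # one-voxel surface shell bound on the discretization error
  shell <- 2 * pi * r * sum(seg_len) * 0.1
  expect_lt(abs(vox_volume - analytic), shell)
})

test_that("simulated arrivals follow layered travel times", {
  arr <- tiny_array()
  # single layer: on-axis pulse at d / c at the nearest element
  med1 <- layered_medium(Inf, 1500)
  ph <- make_phantom(points = rbind(c(0.75, 0.75, 6, 1)))  # on top of an element
  cd <- simulate_channels(ph, arr, med1, nt = 512)
  iel <- which.min(rowSums((arr$element_centers[, 1:2] -
                              matrix(c(0.75, 0.75), 36, 2, byrow = TRUE))^2))
  tr <- matrix(cd$samples, 36)[iel, ]
  tpk <- (which.max(abs(tr)) - 1) * cd$dt
  expect_equal(tpk, 6 / 1.5, tolerance = cd$dt * 1.5)

  # two layers, normal incidence: d1/c1 + d2/c2
  med2 <- layered_medium(c(2, Inf), c(1000, 1600))
  ph2 <- make_phantom(points = rbind(c(0.75, 0.75, 6, 1)))
  cd2 <- simulate_channels(ph2, arr, med2, nt = 512)
  tr2 <- matrix(cd2$samples, 36)[iel, ]
  tpk2 <- (which.max(abs(tr2)) - 1) * cd2$dt
  expect_equal(tpk2, 2 / 1.0 + 4 / 1.6, tolerance = cd2$dt * 1.5)

  # sources above the plane are rejected
  expect_error(simulate_channels(make_phantom(points = rbind(c(0, 0, -1, 1))),
                                 arr, med1),
               class = "obscope_validation_error")
})

test_that("forward model is linear and seed-deterministic", {
  arr <- tiny_array()
  med <- layered_medium(c(1.5, Inf), c(1100, 1550))
  ph1 <- make_phantom(points = rbind(c(0.3, -0.4, 4, 1), c(-1, 1, 6, 0.5)))
  ph2 <- make_phantom(points = rbind(c(0.3, -0.4, 4, 2), c(-1, 1, 6, 1.0)))
  a <- simulate_channels(ph1, arr, med, nt = 256)
  b <- simulate_channels(ph2, arr, med, nt = 256)
  expect_equal(b$samples, 2 * a$samples, tolerance = 1e-12)

  n1 <- simulate_channels(ph1, arr, med, nt = 256, noise_sd = 0.01, seed = 11)
  n2 <- simulate_channels(ph1, arr, med, nt = 256, noise_sd = 0.01, seed = 11)
  expect_identical(n1$samples, n2$samples)
  n3 <- simulate_channels(ph1, arr, med, nt = 256, noise_sd = 0.01, seed = 12)
  expect_false(identical(n1$samples, n3$samples))
})

test_that("travel-time reciprocity holds when source and element swap", {
  med <- layered_medium(c(2, Inf), c(1030, 1540))
  # reciprocity in the horizontal offset: tau depends on |rho| only
  t1 <- travel_time(c(0, 0, 0), c(3, -2, 6), med)
  t2 <- travel_time(c(3, -2, 0), c(0, 0, 6), med)
  expect_equal(t1, t2, tolerance = 1e-10)
})

test_that("protocol generator reproduces the programmed physiology", {
  # hypoxia square wave has the configured 230 s period
  tr <- simulate_trend_series(protocol_spec("hypoxia_cycle"), duration = 920,
                              dt = 0.5, roi = "artery")
  low <- tr$values < max(tr$values) - 1e-9
  onsets <- tr$time[which(diff(c(FALSE, low)) == 1)]
  expect_equal(diff(onsets), rep(230, length(onsets) - 1), tolerance = 1e-9)
  # amplitude drop equals slope * saturation swing (0.76 mV/% x 50% = 38 mV)
  expect_equal(max(tr$values) - min(tr$values), 0.76 * 50, tolerance = 1e-9)

  # venous trace lags the arterial one by the configured delay
  trv <- simulate_trend_series(protocol_spec("hypoxia_cycle"), duration = 920,
                               dt = 0.5, roi = "vein")
  lowv <- trv$values < max(trv$values) - 1e-9
  onv <- trv$time[which(diff(c(FALSE, lowv)) == 1)]
  expect_equal(onv[1] - onsets[1], 15, tolerance = 0.5 + 1e-9)

  # zero-rate decay is a constant trace
  p0 <- protocol_spec("agent_decay", k = 0, tissue_k = 0)
  tr0 <- simulate_trend_series(p0, duration = 100, dt = 1, roi = "vein")
  expect_equal(diff(range(tr0$values)), 0)

  # pure agent component: value at 2000 s is exp(-0.72) of the start
  pk <- protocol_spec("agent_decay", k = 3.6e-4, tissue_k = 0)
  trk <- simulate_trend_series(pk, duration = 2000, dt = 10, roi = "vein")
  expect_equal(trk$values[trk$time == 2000] / trk$values[1], exp(-0.72),
               tolerance = 1e-9)

  expect_error(protocol_spec("unknown_kind"), class = "obscope_usage_error")
  expect_error(simulate_trend_series(protocol_spec("hypoxia_cycle"), 10, 20),
               class = "obscope_usage_error")
})
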