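test_that("trend extraction recovers programmed modulation and venous lag", {
  arr <- tiny_array()
  # constant frames -> constant trend
  fr <- replicate(8, channel_data(array(rep(c(-1, 1), 18 * 32), c(6, 6, 64)),
                                  0.025, arr), simplify = FALSE)
  tr <- extract_trend(fr, roi = rep(TRUE, 36))
  expect_equal(diff(range(tr$values)), 0)

  # amplitude-modulated square wave: depth recovered within 5%
  fs <- 10; nfr <- 200
  mod <- ifelse(((seq_len(nfr) - 1) / fs) %% 10 < 5, 1, 0.6)
  base <- sin(2 * pi * 7.8 * (0:63) * 0.025)
  frames <- lapply(seq_len(nfr), function(i)
    channel_data(array(rep(mod[i] * base, each = 36), c(6, 6, 64)), 0.025, arr))
  tr2 <- extract_trend(frames, roi = rep(TRUE, 36), frame_rate = fs)
  depth_true <- 1 - 0.6
  depth_got <- (max(tr2$values) - min(tr2$values)) / max(tr2$values)
  expect_equal(depth_got, depth_true, tolerance = 0.05 * depth_true + 1e-9)

  # venous lag: the vein's falling edge trails the artery's by the delay
  # (looking at the second cycle, past the t = 0 start-up)
  pa <- simulate_trend_series(protocol_spec("hypoxia_cycle"), 460, 0.1, roi = "artery")
  pv <- simulate_trend_series(protocol_spec("hypoxia_cycle"), 460, 0.1, roi = "vein")
  fall_after <- function(p, t0) {
    i <- which(diff(p$values) < 0 & p$time[-1] > t0)[1]
    p$time[i + 1]
  }
  expect_equal(fall_after(pv, 100) - fall_after(pa, 100), 15,
               tolerance = 0.1 + 1e-9)

  expect_error(extract_trend(fr, roi = logical(36)), class = "obscope_usage_error")
})

test_that("oxygen-saturation calibration recovers a known line", {
  so2 <- c(98, 85, 70, 60, 48)
  amp <- 120 - 0.76 * (98 - so2)
  tr <- trend_series(seq_along(so2), amp, roi = "artery")
  fit <- suppressWarnings(fit_so2_linear(tr, so2))  # exact fit: lm warns
  expect_equal(fit$slope, 0.76, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  set.seed(2)
  trn <- trend_series(seq_along(so2), amp + rnorm(5, sd = 1), roi = "artery")
  fitn <- fit_so2_linear(trn, so2)
  expect_lt(fitn$r_squared, 1)

  expect_error(fit_so2_linear(tr, rep(50, 5)), class = "obscope_fit_error")
  expect_error(fit_so2_linear(trend_series(1:2, c(1, 2), "artery"), c(1, 2)),
               class = "obscope_usage_error")
})

test_that("decay fitting recovers the programmed coefficient", {
  k <- 3.6e-4
  blood <- simulate_trend_series(protocol_spec("agent_decay", k = k, noise_sd = 0.5),
                                 2000, 2, roi = "vein", seed = 1)
  tissue <- simulate_trend_series(protocol_spec("agent_decay", k = k),
                                  2000, 2, roi = "tissue")
  fit <- fit_decay(blood, tissue)
  expect_equal(fit$k, k, tolerance = 0.1)  # within 10% of the true coefficient
  expect_gt(fit$r_squared, 0.9)
  expect_lte(fit$r_squared, 1)

  # zero-decay fixture: k ~ 0 within the noise scale
  b0 <- simulate_trend_series(protocol_spec("agent_decay", k = 0, noise_sd = 0.2),
                              2000, 2, roi = "vein", seed = 2)
  f0 <- fit_decay(b0, tissue)
  expect_lt(abs(f0$k), 5e-5)
})

test_that("decay recovery stays within 10% median error over replicates", {
  k <- 3.6e-4
  tissue <- simulate_trend_series(protocol_spec("agent_decay", k = k),
                                  2000, 2, roi = "tissue")
  # 20 dB amplitude SNR on a ~100 a.u. trace
  errs <- vapply(1:100, function(s) {
    b <- simulate_trend_series(protocol_spec("agent_decay", k = k, noise_sd = 10),
                               2000, 2, roi = "vein", seed = s)
    abs(fit_decay(b, tissue)$k - k) / k
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("faster blood decay than tissue is detected on the printed fixture", {
  # blood down 28% at 2000 s, tissue down 10%
  blood <- simulate_trend_series(
    protocol_spec("agent_decay", k = 3.6e-4, agent_fraction = 0.39),
    2000, 2, roi = "vein")
  tissue <- simulate_trend_series(protocol_spec("agent_decay"), 2000, 2,
                                  roi = "tissue")
  expect_equal(blood$values[blood$time == 2000] / blood$values[1], 0.72,
               tolerance = 0.005)
  expect_equal(tissue$values[tissue$time == 2000] / tissue$values[1], 0.90,
               tolerance = 0.005)
  flat <- trend_series(blood$time, rep(1, length(blood$time)), "tissue")
  # the mixed blood trace is not a pure exponential; nls may hit its
  # iteration cap (warnOnly) — only the fitted-rate ordering is asserted
  kb <- suppressWarnings(fit_decay(blood, flat)$k)
  kt <- suppressWarnings(fit_decay(tissue, flat)$k)
  expect_gt(kb, kt)
})

test_that("compliance differences follow the validity rule and closed form", {
  r <- compliance(c(102, 108), c(50, 80))
  expect_equal(unname(r$dR_dP), 0.2, tolerance = 1e-12)
  # the published experiment: 102/108/114 % at 50/80/110 mmHg
  r2 <- compliance(c(102, 108, 114), c(50, 80, 110))
  expect_equal(unname(r2$dR_dP), c(0.2, 0.2), tolerance = 1e-12)
  # equal ratios -> zero compliance
  expect_equal(unname(compliance(c(105, 105), c(50, 80))$dR_dP), 0)
  # invariance to a constant ratio offset
  r3 <- compliance(c(112, 118, 124), c(50, 80, 110))
  expect_equal(r3$dR_dP, r2$dR_dP, tolerance = 1e-12)
  # a 30 mmHg point is excluded and reported
  r4 <- compliance(c(99, 102, 108), c(30, 50, 80))
  expect_equal(nrow(r4$excluded), 1)
  expect_equal(r4$excluded$pressure, 30)
  expect_error(compliance(c(99, 102), c(30, 50)), class = "obscope_usage_error")
})

test_that("diameter change from the peak signal change is exact and monotone", {
  expect_equal(fmd_diameter_change(0.163), sqrt(1.163) - 1, tolerance = 1e-15)
  expect_equal(round(100 * fmd_diameter_change(0.163), 1), 7.8)
  expect_equal(fmd_diameter_change(0), 0)
  expect_equal(fmd_diameter_change(0.21), 0.1, tolerance = 1e-12)
  p <- seq(-0.5, 0.5, by = 0.05)
  out <- fmd_diameter_change(p)
  expect_true(all(diff(out) > 0))
  expect_equal((1 + out)^2, 1 + p, tolerance = 1e-12)
  expect_error(fmd_diameter_change(-1), class = "obscope_domain_error")
})

test_that("occlusion protocols reproduce the programmed step responses", {
  for (cfg in list(list(kind = "occlusion_vein", delta = 23),
                   list(kind = "occlusion_artery", delta = -37))) {
    tr <- simulate_trend_series(protocol_spec(cfg$kind), 220, 0.5)
    base <- tr$values[tr$time < 60]
    occ <- tr$values[tr$time >= 60 & tr$time < 100]
    expect_equal(mean(occ) / mean(base) - 1, cfg$delta / 100, tolerance = 1e-9)
  }
})
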