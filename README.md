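# obscope

Computational stack for a flexible, wearable optoacoustic blood
"stethoscope" — a skin patch that delivers pulsed light into superficial
vessels through a 5 x 5 micro-lens array and records the laser-induced
ultrasound on a 6 x 6 grid of piezoelectric elements (2.28 mm² each,
0.15 mm gaps, 7.8 MHz centre frequency, ~100% fractional bandwidth).
`obscope` implements everything between the raw multi-channel traces and
the cardiovascular readouts:

* **PS-NUFFT reconstruction** — Fourier-domain volumetric imaging for
  layered media. The recorded field `p(x, y, z = 0, t)` is transformed to
  `P(kx, ky, omega)`, extrapolated through each layer by the phase shift
  `exp(-i sign(omega) kz_l d_l)` with
  `kz_l = sqrt((omega/c_l)^2 - kx^2 - ky^2)`, resampled onto a uniform
  `kz` grid along the Stolt dispersion relation
  `omega = c sqrt(kx^2 + ky^2 + kz^2)` with the Jacobian
  `c kz / sqrt(kx^2 + ky^2 + kz^2)` using a windowed-sinc (non-uniform FFT)
  basis, and inverted by a 3D inverse FFT — `O(L n^3 log n^3)` overall.
  Pre-migration redatums gently bent arrays onto the fitted reference
  plane.
* **Delay-and-sum baseline** with straight-ray and Fermat-refracted
  layered travel times (the `O(n^5)` comparison arm).
* **Forward simulator** — an independent point-absorber oracle with
  refraction-correct arrival times, used as ground truth by every
  reconstruction test.
* **Image metrics** — -6 dB profile widths, CNR
  (`20 log10(|mu_s - mu_b| / sd_b)`) and gCNR (one minus histogram
  overlap).
* **Monte Carlo photon transport** comparing the micro-lens, central-window
  and side illumination schemes in dermis-like tissue
  (`mu_s = 357 1/cm`, `mu_a = 0.46 1/cm` at 532 nm), with the -20 dB
  blind-region / effective-area metric.
* **Receive-field model** — Rayleigh-integral element sensitivity maps,
  array field-of-view statistics, and the bandwidth-criterion axial
  resolution.
* **Vascular biomarkers** — oxygen-saturation calibration (mV per % sO2),
  exponential exogenous-agent decay against a tissue baseline, venous
  compliance `dR/dP` (% per mmHg, readings at <= 40 mmHg excluded), and
  flow-mediated dilation `sqrt(1 + p_A) - 1`.

## Worked example

Simulate the packaged two-layer comparison fixture (point target at
x = 3.5 mm under a 1 mm, 1030 m/s device standoff), reconstruct with both
methods, and compare:

```r
library(obscope)

cd  <- fixture_channels(seed = 1)                 # 32 x 32 x 512 channels
vol <- reconstruct_psnufft(cd, fixture_medium(),  # Fourier-domain method
                           nz = 150, dz = 0.08, upsample = 4)
dvol <- fixture_das(cd)                           # traditional DAS arm

fixture_resolution(vol)    # 0.4236 mm  (-6 dB lateral width, PS-NUFFT)
fixture_resolution(dvol)   # 1.3877 mm  (DAS under the homogeneous-skin assumption)
cnr(vol,  fixture_rois(vol))    # 21.29 dB
gcnr(vol, fixture_rois(vol))    # 0.7518
gcnr(dvol, fixture_rois(dvol))  # 0.6054
```

The Fourier-domain method renders the point three times narrower and with
higher contrast than the traditional beamformer, whose homogeneous-path
assumption smears the target into a displaced ring. A biomarker example:

```r
blood  <- simulate_trend_series(protocol_spec("agent_decay", k = 3.6e-4,
                                              noise_sd = 5),
                                duration = 2000, dt = 2, roi = "vein", seed = 5)
tissue <- simulate_trend_series(protocol_spec("agent_decay", k = 3.6e-4),
                                duration = 2000, dt = 2, roi = "tissue")
fit_decay(blood, tissue)
#> <decay_fit> k = 0.00036 1/s, R^2 = 0.885, RMS agreement = 92.5%

100 * fmd_diameter_change(0.163)   # 7.84 (% diameter change at peak A)
axial_resolution(7.8, 1.0, 1500)   # 192.3 um
```

See `vignettes/obscope-methods.Rmd` for the model, its assumptions, the
fixture definition and known limitations.

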