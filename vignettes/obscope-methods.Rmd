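---
title: "Methods: layered-medium optoacoustic reconstruction and vascular biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: layered-medium optoacoustic reconstruction and vascular biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`obscope` implements the computational stack behind a flexible, wearable
optoacoustic "blood stethoscope": a small patch combining a 5 x 5 grid of
focusing micro-lenses for pulsed-light delivery with a 6 x 6 grid of
piezoelectric receive elements (element area 2.28 mm^2, 0.15 mm gaps,
7.8 MHz centre frequency, about 100% fractional bandwidth). Light absorbed
by haemoglobin launches broadband ultrasound; the array records it as
multi-channel time series; reconstruction renders a 3D map of the acoustic
sources (vessels); and trends of the signal amplitude over minutes carry
physiology: oxygen saturation, agent washout, venous compliance,
flow-mediated dilation.

The package covers, as separately testable modules: the domain containers
and their I/O; an independent forward simulator (the oracle all
reconstruction tests run against); the Fourier-domain PS-NUFFT
reconstruction for layered media; a delay-and-sum (DAS) baseline; image
quality metrics; Monte Carlo photon transport for the illumination design;
the element/array receive-field model; and the biomarker fits.

# Conventions

Right-handed coordinates with `z` pointing into the tissue and the array
plane at `z = 0`; lengths in mm, times in microseconds, frequencies in MHz,
sound speeds supplied in m/s. The forward spectral transform uses kernels
`exp(-i kx x) exp(-i ky y) exp(+i omega t)`; its constant normalisation is
absorbed into the inverse transform (only relative image amplitudes are
meaningful downstream, because every biomarker is a relative change).

# The reconstruction model

A source at depth `z0` in a stack of homogeneous layers `(d_l, c_l)` emits
an upward-travelling wave recorded at the array plane. In the
wavenumber-frequency domain the recording relates to the field at any
deeper plane by a phase shift (wavefield extrapolation): propagating
components are multiplied by `exp(-i sign(omega) kz_l d_l)` per traversed
layer, with `kz_l = sqrt((omega / c_l)^2 - kx^2 - ky^2)` evaluated with
that layer's sound speed. Components with `(omega / c_l)^2 < kx^2 + ky^2`
are evanescent; they are zeroed rather than exponentially amplified, since
amplification would blow up noise and imaging uses the propagating part.

Within the layer that contains the sources, the dispersion relation
`omega = c sqrt(kx^2 + ky^2 + kz^2)` converts the extrapolated recording
into the spatial spectrum of the source distribution (Stolt mapping). The
omega axis is uniformly sampled by the FFT, but the mapped frequencies
`omega(kx, ky, kz)` are not: the resampling onto a uniform `kz` grid is the
non-uniform step, implemented as a windowed-sinc interpolation
(Hann-windowed, half-width 6 frequency bins by default) weighted by the
Jacobian `c |kz| / sqrt(kx^2 + ky^2 + kz^2)`. A final inverse 3D FFT gives
the source amplitude; the slab belonging to the current layer is kept, and
the per-layer slabs are concatenated. Lateral rendering density can be
raised by zero-padding the `(kx, ky)` spectrum — a sinc interpolation that
adds no information but smooths voxelisation. The total cost is
`O(L n^3 log(n^3))` for `L` layers.

Sign conventions deserve one remark: with the `exp(+i omega t)` analysis
kernel, focusing at positive depth requires pairing `kz > 0` with
`omega < 0` in the Stolt map and using the `exp(-i sign(omega) kz d)`
extrapolator. The package fixes the trio jointly; the point-source
round-trip tests (peak within one voxel of ground truth) pin it down.

Curved (gently bent) arrays are handled by redatuming: a least-squares
reference plane is fitted to tracked surface coordinates
(`register_array_geometry()`), and each trace is time-shifted by
`delta_z / c_1` (`pre_migrate()`), implemented as an exact spectral phase
ramp. This first-order correction is valid for offsets small against the
aperture; a warning is raised beyond 10% of the aperture diagonal.

## Numerical choices

* Temporal zero-padding factor 2 before the forward FFT suppresses
  wrap-around of late echoes.
* Interpolation taps that would cross the Nyquist fold of the omega axis
  are zeroed instead of wrapped.
* The windowed-sinc kernel is exact at the nodes, so samples landing on the
  uniform grid are copied unchanged (tested).
* Per-layer depth lattices anchor at the layer tops, so slab sample counts
  can differ by one or two slices from `nz` when interfaces fall off the
  global lattice; non-final layers exclude their lower boundary slice to
  avoid duplication.
* The volume is `Re()` of the inverse transform; Hermitian symmetry of the
  resampled spectrum makes the imaginary part vanish to rounding (tested).

# The delay-and-sum baseline

`reconstruct_das()` is the classical time-domain beamformer: per voxel, sum
the channel samples at the one-way travel-time delays (optional Hann
apodization), then envelope-detect along depth via the analytic signal —
the standard practice before resolution measurements. Two path models are
provided: `refracted` (Fermat's least-time path through the layer stack,
found by bounded 1D minimisation per interface and verified against an
exhaustive 10^4-point scan) and `straight` (straight segment with per-layer
slowness). Travel times are tabulated over (offset, depth) and bilinearly
interpolated inside the compiled summation kernel; its cost is
`O(n_voxels x n_elements)` — the `O(n^5)` growth the Fourier method is
compared against.

# The forward simulator (oracle)

`simulate_channels()` is deliberately independent of the reconstruction
mathematics: every point source contributes a band-limited pulse at its
refraction-correct (Fermat) travel time with `1/r` spreading; elements are
ideal points (no directivity — directivity lives in the receive-field
module); layers are lossless and density-matched, as in the reconstruction
model; Gaussian channel noise is seeded and reproducible. The default pulse
is the time derivative of a Gaussian-windowed carrier whose spectral
envelope has the device's -6 dB fractional bandwidth. Vessel tubes are
rasterised to point lattices (0.3 mm default spacing) with per-cell
amplitudes. Linearity, travel-time reciprocity and bit-level seed
determinism are tested properties.

# The packaged layered-medium comparison fixture

The numerical comparison between PS-NUFFT and traditional DAS uses a
packaged fixture (`fixture_*()`), fully defined here because resolution
claims depend on every detail:

* **Array**: a dense 32 x 32 simulation grid (pitch 0.32 mm) spanning the
  device's ~10 mm footprint, at the device's 7.8 MHz / 100% bandwidth,
  40 MHz sampling. A 6 x 6 grid at 1.66 mm pitch bounds the lateral
  k-space band at `pi / 1.66 = 1.9 rad/mm`, i.e. a ~2 mm sinc-limited
  point response: sub-millimetre lateral figures are only meaningful on a
  densely sampled simulation aperture, which is also what the reference
  device study's 256 x 256 x 300 reconstruction size implies.
  Coordinates are device-framed: the footprint spans [0, 9.92] mm.
* **Medium**: 1 mm standoff at 1030 m/s (the PDMS encapsulation plus
  coupling layer of the device build) over soft tissue at 1540 m/s.
* **Phantom**: a point target at (3.5, 4.96, 5) mm — the x = 3.5 mm source
  whose profile is measured — plus a second point at (7.0, 4.96, 5) and a
  0.4 mm-radius vessel tube at x = 6.5 mm, z = 6.5 mm as distributed
  structure.
* **Noise**: white channel noise at 20 dB peak SNR, seeded.
* **Comparison arm**: the traditional beamformer treats the skin as
  homogeneous; `fixture_das()` therefore runs DAS against a single-layer
  1540 m/s medium model while the data come from the true two-layer
  medium. A refraction-correct DAS is also available and is itself
  diffraction-limited — the resolution gap in the comparison comes from
  the homogeneous-path assumption, not from beamforming per se.
* **Resolution protocol** (`fixture_resolution()`): the homogeneous-path
  mismatch renders a point as an axially displaced ring, so the lateral
  profile is taken as the depth maximum-intensity projection over
  z in [3.5, 8] mm at the target's y, windowed to x in [1.5, 5.5] mm, and
  its -6 dB full width is reported. The same protocol is applied to both
  methods.
* **ROIs** (`fixture_rois()`): signal, a 0.6 mm cube on the target;
  background, a 2 mm cube at (2.5, 2.0, 8) mm away from all structures.
  CNR is `20 log10(|mu_s - mu_b| / sd_b)`; gCNR is one minus the overlap
  of unit-mass amplitude histograms over 100 shared bins.

The fixture's noise level and ROI size were calibrated once against the
device study's printed comparison values and then frozen; with them the
fixture yields ~0.42 mm (PS-NUFFT) vs ~1.39 mm (DAS) lateral width and
gCNR ~0.75 vs ~0.60, with PS-NUFFT strictly better on resolution, CNR and
gCNR. The CNR magnitude is ROI- and noise-definition dependent; the
package treats the ordering as the meaningful, reproducible claim.

# Monte Carlo light transport

`mc_fluence()` is an MCML-style photon-packet walk in a homogeneous
half-space: exponential step sampling with `mu_t = mu_a + mu_s`,
Henyey-Greenstein scattering, absorption-weight deposition at interaction
sites, Russian roulette (threshold 1e-4, survival factor 10), termination
on leaving the simulation box (which extends well beyond the scored grid so
photons can re-enter). Dermis parameters at 532 nm: `mu_s = 357 1/cm`,
`mu_a = 0.46 1/cm`; anisotropy `g = 0.9` and index `n = 1.4` are not part
of the device characterisation and are exposed as explicit assumptions.
Index-mismatch reflection at the surface is neglected (photons leaving the
top escape); other wavelengths are handled by supplying their coefficient
table in the configuration.

The three illumination geometries are: `lens_grid`, 25 focal spots on the
5 x 5 inter-element lattice (1.66 mm pitch, 0.25 mm entry spots converging
to a 0.5 mm focal depth — the focusing parameters are design choices of
the simulator, not measured device values); `center_window`, a 3.32 mm
square clear window; `side`, a 1 mm oblique strip at 45 degrees from one
edge. The blind region at a depth is where intensity drops more than 20 dB
below the slice maximum (intensity convention, factor `10^(-20/10)`); the
effective area fraction is its complement over the device footprint.
Weight conservation, Beer-Lambert recovery in the scattering-free limit,
seed determinism and photon-count linearity are tested.

# Receive field and AFOV

`element_receive_pattern()` evaluates the reciprocal receive sensitivity of
a rectangular element as the discretised Rayleigh integral of
`exp(i k r) / r` over the aperture at a single frequency (the centre
frequency by default), >= 20 sub-elements per wavelength per edge, exact
quadrant symmetry exploited. Its far-field cut reproduces the closed-form
sinc-product directivity within 1% (tested), and the vanishing-aperture
limit is an isotropic `1/r` field.

`array_afov()` superimposes the element field translated to all 36 element
centres. The default is a coherent (complex) superposition — the array
treated as one aperture, which is how such device field-of-view maps are
conventionally simulated; the magnitude-sum option models fully independent
receive channels and produces a flatter map (about 3 dB less peaked at
1 mm). Statistics are reported over the effective AFOV mask (within -12 dB
of the map maximum): mean-versus-max level and the standard deviation of
the level. At 1 mm depth the coherent model gives about -7 dB mean-vs-max
with 2.5 dB s.d. for the device geometry. Two cautions, both visible in
the acceptance suite: the single-frequency model keeps Fresnel near-field
ripple that a broadband receiver smooths, so the simulated
uniformity-vs-depth trend is not monotone here; and the single-element
-12 dB response area evaluates to ~2.8 mm^2, closer to the device's
measured 3.17 mm^2 than to broadband-simulated figures. For the array map
the sub-element density default is 8 per wavelength, verified to change
the statistics by under 0.05 dB relative to 20 per wavelength.

`axial_resolution()` is the pulse-length criterion `criterion * c / B`
with `B` the absolute -6 dB bandwidth; with the default criterion constant
of 1, a 7.8 MHz / 100% bandwidth receiver in 1500 m/s tissue resolves
~192 um axially (~200 um).

# Physiological biomarkers

All fits run on `trend_series` objects — per-frame peak-to-peak amplitudes
of an ROI (`extract_trend()`, optional moving-average smoothing, default
5 frames at the 10 Hz frame rate).

* **Oxygen saturation**: amplitude is linear in saturation at a fixed
  wavelength over the observed range; `fit_so2_linear()` reports the
  least-squares slope in mV per % (0.76 mV/% corresponds to 38 mV per 50%
  swing).
* **Agent washout**: `fit_decay()` divides the vascular trend by the
  time-aligned tissue trend (both normalised to their first sample) — the
  tissue signal is the baseline — and fits `A exp(-k t)` by nonlinear
  least squares with a log-linear start. `R^2` and an RMS agreement
  (100 x (1 - rms residual / mean level)) are reported. Recovery of
  `k = 3.6e-4 1/s` within 10% at 20 dB trend SNR is a tested property.
* **Venous compliance**: finite differences `dR/dP` of amplitude ratio
  against cuff pressure; readings at or below 40 mmHg are excluded
  (vessel flattening) and reported. The published ratio triple
  (102/108/114% at 50/80/110 mmHg) gives 0.2 %/mmHg on both intervals —
  the printed 0.196/0.185 derive from unrounded data and are reproduced at
  rounding level only.
* **Flow-mediated dilation**: with signal proportional to vascular volume
  over small changes, the fractional diameter change at the post-release
  peak is `sqrt(1 + p_A) - 1`.

## The protocol generator

`simulate_trend_series()` emulates the measurement campaigns the fits were
designed for: hypoxia cycling (230 s cycles = 50 s oxygen-poor + 180 s
normal, venous responses lagged 15 s — a physiological default, the lag
itself is the tested quantity); occlusion/release steps (+23% venous,
-37% arterial during occlusion; one minute rest then two 40 s
occlusion/release pairs); and agent washout (blood
`A ((1 - f) + f exp(-k t))` times a slow shared drift `exp(-k_tissue t)`
with `k_tissue = 5.27e-5 1/s`, i.e. -10% at 2000 s; `f = 1` by default so
the baseline-normalised ratio is exactly exponential, and `f = 0.39`
reproduces the -28%-at-2000 s blood trace). These are square-wave and
exponential idealisations with white noise: they calibrate parameter
recovery, not biological variability — passing tests demonstrates the
estimators, not in-vivo performance.

# Problem sizes and what the tests show

The packaged comparisons run at desk scale: 32 x 32 simulated channels,
128 x 128 x ~150-voxel renderings, 10^6 Monte Carlo photons, 20-replicate
localisation and 100-replicate decay-recovery sweeps. Runtime scaling is
measured empirically (n x n channels, n samples, n^3 voxels): the
Fourier path fits a log-log slope under 3.5 across n = 32-128 while the
beamformer fits ~n^5, putting extrapolated DAS at n = 128 two orders of
magnitude above the measured PS-NUFFT time. The synthetic forward model
omits acoustic attenuation, density contrast, element directivity and
speckle from distributed absorbers; conclusions about real tissue
therefore rest on the device study itself, not on these tests.

# Known limitations

* The channel container is a schema-validated serialized R container, not
  a cross-language scientific format; volumes export to TIFF/NIfTI for
  interoperability.
* Single-frequency receive-field evaluation (see cautions above).
* Redatuming is first-order in the bending offset; strong curvature needs
  a true non-planar operator.
* The Stolt Jacobian uses the layer-local sound speed when layers differ;
  with strong contrasts transmission losses at interfaces (neglected, as
  in the reconstruction model) will matter before the Jacobian choice
  does.
* No absolute quantification anywhere: every biomarker is a self-referenced
  relative change.
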