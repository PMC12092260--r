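---
title: "Planar Fabry-Perot photoacoustic tomography: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planar Fabry-Perot photoacoustic tomography: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fpscan` models the computational chain of a planar Fabry-Perot (FP)
photoacoustic tomography scanner: a thin polymer Fabry-Perot interferometer
(FPI) on the skin surface converts the photoacoustic pressure field into a
modulation of reflected optical power, an array of focused interrogation
beams reads it out point by point, and the recorded time series
`p(x, y, t)` is reconstructed into the initial pressure `p0(x, y, z)` laid
down by pulsed-laser absorption in blood. This vignette documents the
models, the numerical choices behind them, and what the synthetic phantoms
do and do not establish.

## The sensor model

The FPI transfer function (ITF, reflected power versus interrogation
wavelength) is modelled as an Airy reflectance scaled by the fringe
visibility on a unit background,

$$R(\lambda) = 1 - \frac{V}{1 + F_c \sin^2\!\big(\pi (\lambda - \lambda_0)/\mathrm{FSR}\big)},
\qquad F_c = \sin^{-2}\!\big(\pi / (2F)\big),$$

so that the stated finesse `F`, visibility `V` and free spectral range
`FSR` are reproduced exactly: the fringe FWHM is `FSR / F` and the fringe
depth is `V`. The form itself is a modelling choice — only `F`, `V` and
`FSR` are specified for the physical sensors — but it is the standard
two-mirror lossless-cavity result. Acoustic sensitivity is proportional to
the ITF slope, so the optimum bias wavelength `optimum_bias()` maximizes
`|dR/dlambda|`; of the two slope extrema per fringe the positive-slope
flank is returned by convention.

With 64 beams sharing one laser wavelength, spacer-thickness non-uniformity
spreads the per-beam optimum bias over a range `dlambda_b`. We interpret
`dlambda_b` as the *full spread* with the laser tuned to its centre, so the
worst beam is detuned by `dlambda_b / 2`. Under the Airy model a 0.08 nm
spread on a 0.35 nm fringe keeps the worst-case slope at ~85-90% of its
peak (the flatter flank is the binding side);
a one-sided detuning of the full 0.08 nm would drop it to ~74% on the
flatter flank, which is inconsistent with the engineering requirement the
spread tolerance encodes. The corresponding spacer-thickness tolerance is
the exact bilinear relation `dl = l dlambda_b / lambda_b` (~1.29 nm for a
25 µm spacer biased at 1550 nm).

The acoustic frequency response is a sinc-type thickness-averaging
magnitude with its argument calibrated per sensor so the -3 dB point equals
the stated `f3db` (35 / 31.5 / 27.6 MHz for 24.6 / 26.6 / 29.6 µm spacers).
The stated bandwidths do not scale exactly as the inverse spacer thickness
(the protective overcoat's contribution is unknown), which the per-sensor
calibration sidesteps. The spatial noise-equivalent-pressure (NEP) map is
drawn from a log-normal distribution parameterized by its mode (0.2 kPa)
and FWHM (0.25 kPa) via numerical moment matching — a skewed unimodal
family consistent with measured NEP histograms, chosen because only mode
and FWHM are known.

## Acquisition geometry and timing

The multibeam read-out uses a 4 x 16 array of interrogation spots at
324 µm pitch; all 64 A-lines of a laser pulse are simultaneous, so the
A-line rate is `N x PRF` (6,400 A-lines/s at 100 Hz, 64,000 at 1 kHz). On a
108 µm detection grid the array pitch corresponds to 3 grid steps, so each
beam covers a 3 x 3 block of sub-steps; the raster visits sub-steps in
row-major order and tiles the array across the grid. The random mode
permutes whole pulses (the beam array is rigid), giving non-overlapping
uniform coverage whose first half already samples the aperture evenly —
the property that makes sliding-window reconstruction of a continuous
random scan meaningful. Subsampling keeps the earliest-acquired fraction of
A-lines, mirroring extraction of the first 12.5/25/50% of a recorded data
set, and sliding windows advance by `round(f x window)` A-lines with
end-truncation; 153,600 A-lines, a 7,680-A-line window and 10% advance give
200 frames and a 16.7 fps refresh rate at 12,800 A-lines/s.

An efficiency factor `eta` (default 1) is exposed but never silently
applied: some reference operating points imply dead time that the pulse
arithmetic alone does not explain, and we record the discrepancy rather
than guess its source.

## Phantoms

The synthetic scenes stand in for in vivo vasculature:

* **Vessel trees** — recursive binary branching with smooth random
  curvature, per-generation radius decay (default 0.8), root radius 150 µm
  and 10 kPa initial pressure, confined to a stated depth band (0.5 mm
  downwards; the deep end is clipped to the simulated volume). Tubes are
  rasterized with a half-voxel anti-aliased edge to avoid staircase
  artefacts in PSF-sensitive tests. The generator returns the ground-truth
  centrelines and radii, so morphometrics (tortuosity, occupied volume)
  have analytic oracles.
* **Layered skin** — a superficial absorbing slab (default 200 µm, 5 kPa)
  emulating the predominantly avascular melanin-pigmented epidermis, over a
  vessel tree.
* **Point/line targets** for PSF and resolution probing.
* **Dynamic sequences** — occlusion-reperfusion: vascular regions held at
  20% of baseline during cuff occlusion, then ramped linearly to baseline
  over 2.5 s (the normal 2-3 s reperfusion time scale) after per-region
  onsets ordered artery-first; the epidermis region stays constant. A
  pulsatile vessel modulates its radius as `r0 (1 + eps sin 2 pi f t)`
  with `eps = 0.05` and `f` = 70 beats/min.

Channel noise is white Gaussian per A-line, scaled so its RMS over the
20 MHz measurement band equals that channel's NEP drawn from the log-normal
map. What these phantoms do *not* emulate: optical fluence decay and
acoustic attenuation (depth-dependent amplitude loss), tissue acoustic
heterogeneity, motion, and physiological background fluctuations — so
passing tests establish the correctness of the computational chain, not
in vivo image quality.

## The acoustic operator and its adjoint

For a homogeneous half-space with point-like detectors in the plane z = 0,
the forward map and the one-step ("k-space backprojection") inverse are
spectral remaps along the dispersion shell
$\omega = c\sqrt{k_x^2 + k_y^2 + k_z^2}$:

$$P(k_x,k_y,\omega) = \frac{\omega}{2 c^2 k_z} P_0(k_x,k_y,k_z(\omega)),
\qquad
P_0(k_x,k_y,k_z) = \frac{2 c^2 k_z}{\omega} P(k_x,k_y,\omega(k_z)),$$

with $k_z(\omega) = \mathrm{sign}(\omega)\sqrt{\omega^2/c^2 - k_\parallel^2}$,
evanescent components zeroed, and the factor 2 accounting for one-sided
detection. The sign coupling of `kz` and `omega` keeps the operator
real-to-real.

Numerical choices that matter:

* **Off-grid spectral evaluation.** The remapped axis must be evaluated at
  non-integer bins of a spectrum whose phase oscillates rapidly (content at
  depth `z` oscillates with period `~nz/z` bins), so naive linear
  interpolation destroys deep content. The implementation is a type-2
  NUFFT: the source axis is centred (so its support fits the oversampled
  band), deconvolved by the transform of a 6-tap Kaiser-Bessel kernel,
  FFT-oversampled by 1.25x, and gathered with the kernel; the centring
  shift returns as a per-output-bin phase. Spot checks against exact
  nonuniform evaluation show ~1e-4 relative accuracy.
* **Exact adjoint.** The gather is a real sparse linear map applied between
  FFTs, so the adjoint is its exact transpose between the conjugate
  transforms; the forward/adjoint pair passes the dot-product identity at
  rounding precision, which is the load-bearing contract for the iterative
  reconstruction.
* **Valid-cone taper.** The mapping diverges as `omega / (c kz) =
  1/cos(theta)` at grazing incidence. Both directions carry a raised-cosine
  taper on `cos(theta)`, unity above 0.3 (within ~72 degrees of normal) and
  zero below 0.15. Tightening the cone suppresses the lateral
  periodic-image ghosts inherent to an FFT-based operator but clips genuine
  wide-angle content of spherical wavefronts; the default is the
  permissive setting, exposed as the `taper_lo`/`taper_hi` cone policy.
* **Grids and units.** Depth pitch must satisfy `dz <= c dt` (the finest
  alias-free sampling, ~25 µm at 16.67 ns and 1500 m/s); voxel plane k sits
  at depth `(k-1) dz`. Internally distances are µm, times ns, pressures
  kPa, with conversions centralized.
* **Validation.** The on-axis waveform of a uniform 0.3 mm sphere matches
  the closed-form solution `p = (R - ct)/(2R) p0(|R - ct|)` to < 5% L2
  after band-limiting, on a geometry chosen so that the periodic lateral
  images (an inherent artefact of the spectral operator, attenuated by
  1/r spreading and the cone taper) arrive outside the compared window.
  The sensor's own response can be applied to simulated data
  (`apply_sensor_bandwidth()`); it is deliberately *not* folded into the
  operator used by the iterative reconstruction, a documented toggle.

## Preprocessing

* **Band-pass** (50 kHz - 20 MHz; 30 MHz in the high-resolution mode): the
  squared magnitude of a 4th-order Butterworth band-pass applied in the
  frequency domain — the exact zero-phase transfer function of a
  forward-backward filter, without edge transients, vectorized over all
  A-lines.
* **Spatial upsampling** (x2 routinely, x3 for dynamic line scans): Fourier
  zero-padding with Nyquist-bin splitting, so original samples are
  preserved exactly and spatially band-limited fields are reproduced at the
  new nodes. Refusing masked input is intentional: interpolating across
  unmeasured channels would fabricate data that the TV reconstruction
  handles properly.
* **Autofocus sound speed**: coarse grid search (default 25 m/s steps over
  1350-1700 m/s) maximizing the Brenner gradient (sum of squared axial
  first differences of the envelope) of trial reconstructions, refined by
  golden-section search. The metric choice is documented and swappable;
  on featureless data the profile is flat and the range midpoint is
  returned with a warning. Self-consistency tests recover simulation
  speeds of 1547 and 1650 m/s within one coarse step.
* **Attenuation correction**: post-reconstruction scaling by `exp(mu z)`
  with `mu` in 100-150 m^-1 (default 120), a first-order correction for
  fluence decay plus acoustic attenuation; exactly invertible by negating
  the exponent. Whether `mu` should be tuned per image is unknown; it is a
  plain exposed parameter.

## Reconstruction

`reconstruct_kspace()` is the one-step remap above (linear, real output,
point targets localize within a voxel), with optional x2 lateral Fourier
interpolation of the result. A dual-sound-speed composite reconstructs the
full volume at an inner and an outer speed and blends them through a
lateral region mask with a 3-pixel cosine seam — the situation where a
region such as the nail plate is acoustically faster than surrounding soft
tissue.

`reconstruct_tv()` solves

$$\min_{x \ge 0} \tfrac12 \lVert M A x - y \rVert^2 + \lambda_{\mathrm{abs}}\, \mathrm{TV}(x)$$

for subsampled data, where `M` keeps only measured A-lines (exclusion, not
zero-filling), `TV` is the isotropic forward-difference seminorm, and the
solver is monotone FISTA: gradient step `1/L` with `L` from a seeded
20-iteration power method (computed once per operator and reused for masked
operators, since `||MA|| <= ||A||`), TV proximal step by 10 dual
fast-gradient-projection iterations (C++), zero initialization so the
objective-monotonicity contract is unambiguous, and candidate rejection
with momentum restart when a step would raise the objective (three
consecutive rejections raise a divergence error naming the step size).
The weight for fully sampled data is `lambda = 12e-4`, multiplied by the
subsampling fraction for subsampled data. Because the reference value has
no stated normalization, `lambda` here is made dimensionless by scaling
with `max |A^T y|`; reconstructions are then invariant to the data scale,
at the price that the absolute weight is not numerically comparable across
implementations. A consequence worth knowing: under this convention
`lambda = 12e-4` is a light regularizer — against channel noise at the
sensor's NEP it is the implicit regularization of the finite iteration
budget, not the TV term, that sets the reconstruction noise floor, so
contrast-to-noise trends across subsampling fractions are milder (of order
0-3 dB per halving of data on the standard phantom, as the acceptance
suite measures) than regularization-dominated processing would produce.
The `lambda = 0` consistency check against the one-step image is exact
only for phantoms band-limited inside the acceptance cone; for broadband
scenes the one-step remap tapers cone-edge content that the least-squares
solution re-equalizes.

## 2D video-rate mode

A line scan with the beam array's long axis on the line synthesizes a 1.5D
array: `m` columns x 4 elevation rows. Elevation offsets for the 4 rows at
324 µm pitch are (-486, -162, +162, +486) µm about the imaging plane (the
plane convention is ours; only the pitch is fixed). Receive focusing is
depth-dependent delay-and-sum across rows with
`tau(z, y_e) = (sqrt(z^2 + y_e^2) - z)/c` evaluated at the focal depth
`z = c t` per output sample, uniform apodization (exposed), and linear
sub-sample delay interpolation. Focusing with all offsets zero reduces
exactly to the row sum; in-plane points gain nearly 4x coherently while
out-of-plane arrivals are misaligned and suppressed. In-plane images then
come from the 2D analogue of the spectral remap. Whether to focus before or
after in-plane reconstruction is not fixed by the physical system; this
package focuses first. At 15.55 mm line length, 162 µm steps and 200 Hz PRF
the frame time is 30 ms (33 fps). Vessel diameters are tracked per frame as
the FWHM of the depth profile through the column of largest integrated
intensity (the minor axis), with interpolated half-maximum crossings.

## Quantitation

* **CNR**: the stated procedure computes per-plane (x-y) mean intensities
  as the background measure and takes the peak over depth of the
  background-subtracted plane mean as the contrast. Subtracting each
  plane's own mean would null the quantity being measured, so the
  background scalar is defined as the mean of the plane means — a logged
  interpretation. Noise is the RMS in a caller-supplied feature-free
  region; CNR = 20 log10(contrast/noise), the amplitude convention
  consistent with ~3 dB steps per halving of averaged data.
* **Vessel density V_s**: intensity k-means (K = 2, deterministic
  quantile-based initial centres, hence scale-equivariant), highest-mean
  cluster as vasculature, 3D topological curve thinning to a skeleton
  (distance-ordered simple-point removal — peeling in order of city-block
  distance to background keeps the surviving curve on the medial axis,
  with endpoints and topology preserved), and V_s = skeleton voxels as a
  percentage of the volume.
* **V_I**: suprathreshold voxel count within a region of interest; the
  default threshold is background + 2x noise RMS (exposed), since "above
  the background" has no canonical definition.
* **Tortuosity index**: polyline arc length over endpoint chord; exact
  closed forms (semicircle = pi/2) and rigid-motion invariance are tested.
* **ROI time courses**: per-frame ROI means, the readout used for
  occlusion-reperfusion dynamics.

## Problem sizes and determinism

The test and acceptance workloads run on desk-scale grids: operator
contracts at 64 x 64 x 128, the compressed-sensing study on a
96 x 96 x 192 vessel phantom with 50 outer iterations, point-spread probes
over 1-12 mm depth on a 64 x 64 aperture, and smaller grids for unit
tests. These sizes were chosen as the smallest that leave the tested
properties' regimes intact (aperture angles, depth ranges, subsampling
statistics). All randomness (phantom growth, noise, scan order, solver
initialization) is seeded; fixed seeds give bit-identical iterates.

## Known limitations

* The acoustic model is lossless, homogeneous and linear; no attenuation,
  dispersion, shear modes or sensor directivity (elements are treated as
  point-like, consistent with the 49 µm spot being the effective element
  size).
* The FFT-based operator is laterally periodic: compact sources produce
  faint wrapped images of themselves, attenuated by spreading and by the
  cone taper. Test geometries place the compared signal windows away from
  these ghosts; real reconstructions see them as a weak far-field haze.
  Periodicity also means there is no finite aperture, so the lateral
  point-spread function is depth-invariant unless the data are explicitly
  windowed to a scan footprint — `psf_probe(aperture_mm = )` does exactly
  that, and the depth-dependent resolution properties are assessed there.
* Absolute reported in vivo metrics (CNR values, 60-120 µm measured
  resolution, clinical V_s / V_I / tortuosity values) depend on hardware
  and patients and are not reproduced; the package's acceptance checks are
  the corresponding structural properties (orderings, recoveries,
  invariances) on synthetic scenes.
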