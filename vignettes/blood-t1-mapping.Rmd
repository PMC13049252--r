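---
title: "Single-shot spiral inversion-recovery blood T1 mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-shot spiral inversion-recovery blood T1 mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spiralT1)
```

This vignette is the package's account of its science: the signal model and
acquisition it simulates, the reconstruction it solves, the analysis chain,
the parameters that matter, and the design decisions taken where the method
description left the design open. It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## 1. The acquisition and its signal model

A single shot measures a whole inversion-recovery curve. An adiabatic
hyperbolic-secant pulse inverts all spins; then at each inversion time
TI = 50 + 200·(k−1) ms (k = 1…55) a 90° slice excitation is followed by one
spiral readout arm. Two populations behave very differently:

* **Flowing blood** entering the slice has experienced only the inversion.
  Because ΔTI > THK/v (5 mm slice, 200 ms spacing: any velocity above
  2.5 cm/s), the blood excited at one TI has left before the next, so each
  excitation samples a fresh point of
  \[ M(TI) = M_0\,\bigl(1 - (1+\varepsilon)\,e^{-TI/T_1}\bigr), \]
  with inversion efficiency \(\varepsilon = 1\) for ideal inversion
  (`acq_params(inversion_efficiency=)` exposes it; the Bloch module
  computes what the pulse actually achieves).
* **Static tissue** is hit by every 90° pulse and recovers for only
  ΔTI = 200 ms, so it sits at the saturation plateau
  \(M_0 (1 - e^{-\Delta TI/T_1})\) in every frame. A WET pre-saturation
  train enforces the same state before the first excitation.

The temporal sparsity the reconstruction exploits is exactly this: the
background is constant in time, and blood varies smoothly.

`simulate_ir_series()` implements both branches in closed form. The
protocol literature gives two values (150 ms and 200 ms) for the delay
between pre-saturation and inversion; the package exposes
`presat_delay_ms` (default 150) and an optional `background_mode =
"exact_first"` that models the first frame's background explicitly instead
of assuming the plateau; the plateau is the default because it is the
regime the sparsity model relies on.

## 2. What the phantom emulates, and what it does not

`make_phantom()` builds a 2D slice: circular vessels (pixel-center-in-circle
rasterization — the simplest reproducible rule) inside an elliptical
"neck". The background is deliberately heterogeneous: its T1 varies
smoothly between 0.25× and 1× `background_t1_ms` through a fixed sinusoid
mixture (no randomness), emulating the fat / muscle / gland composition of
a real slice. This matters beyond realism: short-T1 tissue recovers to a
brighter saturation plateau, and that static anatomical structure is what
frame-to-frame registration anchors on. On a perfectly uniform background
the registration window contains nothing but rotating undersampling
residue whenever the target vessel crosses its inversion null, and no
metric can tell a false match from a true one.

Not emulated: through-plane flow dynamics beyond the binary refresh
assumption, pulsatility, B1 transmit inhomogeneity, physiological motion.
Passing tests therefore demonstrate correctness of the algorithms under
the stated model, not robustness to every in-vivo confound.

Default study conditions (chosen once, used by tests and the acceptance
script): 96 × 96 matrix over the protocol's 180 mm FOV, three vessels with
blood T1 1650 / 1850 / 2000 ms (a six-vessel bilateral layout spanning
1550–2050 ms serves the repeatability study), four coils with smooth
Gaussian-lobe sensitivities, 4800 samples per arm (12 ms readout at 2.5 µs
dwell), and complex k-space noise `noise_sigma = 2.0`, which puts the
gridding-reconstruction SNR of vessel blood at equilibrium near 30 —
typical of single-shot spiral imaging. The full 180 × 180 protocol matrix
is available by setting `res_mm = 1`; the 96-point matrix is the package's
standard desk-scale study size.

## 3. Trajectory design

`design_vd_spiral()` integrates a constant-angular-velocity Archimedean
spiral whose local radial pitch is `reduction(r)` times the Nyquist pitch
1/FOV: reduction 1 inside 15 % of k-max, 5 outside 50 %, linear in between.
Gradient hardware (slew, amplitude, eddy currents) is not modeled: the arm
is a sampling geometry, and reconstruction correctness does not depend on
how a scanner would realize it. The arm ends exactly on the Nyquist radius
matrix/2 (in cycles/FOV). Rotation is counter-clockwise in (kx, ky),
angles in degrees — a convention fixed for bit-reproducibility.

Density compensation uses the analytic annular-area element |k|·d|k| per
sample with a small-radius floor, normalized so the weights sum to N²; a
centered point source then reconstructs at its true amplitude under the
1/N²-scaled adjoint. The acquisition's effective acceleration is reported
as Nyquist-disk samples ÷ acquired samples (`effective_acceleration()`);
the package does not claim this matches any particular undersampling
factor quoted for the in-vivo protocol, whose counting convention is not
stated.

## 4. The non-uniform Fourier transform

Two implementations share one coordinate convention (image indices
centered on the matrix center, k in cycles/FOV, negative exponent
forward):

* `nudft_forward()` / `nudft_adjoint()` — direct summation, exact, capped
  at 64 × 64; this is the oracle.
* `nufft_plan()` + `nufft_forward()` / `nufft_adjoint()` — Kaiser–Bessel
  gridding: 2× oversampled FFT, width-6 kernel, shape parameter from the
  standard minimal-aliasing formula, deapodization by the kernel's exact
  continuous Fourier transform. The interpolation is a stored sparse
  matrix, so forward and adjoint are exact conjugate transposes by
  construction; accuracy against the oracle is ~1e−6 relative (tested at
  1e−3 tolerance).

## 5. The reconstruction

`solve_ktsparse()` minimizes
\( \tfrac{1}{N^2}\|k - SFI\|_2^2 + \lambda \sum \sqrt{|D_t I|^2 + \epsilon^2} \)
by Polak–Ribière nonlinear conjugate gradient with backtracking line
search; `D_t` is the forward temporal difference. Numerical conventions:

* **Scale.** λ is meaningless without a scale convention, so k-space is
  normalized to unit 98th-percentile magnitude of the density-compensated
  adjoint image, and the fidelity term carries the 1/N² Parseval factor of
  the unnormalized transform. Both are needed: without the Parseval factor
  the fidelity term is ~10⁴ times the TV term and λ = 0.1 does nothing
  (measurably: temporal artifacts survive and vessel T1 errors reach tens
  of percent).
* **Smoothing.** The ℓ1 term uses ε = 1e−6 of the normalized signal scale.
* **Initialization.** The density-compensated adjoint — deterministic and
  close enough that 60 iterations (the default) converge the study used
  here; the solver is stochastic-free, so fixed inputs give bit-identical
  output.
* **Line search.** The first trial step is the exact minimizer of the
  quadratic part along the search direction; E·direction is computed once
  per iteration so backtracking costs only vector arithmetic.
* **Boundary.** Forward differences with the padding scheme handling the
  physical series ends; the prepended frames carry negated k-space
  (`pad_frames()`), so the magnetization discontinuity at TI = 0 is turned
  into a smooth continuation and the golden-angle pattern continues across
  the seam (134.46° vs 137.51°).

The complex reconstruction is phase-aligned per pixel with the last
frame's phase (blood near equilibrium, everything positive) and the real
part is taken (`signed_real_series()`); whether the original
implementation fitted complex, magnitude or signed-real images is not
stated, and this choice is documented rather than claimed equivalent.

Off-resonance deblurring (`deblur_offres()`) is frequency-segmented on the
Cartesian spectrum of each frame, using the readout-time-versus-k-radius
map t(|k|) derived from the spiral arm: each frame is demodulated at
`n_bins` (default 9) frequencies spanning the B0 map's range and combined
per pixel by linear interpolation at the local offset. Implemented this
way, zero offset is an exact identity and a spatially uniform offset
reduces exactly to single-frequency demodulation — both are tested. The
t(|k|) approximation is exact for a center-out arm up to its azimuthal
position, the standard trade of this correction family.

## 6. The analysis chain

**Registration** (`register_frames()`): consecutive frames, rigid
(translation + rotation about the ROI center), on magnitude images
restricted to the 20 × 20 mm window around the target vessel; cumulative
composition aligns all frames to frame 1. The pipeline registers
separately per target vessel: a spurious rotation about one vessel's pivot
would displace distant vessels. The optimizer is a regular-step descent
(normalized-gradient steps, halved on failure to improve, then a cyclic
per-coordinate polish). Look–Locker series punish naive metrics, and the
following choices were each forced by a measured failure mode:

* *z-normalized MSE* (equivalently, normalized cross-correlation) instead
  of raw MSE: the global intensity of consecutive frames differs as the
  signal recovers, and raw MSE converts that brightness change into
  spurious brightness-compensating shifts that accumulate over ~50
  compositions.
* *Minimum-improvement acceptance and per-coordinate parsimony*: rotation
  of a small near-circularly-symmetric ROI is close to unidentifiable, and
  unconstrained it random-walks away from identity on noise.
* *Reliability gate*: a pair whose optimized transform explains <10 % of
  the initial mismatch has no registrable structure (the vessel near its
  null) — the honest answer is "no detectable motion".
* *Skip-one-frame corroboration*: an isolated false match must agree with
  the transform found across the skipped predecessor or it reverts to
  identity.
* *0.3 px / 0.3° deadband*: the reconstruction itself moves the apparent
  vessel centroid by fractions of a pixel as the signal re-emerges through
  its null (PSF and partial-volume physics, not motion); tracking that
  creep corrupts the fitted curve. Sub-deadband motion is declared
  undetectable — a real slow drift below 0.3 px/frame would be missed,
  a documented limitation.

**Segmentation** (`segment_fwhm()`): 4-connected region growing at 0.7 ×
the region's peak, with the peak refined iteratively (the threshold is
relative to the vessel's peak, not the seed's value). "FWHM with a 0.7
threshold" is read as this fraction-of-peak rule — the reproducible
interpretation of a name that mixes two conventions. Segmentation runs on
the last acquired frame, where blood is near equilibrium and bright; the
first frame, sometimes named as the segmentation phase, has near-null
blood magnitude at typical blood T1 and would make the 0.7 threshold
unstable. The frame is configurable.

**Fitting** (`fit_ir_t1()`): Levenberg–Marquardt least squares of the
three-parameter model on the 50 acquired TIs (padded frames excluded),
multi-started over T1 ∈ {300, 800, 1600, 2400} ms to cover pre- and
post-contrast regimes; the 95 % CI on T1 is the linearized
(Jacobian-covariance, t-quantile) interval, and fits with CI width
≥ 100 ms are flagged excluded. Signed-real signals are fitted directly; a
magnitude mode restores polarity by trying each candidate null position
and keeping the best residual.

**Comparison** (`compare_methods()`): Pearson r, least-squares line, and
Bland–Altman bias / 1.96-SD limits of agreement on paired percent
differences.

## 7. Preparation pulses

`hs_pulse()` builds the 13.3 ms hyperbolic-secant inversion (peak B1
13.5 µT, bandwidth 1202 Hz). The published parameters omit the shape pair
(β, µ): the package fixes the truncation at sech(β) = 0.01 (β ≈ 5.3
dimensionless) and sets the sweep to span the stated bandwidth, which
determines µ = π·BW/β_rad ≈ 4.7. Propagation is hard-pulse
rotation-matrix integration (`bloch_simulate()`, midpoint-B1 over ≥ 2000
steps, norm-preserving without relaxation to 1e−9); convergence is tested
by step halving against a 10×-finer oracle. At exactly ±BW/2 the
inversion profile crosses Mz = 0 — that is what "bandwidth" means for this
pulse — so the band test asserts Mz ≤ −0.9 over the inner 80 % of the band
and the Mz<0 band width within 15 % of 1202 Hz.

`wet_train()` / `wet_residual()` model the four-pulse WET saturation
(89°, 98°, 82°, 157°; 4.2 ms rectangular sub-pulses — the vendor's
optimized shape is proprietary and rectangular is documented, not claimed
equivalent) with T1 recovery between sub-pulses and spoiled transverse
magnetization. The instantaneous limit is the product of cosines,
≈ 3.1 × 10⁻⁴, and the residual stays below 2 % across T1 400–4200 ms.

## 8. Problem sizes and study design

The package's standard study sizes, used by the test suite and acceptance
script: operator oracles at 16 × 16 (400 samples); solver unit studies at
32 × 32 with an 8+2(+2) frame schedule and 600-sample arms; the main
recovery study and padding ablation at 96 × 96 with the full 55-frame
shot, 4 coils, 4800-sample arms; the repeatability study at 64 × 64 with
six vessels and two independent noise realizations, compared by
`compare_methods()`. All randomness flows from one seed; per-frame noise
substreams are derived deterministically from it.

## 9. Known limitations

* The solver is a smoothed-ℓ1 NCG, not a proximal method; very large λ
  values converge slowly.
* Deblurring assumes the time-radius map of a center-out arm; it is not a
  general conjugate-phase reconstruction.
* Registration cannot see motion below its deadband or during frames with
  no registrable structure; it reports identity there by design.
* The inflow model is binary (fully refreshed or static); slow or
  recirculating flow violates it, and the simulator warns when the refresh
  condition fails.
* Vessel rasterization has no partial-volume edge model, so segmentation
  accuracy statements concern the reconstruction, not sub-pixel vessel
  delineation.
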