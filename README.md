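# spiralT1

Ultrafast blood T1 mapping from a **single-shot, golden-angle rotated,
variable-density spiral** inversion-recovery acquisition — simulation,
reconstruction and quantification in one R package.

## The problem

Blood T1 is a direct readout of blood composition (hematocrit, oxygenation,
gadolinium concentration), and measuring it in the internal jugular veins or
carotid arteries gives a fast, contact-free window on those quantities. The
sequence simulated here samples a full inversion-recovery curve in one shot:
after an adiabatic non-selective inversion, a 90° excitation and a single
spiral k-space arm are acquired at each of 55 inversion times
(TI = 50, 250, …, 10 850 ms; ΔTI = 200 ms). Flowing blood is refreshed
between excitations (ΔTI > THK/v), so every TI sees a clean point on the
recovery curve, while static tissue is pinned to a constant
saturation-recovery plateau by the repeated excitations and a WET
pre-saturation train.

One arm per frame means each frame is massively undersampled. Three design
elements make the reconstruction work:

* **golden-angle rotation** (137.51° between consecutive TIs) spreads the
  arms near-uniformly over k-space for any number of frames;
* **variable-density sampling** keeps the central 15 % of k-space fully
  sampled and undersamples the rim 5-fold, with a linear ramp between;
* **k-t sparse SENSE**: the image series is recovered as

  ```
  I = argmin_I  || k − S F I ||²  +  λ || TV_TI(I) ||₁ ,   λ = 0.1
  ```

  where `F` is the non-uniform Fourier transform along each rotated arm,
  `S` the coil sensitivities, and `TV_TI` the finite-difference operator
  along the inversion-time axis, solved by nonlinear conjugate gradient.

Because temporal TV has no data beyond the series ends, the series is
padded: 5 extra TIs are appended during the shot, and 4 of them are
prepended **with their k-space sign inverted** (the magnetization before
TI = 0 is the near-mirror of the late frames, and the golden-angle seam
between frame 55 and frame 1 is 134.46° ≈ 137.51°), giving 59 frames in
the solver. The padded frames are excluded from fitting.

Downstream, each vessel is segmented by a 0.7-of-peak FWHM region grown
from a seed, frames are rigidly registered on a 20 × 20 mm² window around
the target vessel, the ROI-mean signal is fitted to

```
M(TI) = M0 + (Minit − M0) · exp(−TI / T1)
```

and fits whose 95 % confidence interval on T1 is ≥ 100 ms wide are
excluded. Paired measurements are compared by linear regression and
Bland–Altman statistics.

There is no scanner data in this package: a digital vessel phantom
generates ground-truth magnetization series and multi-coil spiral k-space
(with complex Gaussian noise and optional off-resonance), so the whole
chain is exercised end to end with known answers.

## Worked example

```r
library(spiralT1)

ti_schedule()
#> TI schedule: 50 acquired + 5 appended TIs (50..10850 ms, step 200 ms); 4 prepended -> 59 padded frames

golden_angle_schedule(55)
#> Golden-angle schedule: 55 frames, increment 137.51 deg
#>   frame 55 cumulative angle: 7425.54 deg (folded 134.46 deg)

res <- run_pipeline(pipeline_config(seed = 1))
res$report
#>   vessel true_t1_ms fitted_t1_ms pct_error r_squared ci95_width_ms roi_pixels excluded
#> 1      1       1650     1672.156 1.3427666 0.9999014      21.93254         24    FALSE
#> 2      2       1850     1864.234 0.7693926 0.9999049      24.80297         24    FALSE
#> 3      3       2000     2034.793 1.7396412 0.9997873      41.77214         15    FALSE
```

This simulates the default study — a 96 × 96 phantom (180 mm FOV) with
three vessels of blood T1 1650 / 1850 / 2000 ms in a heterogeneous static
background, 4 coils, one spiral arm per TI at an image SNR near 30 —
reconstructs the 59-frame padded series, registers, segments and fits each
vessel. The fitted T1s land within ~2 % of truth with R² > 0.999 and CI
widths far below the 100 ms exclusion threshold; `pct_error` is the
end-to-end accuracy of the whole chain, not just the fitter. The run takes
a couple of minutes on one CPU and is bit-reproducible for a fixed seed.

A thin command-line wrapper with `simulate` / `recon` / `fit` / `compare` /
`bloch` / `pipeline` subcommands is installed at
`system.file("cli/spiralt1", package = "spiralT1")`.

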