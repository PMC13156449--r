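# naheart

Quantitative myocardial sodium (²³Na) MRI with an interleaved ²³Na/¹H
radial acquisition: simulation, self-gating, motion correction,
anatomy-based B1 bias correction, and apparent tissue sodium
concentration (aTSC) quantification — validated end to end on a dynamic
digital torso phantom.

## Who this is for

Sodium MRI groups who want to prototype or validate the correction chain
of a free-breathing cardiac ²³Na/¹H protocol without scanner data: the
package simulates the full interleaved acquisition over realistic
respiratory and cardiac motion, runs the retrospective corrections the
way they would run in vivo, and checks the recovered concentration
against the programmed ground truth.

## The method

One ²³Na excitation (TR 60 ms, TE 1.15 ms, FA 82°) alternates with two
¹H excitations (TRs 13.08/20.76 ms, FA 10°), both reading out 3D
golden-angle radial projections; each ¹H excitation carries a 10-sample
k-space-centre (k₀) navigator. From the navigators the package derives
a respiratory signal (1.5 s moving average) and a cardiac trigger signal
(spectral peak in 0.5–2 Hz, Butterworth bandpass at f_card ± 2 w_card).
Corrections, in fixed order:

1. **Respiratory**, rigid, in k-space: eight equal-count amplitude bins,
   each bin's ¹H image registered to the exhaled bin, the transform
   applied as a trajectory rotation plus phase ramp
   e^{+2πi k·t} to both nuclei. No data discarded.
2. **Cardiac**, nonrigid: ten phases clustered into systole/diastole by
   SSIM + k-means; a B-spline deformation field estimated from the
   bias-corrected ¹H images warps the systolic ²³Na image into diastole;
   corrected image = count-weighted average.
3. **B1 bias field** (the core algorithm): a synthetic ²³Na prior
   r·RSF_myo + RSF_blood is built from the segmentations via
   T2*-dependent point-spread functions; the bias field is the quotient
   of the Gaussian-filtered (σ = 10 mm) measured and prior images inside
   the heart, B1(x) ≈ sin(FA(x))·B1⁻(x); the assumed ratio r is iterated
   over [0.3, 0.7] until the PVC-measured ratio reproduces it.
4. **Partial-volume correction**: 2×2 unmixing of myocardium/blood mean
   signals by region-spread-function overlap.
5. **Relaxation correction**: divide by
   [r e^{−TE/T2s*} + (1−r) e^{−TE/T2l*}] · (1−e^{−TR/T1})/(1−cos FA·e^{−TR/T1}),
   with the blood-pool median flip angle (dual-TR AFI, including its
   finite-T1 bias model).

Finally aTSC_myo = c_blood · S̄_myo/S̄_blood with
c_blood = (1 − hematocrit)·c_serum.

## Worked example

A beating-heart acquisition (45 s, 60 bpm, fully exhaled), corrected and
quantified against the phantom's 43 mM myocardial ground truth:

```r
library(naheart)

geometry <- phantom_geometry(grid_shape = c(48, 48, 48), voxel_mm = 5)
seqp     <- sequence_params(na_nominal_mm = 5, h_nominal_mm = 5)
coil     <- coil_sensitivities(geometry, n_channels = 2, seed = 1)

sim <- assemble_composite_kspace(geometry, motion_params(), seqp,
                                 TA_s = 45, mode = "cardiac", coil = coil)
sim$na
#> <kspace_set 23Na: 750 projections x 64 samples x 1 channel(s)>
sim$nav
#> <navigator_series: 1500 samples x 2 channels>

result <- run_pipeline(sim, geometry, seqp, grid = 48, voxel_mm = 5,
                       steps = c("cardiac", "b1", "pvc", "relax"))
sprintf("aTSC = %.1f mM (myo-blood ratio %.3f, r_opt %.3f)",
        result$atsc_mM, result$ratio, result$r_opt)
#> "aTSC = 43.6 mM (myo-blood ratio 0.539, r_opt 0.540)"
sprintf("cardiac frequency %.2f Hz, diastolic fraction %.2f",
        result$gate$f_card, result$cardiac$frac_dia)
#> "cardiac frequency 1.00 Hz, diastolic fraction 0.60"
result$image
#> <image3d 23Na [diastole], 48x48x48 voxels @ 5.00 mm, 750 projections>
```

The self-gating recovered the programmed 60 bpm rhythm and the 60%
diastolic fraction, and the corrected, calibrated concentration lands
within 1.5% of the 43 mM ground truth (the concentration ratio 0.539 is
the estimate of 43/81 ≈ 0.531).

The validation experiments behind the test suite are exported:
`experiment_respiratory()`, `experiment_cardiac()`, `experiment_b1()`,
`experiment_repeatability()`; `run_experiment()` writes their metric
tables as CSV. A thin command-line wrapper over the same functions ships
at `inst/cli/naheart.R`. See `vignette source in vignettes/` for the
model, parameter and design documentation.

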