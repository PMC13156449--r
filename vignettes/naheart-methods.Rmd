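---
title: "Quantitative cardiac sodium MRI: simulation, motion and B1 correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative cardiac sodium MRI: simulation, motion and B1 correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(naheart)
```

## The problem

Myocardial tissue sodium concentration (TSC) is a marker of cardiomyocyte
integrity, and sodium (^23^Na) MRI can measure it in vivo. Quantification
is hard for three reasons: the sodium signal is orders of magnitude weaker
than the proton signal, so voxels are large and scans are long; the heart
beats and the chest breathes during those long scans; and at ultrahigh
field the transmit/receive (B1) profile of a torso coil varies by tens of
percent across the heart, multiplying the image by an unknown smooth bias.

`naheart` implements a complete processing chain for an interleaved
^23^Na/^1^H radial acquisition, in which one ^23^Na excitation (TR 60 ms,
TE 1.15 ms, flip angle 82°) alternates with two ^1^H excitations at TRs of
13.08 and 20.76 ms. Because both nuclei are sampled quasi-simultaneously,
high-SNR ^1^H data can drive motion estimation and anatomical priors for
the low-SNR sodium images. The package also contains a dynamic digital
torso phantom and a radial k-space simulator, so every component is
validated end to end on synthetic data with known ground truth.

## The apparent tissue sodium concentration

The final estimate calibrates the corrected mean myocardial signal against
the ventricular blood pool,

$$\mathrm{aTSC}_{myo} = c_{Na,blood}\,\frac{\bar S_{myo}}{\bar S_{blood}},
\qquad c_{Na,blood} = (1 - \mathrm{hematocrit})\, c_{Na,serum},$$

after the chain of corrections described below. The default phantom uses
a myocardial TSC of 43 mM (41 µmol/g at a specific gravity of 1.05 g/mL)
and 81 mM blood, so the pipeline's job on synthetic data is to return
43 mM.

## Phantom and simulator

The phantom (`phantom_geometry()`, `build_labels()`) is a set of
ellipsoids: torso body, two lateral lungs, a pericardial lung shell, and a
heart consisting of a myocardial shell around a ventricular blood pool.
The heart sits anteriorly and is embedded in the lung shell (the cardiac
notch), which matters quantitatively: the tissue surrounding the
myocardium determines how much out-of-model signal spills into the
myocardial mask (see Partial-volume correction below).

Respiratory motion rigidly translates heart and lungs along a raised
cosine with a 3.6 s period and (18.4, 2.4, 0) mm peak excursion in
(SI, AP, LR); `t = 0` is fully exhaled. Cardiac motion contracts the
ventricle over a 1 s cycle (400 ms systole, 600 ms diastole): the inner
radius shrinks by `contraction_fraction` (default 0.25, a plausible
surrogate for a normal ejection fraction) along a smooth systolic ramp,
recovers over the first third of diastole, and rests on a relaxed plateau;
the outer radius follows so that myocardial volume is conserved (the wall
thickens in systole). Both motions are sampled on a 60 ms state grid
(60 respiratory states; 17 cardiac states by default — the state count is
exposed as `n_cardiac_states` because phantom engines differ in their
internal phase sampling).

Tissue parameters (`tissue_params()`): only the myocardial TSC (43 mM),
blood TSC (81 mM), myocardial T2*short (3 ms) and the T1 values (30 ms
myocardium, 49.5 ms blood) are fixed by the study this package emulates;
the remaining relaxation times, the short-component fraction (r = 0.6 for
all sodium compartments), the low effective lung sodium density (4 mM,
reflecting air content), and the ^1^H parameters were chosen once from
typical literature values. The ^1^H effective densities (blood 1.3,
myocardium 0.6, body 0.8, lung 0.12) emulate the appearance of an
inflow-enhanced spoiled GRE — bright ventricular blood against darker
myocardium — which is what makes image-based gating and registration
possible in vivo.

The forward model (`forward_signal()`) evaluates, per k-space sample,

$$S(k_j) = \sum_c w_c(t_j)\, \mathcal F\{\mathbf 1_c \, s_{ch}\}(k_j),
\qquad
w_c(t) = c_c\, E_{ss,c} \left[r_c e^{-t/T^*_{2s,c}} +
(1-r_c) e^{-t/T^*_{2l,c}}\right],$$

with the spoiled steady state
$E_{ss} = \sin\alpha\,(1-E_1)/(1-\cos\alpha\,E_1)$, $E_1=e^{-TR/T_1}$,
and sample times $t_j = TE + j\,\Delta t$ along the readout. The Fourier
transform of each compartment indicator (optionally weighted by smooth
complex coil sensitivities) is evaluated by a type-2 NUFFT. Projections
follow the 3D double golden-angle scheme, so any contiguous or
motion-sorted subset covers k-space near-uniformly. A composite k-space
is assembled by simulating each projection from the phantom state at its
acquisition timestamp (`assemble_composite_kspace()`); every ^1^H
excitation also records a k-space-centre (k0) navigator as the
coil-weighted volume integral of the current state.

### Numerical choices

The NUFFT is Kaiser–Bessel gridding with 2× oversampling; kernel width 6
for the forward model (~1e-5 relative accuracy) and width 5 for
reconstruction and PSF modelling. The adjoint is the exact transpose of
the forward chain, so operator pair tests hold to machine precision.
Density compensation is the analytic $|k|^2$ quadrature rule over the
sampled k-space ball, normalized so reconstructed intensities sit on the
scale of the simulated voxel values independent of the projection count —
gated subsets and all-data reconstructions are directly comparable, and
noise scales as $1/\sqrt{n_{proj}}$. A radial Hamming filter
($0.54 + 0.46\cos(\pi |k|/k_{max})$) suppresses PSF sidelobes by more
than an order of magnitude at the cost of a wider main lobe; both the
reconstruction and the region-spread-function model include it, so the
partial-volume model stays consistent with the images. k-space noise
levels are calibrated analytically (`calibrate_noise_sigma()`): since the
reconstruction is a fixed linear combination of the samples, the image
noise per unit k-space sigma is the l2 norm of the weights, and the
experiments request a blood-pool SNR of 25 for ^23^Na (roughly the in
vivo regime) and 60 for ^1^H.

## Self-gating

The navigator magnitude series is interpolated to a uniform 15 ms grid
(`resample_navigator()`), removing the alternating-TR sampling.
Respiration: a centred 1.5 s moving average suppresses cardiac
fluctuations (at 60 bpm the attenuation is $|\mathrm{sinc}(1.5)| \approx
0.21$, at the 3.6 s breathing period 0.76); each channel's filtered
signal bins the projections of both nuclei into eight equal-count
amplitude octiles, the two extreme bins are reconstructed and rigidly
registered, and the channel with the largest SI displacement wins
(`select_respiratory_channel()`). Because the navigator sign is arbitrary
per channel, the sign of that SI translation decides which extreme is the
exhaled state (`orient_respiratory_bins()`).

Cardiac: each channel's respiration-detrended power spectrum is smoothed
with a Savitzky–Golay filter (window 21 samples, order 3) and the
dominant peak within 0.5–2 Hz located; its topographic prominence
$p_{card}$, centre $f_{card}$ and width at half prominence $w_{card}$
are extracted, the residual in-band power outside $f_{card} \pm
2w_{card}$ is $S_{noise}$, and the channel with the best
$p_{card}/S_{noise}$ is selected. A zero-phase Butterworth bandpass
(order 4, cutoffs $f_{card} \pm 2 w_{card}$) followed by peak detection
with half-period spacing and parabolic sub-sample refinement yields the
triggers; projections are sorted into 10 phases by the time since the
last trigger normalized by the local RR interval (normalization by the
local interval rather than absolute time is this package's choice — it
keeps phase labels consistent under heart-rate drift, and is switchable
by construction since the phase formula is explicit). Ten phase images
are clustered into systole and diastole by k-means on their mutual SSIM
within the heart; the larger cluster is diastole (diastole occupies 60%
of the cycle).

## Motion correction

Respiratory correction operates directly in k-space: each bin's ^1^H
image is reconstructed, support-region bias corrected (below) and rigidly
registered to the exhaled bin within the heart region; the transform is
then applied to that bin's k-space of both nuclei by rotating the
trajectory directions and multiplying the phase ramp
$e^{+2\pi i\,k\cdot t}$ (`apply_rigid_kspace()`). No projection is
discarded. The bias correction before registration matters: the static
receive profile shades the moving heart differently in each bin, and on
uncorrected images that shading biases the recovered translations by
several millimetres.

The rigid engine maximizes masked normalized cross-correlation with an
analytic gradient (BFGS with a simplex polish), multi-resolution, with a
coarse exhaustive translation search for capture range. Both images are
smoothed identically at each level — asymmetric interpolation blur
otherwise biases the metric toward the identity. A weak quadratic prior
on the Euler angles (firmer, `1e-3`, in the respiratory pipeline)
regularizes the rotation components, which are nearly unobservable for
the close-to-ellipsoidal heart; respiratory heart motion is modelled as
rigid and translation-dominated, as in the method this package
implements.

Cardiac correction is nonrigid: the bias-corrected systolic ^1^H image is
registered to the diastolic one with a cubic B-spline free-form
deformation (masked NCC, bending-energy penalty, analytic gradients,
L-BFGS, multi-resolution control spacings of 8 and 4 voxels, optimized on
the heart bounding box). The same field warps the systolic ^23^Na image
(on magnitudes — nonrigid resampling does not preserve phase), and the
corrected image is the projection-count-weighted average of diastole and
warped systole, i.e. an approximation to an all-data reconstruction in
the diastolic frame. Before the warp the ^23^Na images are zero-filled
two-fold to the ^1^H grid, as in the acquisition protocol; this also
matters numerically, because on the band-limited zero-filled grid the
trilinear warp is noise-neutral, whereas warping at acquisition
resolution would average independent voxel noise and overstate the SNR
of the corrected image. The expected SNR gain over diastolic gating is
roughly $\sqrt{1/f_{dia}}-1 \approx 25\text{–}30\%$ for a diastolic
fraction $f_{dia} \approx 0.6$, reduced by the rep-to-rep variability of
the re-estimated gating and field.

## B1 bias correction, PVC and relaxation correction

The anatomy-based ^23^Na B1 correction builds a synthetic prior from the
segmentations: each compartment mask is convolved with its own
acquisition PSF (readout T2* weighting and Hamming filter —
`compartment_psf()`), giving region-spread functions, and the prior is
$r_{assumed}\,\mathrm{RSF}_{myo} + \mathrm{RSF}_{blood}$. Both the
measured image and the prior are masked to the heart and low-pass
filtered with a mask-normalized Gaussian (σ = 10 mm; normalized
convolution avoids the edge bias of plain filtering at the mask
boundary), and their quotient is the estimated bias field

$$B_{1,bias}(x) = \frac{S_{orig,filt}(x)}{S_{prior,filt}(x)}
\approx \sin(FA(x))\,B_1^-(x),$$

normalized to mean 1 over the mask (its absolute scale is arbitrary) and
divided out voxel-wise. The measured myo-blood ratio of the corrected
image is recovered by partial-volume correction, and the assumed ratio is
iterated over [0.3, 0.7] in steps of 0.005 until measurement matches
assumption (`iterate_ratio()`; ties take the smaller ratio, and the
per-ratio loop reuses the three filtered fields, so the whole search
costs little more than one correction).

Two design points deserve emphasis. First, the RSFs carry each
compartment's known relaxation/saturation factor, so $r_{assumed}$
parametrizes the concentration-scale myo-blood ratio — consistent with a
search grid that brackets 43/81 ≈ 0.53 — and PVC plus relaxation
correction become one joint solve. Second, the filtering mask is the
tight myocardium+blood union rather than a dilated one: with a 10 mm
margin, surrounding lung signal leaks into the filtered quotient and
shifts the fixed point of the ratio iteration by about 0.03, while with
the tight mask the unbiased fixed point is recovered to better than 0.01.
The dilated mask is still the right choice for registration, where
context helps.

PVC solves the 2×2 system $M c = s$, $M_{ij} = \langle \mathrm{RSF}_j
\rangle_{mask_i}$, $s_i = \langle S \rangle_{mask_i}$. It is exact when
the image is a mixture of the two modelled compartments (recovered to
1e-6 on synthetic mixtures, and to <1% on a phantom whose surroundings
carry no sodium). With full anatomy, spillover from tissue outside the
two-compartment model biases the concentration ratio by about +2.5% at
desk resolution — the known limitation of a two-compartment PVC, which
this package keeps deliberately (extending the unmixing to more
compartments changes the method). The end-to-end budget absorbs it.

The ^1^H images use the simpler support-region variant
(`h1_bias_correction()`): an Otsu-thresholded body mask is the
homogeneous prior, σ = 12 mm. It flattens the receive shading well
enough for registration and segmentation but reduces genuine
myocardium-blood contrast — a documented side effect, acceptable because
the ^1^H images are not quantified.

Relaxation correction divides the corrected signals by

$$\left[r\,e^{-TE/T^*_{2s}} + (1-r)\,e^{-TE/T^*_{2l}}\right]
\frac{1-e^{-TR/T_1}}{1-\cos(FA)\,e^{-TR/T_1}},$$

per compartment with literature relaxation times and the subject's
blood-pool median flip angle. (The printed form of this correction in the
source literature is typographically ambiguous; this grouping — divide
out TE decay and the saturation factor, excluding the common sin FA — is
pinned by limit tests: no correction for TE = 0 and TR ≫ T1, a factor e
for r = 1, TE = T2*s.) The flip-angle map comes from the dual-TR AFI
estimator $FA = \arccos((\rho n - 1)/(n - \rho))$, $\rho = S_2/S_1$,
$n = TR_2/TR_1$, smoothed at σ = 14 mm; because TR1/2 are not ≪ T1 for
sodium, the package also models the exact two-TR steady state
(`afi_t1_bias()`) and can invert it to de-bias measured flip angles.

## Correction order and the pipeline

`run_pipeline()` enforces the order respiratory → cardiac → B1 → PVC →
relaxation (refusing reordering unless forced): motion corrections act on
k-space, the bias correction on the reconstructed image, PVC and
relaxation on compartment means. Masks are the phantom's ground-truth
compartments on the reconstruction grid — segmentation itself is outside
this package's scope, and external masks can be supplied through the same
interfaces (`truncate_blood_mask()` implements the great-vessel cutoff
for supplied blood masks).

## Validation experiments and problem sizes

The four experiments (`experiment_respiratory()`, `experiment_cardiac()`,
`experiment_b1()`, `experiment_repeatability()`) are scaled-down
reproductions of the validation studies. The package's chosen study
sizes: unit and property tests run on 32³ (8 mm) and 48³ (5 mm) grids
with 45–90 s acquisitions; the acceptance script runs the cardiac SNR
experiment at 64³ (4 mm) with a 4 min acquisition (4000 ^23^Na
projections) and 20 noise repetitions. The repeatability experiment uses
ten synthetic subjects with jittered heart geometry, each "measured"
twice; between the sessions the noise realization, the breathing depth
(8–24 mm, as session physiology varies) and the bias field's position
and tilt relative to the anatomy (repositioning within the coil) change.
It simulates respiratory motion only — combined respiratory+cardiac
state spaces multiply the simulation cost by the respiratory state
count, and the cardiac arm is validated separately — so "all
corrections" there means respiratory + B1 + PVC + relaxation, with four
fuller respiratory bins so the per-bin registration stays stable at
desk-scale projection counts. Because the phantom's masks are exact,
the segmentation variability that contributes to in vivo repeatability
is absent here; the experiment isolates the motion- and bias-driven
share.

What the synthetic phantom does and does not show: it validates the
machinery — gating recovers the programmed rates and phases,
registration recovers programmed motion, the B1 iteration recovers
programmed bias fields, and the full chain returns the programmed
concentration. It does not emulate nonrigid respiratory deformation,
through-plane cardiac twist, flow, B0 inhomogeneity, arrhythmia, or
segmentation error from a real segmenter, so passing tests bound
algorithmic correctness, not in vivo accuracy.

## Known limitations

- Two-compartment PVC leaves a small positive ratio bias under full
  anatomy (above).
- The synthetic repeatability experiment does not reproduce the
  correction-driven repeatability gain observed in vivo: with exact
  phantom masks the uncorrected calibration ratio is already very
  repeatable (no segmentation variability, concentric geometry), so the
  correction chain's own estimation variance on sparsely sampled bin
  images outweighs the session differences it removes. The experiment
  reports both coefficients honestly; interpreting them as an in vivo
  prediction would require segmentation-in-the-loop emulation, which is
  out of scope.
- Rotational components of the rigid registration are weakly determined
  on smooth ellipsoidal anatomy and are therefore regularized; programmed
  phantom motion is translational, as is the assumed respiratory model.
- The cardiac model has two clusters (systole/diastole) only.
- The ^23^Na readout is uniform radial with analytic density
  compensation rather than a density-adapted gradient waveform; gradient
  imperfections, eddy currents and B0 effects are not simulated and hence
  not corrected.
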