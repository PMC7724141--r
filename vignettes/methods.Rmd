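---
title: "Models and methods behind scwm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scwm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

scwm implements the computational chain used to ask whether a
retinotopically organized brain region carries spatial working-memory (WM)
representations during a memory delay: population receptive field (pRF)
mapping of voxel tuning, a spatial inverted encoding model (IEM) over polar
angle, a representational-fidelity statistic with permutation inference, and
a comparison of the two models' polar-angle preferences. Because the package
is validated end to end on synthetic data, the synthetic-data generator is a
first-class, tested component; this vignette explains each model, the
parameters that matter, and the design decisions taken where several
readings were possible.

## Coordinate conventions

Polar angle is measured counterclockwise from the right horizontal meridian
(0 degrees) and kept in [0, 360); Cartesian y > 0 is the upper visual field;
all spatial quantities are degrees of visual angle. The fMRI sampling
interval (TR) is 1.5 s throughout.

## The synthetic-data generator

**Retinotopy runs.** `make_bar_aperture_sequence()` renders the aperture of
a sweeping-bar mapping stimulus: an 8 degree wide bar sweeps the full +/-16
degree display in 30 s (20 TRs), once in each of four directions, with 12 s
(8 TR) blanks at the start and end of the run — 96 TRs in all. The bar
center moves linearly across the display, one position per TR at sweep-step
midpoints, so the bar enters and exits at the display edges; the step size
is a modeling choice, since only the sweep duration and bar width are fixed
by the task design. `sample_ground_truth_voxels()` draws voxels with 2D
Gaussian receptive fields, centers area-uniform over the (hemi)field, and
sizes growing linearly with eccentricity (default intercept 0.5 degrees,
slope 0.2 per degree, Gaussian size noise SD 0.3, floored at 0.05 degrees) —
values typical of subcortical visual maps. `simulate_retinotopy_run()`
computes each voxel's neural drive as the overlap of the aperture with its
Gaussian (normalized so a full-field frame gives drive 1), convolves it with
the voxel's HRF, applies gain and baseline, and adds white Gaussian noise.

**HRF.** The hemodynamic response is a difference of gamma densities
parameterized directly by its two delays — time to peak (default 6 s) and
time to undershoot (default 16 s) — with unit peak and a fixed undershoot
ratio of 1/6. Only the two delays are ever fitted; this matches the common
practice of treating lobe shapes as fixed and is the smallest parametric
family with the two free delays the fitting stage estimates.

**WM task.** `make_wm_trial_schedule()` reproduces the memory-guided
saccade (MGS) design: 16 trials of 22.5 s per run; visual targets at 8
polar-angle bins (22.5 to 337.5 degrees in 45 degree steps) jittered
uniformly within +/-10 degrees, at 9-11 degrees eccentricity; four
transformation conditions (identity, mirror across the horizontal meridian,
the vertical meridian, or both) mapping the visual target to the MGS goal;
an intervening visually guided saccade (VGS) to an independent uniform
location. Conditions are counterbalanced over pairs of successive runs —
every (condition, bin) combination occurs exactly once per pair — so each
run samples every bin exactly twice. Within a trial, the stimulus appears
at 0 s (300 ms), the delay spans 0.3-10.8 s (10.5 s), the saccade epoch
10.8-12.2 s, feedback 12.2-12.7 s, and the intertrial interval completes
the 22.5 s.

**WM responses.** `simulate_wm_dataset()` assumes the architecture the IEM
itself assumes: each voxel's delay response is a unimodal function of the
angular distance between its pRF polar angle and the encoded location
(visual, VGS, or MGS — selectable, default MGS). The tuning curve is the
same raised cosine as the IEM basis (configurable exponent), which makes
the encoding model's generative assumption literally true in the noiseless
limit and so permits exact round-trip tests. `snr` is the ratio of tuning
amplitude to the additive Gaussian noise SD. In time-series mode responses
are placed as boxcars over the delay period and convolved with the HRF.

What the generator does *not* emulate: eye movements, scanner physics,
motion, physiological noise spectra, temporal autocorrelation (available as
an option but off by default), hemodynamic nonlinearity, and voxels with
mixed or untuned selectivity. Passing tests therefore demonstrate the
correctness and internal consistency of the analysis chain, not its
performance on real noise structure.

## pRF fitting

`fit_prf()` estimates, per voxel, the Gaussian center (x, y), size sigma,
the two HRF delays, and gain/baseline, by residual-sum-of-squares
minimization in three phases:

1. **Coarse grid search** over x, y in 2 degree steps across +/-16 degrees
   and sigma in {0.5, 1, 2, 4, 8} degrees, against an effective stimulus
   downsampled by bilinear interpolation to 5% of its original resolution.
   Gain and baseline are solved in closed form at every candidate. The grid
   ranges and steps are choices; only "sparse and coarse" plus the 5%
   downsampling are inherited from the procedure being modeled.
2. **HRF delay search** over peak delay 4-9 s (step 0.5 s) and undershoot
   delay 10-20 s (step 1 s), holding the coarse spatial solution fixed.
3. **Refinement** of all five nonlinear parameters with bounded L-BFGS-B
   (numerical gradients, step 1e-5; convergence factor 10; maximum 500
   iterations; one polish restart from the first solution) against the
   full-resolution stimulus. The result never reports a lower r2 than its
   seed; failures return the seed-stage fit flagged unconverged.

Two numerical points matter. First, the linear subproblem profiles not just
gain and baseline but also a linear trend, i.e. data and prediction are
compared after projecting out the intercept-plus-trend subspace. Data
entering the fit are detrended and z-scored per run
(`detrend_zscore()`), and without the matching projection on the model side
the noiseless residual cannot reach zero. Second, r2 is defined as
1 - SSR/SST on the detrended series, with the threshold r2 >= 0.1 applied
inclusively by `select_roi()` (an anatomical fallback set can be supplied
for populations where the functional model fails). The forward model shares
one code path between simulation and fitting, so noiseless self-consistency
is exact by construction; for bar apertures the Gaussian overlap factorizes
into row and column sums (every frame is an outer product), which is what
makes the per-voxel refinement cheap.

Retinotopy summaries follow directly: `aggregate_fov()` is the pointwise
maximum of unit-height Gaussians (value 1 at every pRF center),
`polar_angle_histogram()` the fraction of voxels per angular bin, and
`size_eccentricity_stats()` the OLS line of size on eccentricity with the
Pearson correlation.

## The inverted encoding model

Nine channels tile polar angle at 40 degree spacing, each a squared
one-dimensional cosine over the full cycle,
f_k(theta) = cos^2((theta - c_k)/2) = (1 + cos(theta - c_k))/2. This is the
unimodal reading of "squared cosine": the 180-degree-periodic alternative
cos^2(theta - c_k) cannot represent a single polar location. The channels
sum to n/2 = 4.5 at every angle.

A consequence worth stating plainly: these nine functions span only the
three-dimensional space {1, cos theta, sin theta}, so the trials x channels
design matrix has rank 3 no matter how many distinct training angles are
used. `estimate_weights()` therefore returns the minimum-norm least-squares
solution via the Moore-Penrose pseudoinverse (ridge regularization is
available but off by default) and rejects only designs that fail to achieve
the basis family's intrinsic rank (fewer than 3 distinct angles). For any
voxel population whose tuning lies in the same raised-cosine family — in
particular the synthetic generator's — the minimum-norm solution recovers
the true weights exactly, which the tests exploit.

Trial preprocessing follows the delay-period logic: `delay_window_average()`
averages the last four TRs whose acquisition midpoints fall inside the
10.5 s delay (TRs 4-7 of the 7 delay TRs), and `twofold_combine()` averages
random pairs of trials within each condition x bin cell, halving the trial
count while preserving counterbalancing; labels of combined trials are
circular means. Sessions with an odd number of run pairs leave 5 trials per
cell, which cannot be fully paired; `allow_odd = TRUE` carries one unpaired
trial per cell through unaveraged, and the strict default rejects such
designs.

Training uses only untransformed ("same location") trials; inversion
applies the pseudoinverse of W to the held-out transformed trials, and each
trial's reconstruction is the channel-coefficient-weighted sum of basis
functions on a 1 degree grid. `align_and_average()` rotates each profile so
its reference location sits at 0 degrees — evaluated analytically from the
channel coefficients, so alignment introduces no interpolation error — and
averages. `bootstrap_reconstruction()` repeats the whole pass over random
re-pairings (the study-scale default is 10000 iterations; tests use tens to
hundreds). Whether the bootstrap refits W per iteration or only re-pairs
test trials is not uniquely determined by the source description; refitting
is the default here.

## Fidelity and inference

`fidelity_basic()` projects the reconstruction onto the unit vector of the
target direction: the grid mean of recon(theta) * cos(theta - target). A
flat profile scores exactly 0 and a raised-cosine profile at the target
scores exactly 0.25.

`fidelity_modified()` implements
F = \<f_stndrd, f_recon\> x g(err): the inner product of the reconstruction
with a raised-cosine standard tuning centered at the target, times a cost
function of the circular distance between the reconstruction peak and the
target. The default cost is Gaussian, g(err) = exp(-err^2 / (2 kappa^2))
with kappa = 90 degrees — the half-width at half-maximum of the standard
tuning — and g(0) = 1, so the statistic reduces to the plain inner product
for a perfectly localized reconstruction. Cosine and hard-window costs are
selectable. Two deliberate choices: the standard tuning is kept nonnegative
(not demeaned), because with a signed inner product the cost would shrink
the *magnitude* of negative values and the statistic would no longer
decrease monotonically as a profile rotates from 0 to 180 degrees
off-target; and peak ties are broken by the circular mean of the tied
maxima, with flat profiles scoring 0. Because the nonnegative standard
tuning passes the reconstruction's DC component through, null-centering
diagnostics use the basic (cosine-kernel) fidelity, whose kernel integrates
to zero, while null comparisons of the modified statistic are rank-based
(percentiles), which the DC term cannot distort.

**Permutation null.** `permutation_null()` refits the encoding model after
shuffling the training data, once per permutation, with the twofold pairing
held fixed. "Shuffling the training data" admits two readings, and they
behave very differently. Permuting the trial *labels* makes the channel
design nearly orthogonal to strongly tuned training data, so the fitted
weights shrink toward the noise floor and their pseudoinverse *amplifies*
the null reconstructions — at high SNR the null can exceed the noiseless
ceiling of the real statistic, destroying power. Permuting the *voxel
columns* severs the voxel-to-tuning correspondence while preserving the
scale of the weights, yielding a null centered at zero with calibrated
spread. The package default is the voxel shuffle; label permutation remains
available (`permute = "labels"`), and the choice is recorded in pipeline
metadata. One structural caveat, visible at high SNR: on mirror-both trials
the MGS goal is exactly antipodal to the visual target, so visual-aligned
reconstructions carry a coherent bump at 180 degrees whose (cost-suppressed)
fidelity can fall outside a tight null's central region even though no
visual code is present; this is a property of the mirror design itself, not
of the estimator, and it vanishes at realistic noise levels.

Subject-level inference compares bootstrap and null fidelity distributions
with a two-sample Kolmogorov-Smirnov test (`subject_level_test()`); group
level uses subject means, a 1000-iteration bootstrap over subjects for the
confidence interval, and a paired one-tailed t test (`group_level_test()`;
the exact procedure string is returned with the result). The pRF-IEM
comparison (`compare_prf_iem_tuning()`) keeps voxels with pRF eccentricity
>= 5 degrees (the task's stimuli are peripheral), takes each voxel's IEM
tuning peak from its weight row, and evaluates the Fisher-Lee T-linear
circular correlation with a permutation p value — the estimator is
rotation-invariant and is computed in its O(n) closed form.
`delay_activity_summary()` contrasts the last four delay TRs against a
pretrial baseline window (default the 4.5 s before stimulus onset), split
by whether the MGS target fell in each voxel's preferred hemifield.

## Reproducibility and problem sizes

Every stochastic function takes a seed and restores the caller's RNG state;
`run_full_pipeline()` derives per-stage seeds from one global seed, writes
all tables as TSV plus a JSON record of every parameter, and reruns with an
identical configuration are byte-identical (the resume option reuses
outputs only when the stored configuration matches exactly). The validation
suite exercises: noiseless pRF recovery at 200 voxels and noisy recovery at
40 voxels (SNR 1); the IEM round trip at 40 voxels; permutation inference at
100 voxels x 160 trials with 1000 permutations; CI-coverage of the
size-eccentricity slope over 300 replicates of 500 voxels; null calibration
of the circular correlation over 100 simulations of 500 angle pairs; and a
double run of the full pipeline at 40 voxels. These sizes were chosen so
the full suite completes in minutes on a single CPU while leaving each
check statistically meaningful.

## Known limitations

- The pRF optimizer is local after the grid stage; adversarial noise can
  leave it in a local minimum (mitigated, not eliminated, by the polish
  restart and the monotone-r2 guarantee).
- The IEM reconstruction lives in the rank-3 span of the basis, so
  reconstructed profiles are sinusoids plus a constant; sharper features of
  the underlying representation are invisible by construction.
- The modified fidelity's DC sensitivity makes its absolute scale
  design-dependent; compare it only against nulls computed under the same
  design, as the pipeline does.
- Group-level inference assumes exchangeable subjects and uses a normal
  approximation through the t test; with very few subjects the KS-based
  subject-level tests are the more trustworthy output.
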