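---
title: "Models and methods behind datspectnorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind datspectnorm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific choices inside `datspectnorm`: the
image model, the two quantifiers, the calibration and normal-range
statistics, what the synthetic generator does and does not emulate, and
the places where the design was genuinely open.

## 1. The image model

A DaT-SPECT acquisition is represented by a piecewise-constant activity
map on an isotropic voxel grid: an ellipsoidal brain filled with
non-specific background concentration $B$, and four striatal ellipsoids
(caudate and putamen per side, about 5 and 6 mL each) at concentration
$B\,(1 + \mathrm{SBR}_\text{true})$. Reconstruction strategies are then
modelled *in image space* rather than through sinograms, because the
comparison of interest runs entirely through their effect on measured
SBR, which is linear in the effects below:

1. **Attenuation** — a multiplicative, depth-independent retention factor
   $a \in (0, 1]$ applied when no attenuation correction is performed.
   Because SBR is a ratio of concentrations, $a$ cancels from noiseless
   SBRs; its role is in the count statistics (see noise).
2. **Resolution** — isotropic Gaussian PSF of FWHM 10-12 mm, applied by
   DFT multiplication (DC gain 1, counts conserved).
3. **Scatter and septal penetration** — a fraction $s$ of total counts is
   redistributed over the brain mask blurred at twice the PSF; an
   additional *extra-brain* septal-penetration offset (mean 8% of $B$)
   models high-energy photons from activity outside the brain punching
   through the collimator septa. Both are absent when corrections are
   applied (ACSC).
4. **Noise** — voxelwise Poisson, drawn at the *detected* count level:
   all reconstructions of one acquisition share the same projections, so
   a corrected image whose mean is restored to the unattenuated level
   must carry the noise of the attenuated acquisition. This is
   implemented by drawing at `mean * count_scale` and rescaling, with
   `count_scale` set to the physical attenuation factor for ACSC. FBP
   additionally receives zero-mean Gaussian noise and is the only mode
   whose negative voxels are not clipped (iterative algorithms impose a
   non-negativity constraint).
5. **Post-filter** — a radial 3D Butterworth filter with gain
   $1/(1 + (f/f_c)^{2n})$, $f$ in cycles/cm, defaults $f_c = 0.55$,
   $n = 10$. The gain convention is fixed by the testable anchor
   $\mathrm{gain}(f_c) = 1/2$; the filter's own resolution, summarised by
   the Gaussian with the same half-power frequency, is about 8 mm FWHM
   and combines with the PSF in quadrature (`effective_fwhm()`).

The three named modes are: **ACSC** ($s = 0$, $a = 1$, non-negative),
**IRNC** ($s > 0$, $a < 1$, non-negative), **FBP** (as IRNC plus extra
noise and signed voxels).

### Between-subject variability of the uncorrected effects

Attenuation depends on head size, and septal penetration on extra-brain
uptake (salivary glands, distant organs), so in uncorrected
reconstructions these effects vary from subject to subject; corrections
remove both the mean effect *and* its variability. Subject renders under
IRNC/FBP therefore jitter the scatter fraction (SD 0.05), the attenuation
factor (SD 0.04) and the septal offset (SD 0.05 of $B$) per subject,
while phantom renders never do — a physical calibration phantom is the
same object in every session. This is the mechanism by which scanner
characterisation matters more for the uncorrected reconstructions, and
more for the large-VOI quantifier (whose background subtraction scales
with VOI volume) than for tight-VOI density ratios.

## 2. The two quantifiers

**Tight-VOI (BRASS-analogue).** Eroded anatomical masks over caudate and
putamen; occipital-like posterior reference (brain interior, at least
10 mm from the surface so blur spill-out does not depress the reference);
$\mathrm{SBR} = (\bar{C}_t - \bar{C}_r)/\bar{C}_r$ per side and
structure, the striatum being the caudate-putamen voxel union. Tight
VOIs make this estimator strongly resolution-dependent: on noiseless
phantoms its SBR decreases strictly with PSF FWHM (a property test).

**Large-VOI (Southampton-analogue).** Per side, the striatal ellipsoids
dilated by a margin of twice the *effective* FWHM, clipped to the
mid-sagittal plane and to the brain interior; reference = remaining
interior brain. Specific counts = total counts in the VOI minus
reference concentration x VOI volume, normalised by the counts a nominal
striatal volume (the geometry's analytic caudate+putamen volume, ~11 mL)
would hold at reference concentration. Computation runs on the axial
slab spanning the VOI (identical to full 3D). Because the VOI captures
essentially all blurred striatal counts, the estimate is
resolution-robust (variation below 5% across 6-12 mm FWHM, below 1% under
margin growth on unfiltered noiseless phantoms — property tests). Two
numerical subtleties both matter and are tested: VOI and reference must
stay inside the uniform-background interior (a VOI voxel in the
spill-out shell subtracts background it does not contain), and the
sharp Butterworth's ringing tails perturb the estimate at the few-percent
level, which is why the margin is defined against the effective rather
than the PSF-only resolution.

## 3. Calibration

Per (scanner, reconstruction, quantifier, structure), ordinary least
squares of *measured on true* phantom SBR; phantom truth is noise-free by
construction, making measured the natural response. Application inverts
the line: $\mathrm{SBR}_\text{true} = (m - b)/a$; a fitted slope
$\le 0$ is a hard error (unusable characterisation). Separate lines per
structure are the default; a shared-line mode exists
(`share_structures`), since the source material does not state the
granularity. Non-calibrated analyses copy the raw measured values
unchanged. A property test checks harmonisation: for three scanners with
distinct linear characteristics and a shared noise-free cohort, the
between-scanner variance of calibrated SBR is under 10% of that of
measured SBR.

## 4. Age-dependent normal ranges

Healthy striatal SBR is regressed on age (OLS); the normal range is
$\hat{y}(x) \pm k \cdot \mathrm{SE}(x)$ with $k = 2$ by default and

$$\mathrm{SE}(x) = s\sqrt{\delta + \tfrac{1}{n} + \tfrac{(x - \bar{x})^2}{S_{xx}}},$$

$\delta = 0$ giving the confidence band of the mean and $\delta = 1$ the
prediction band for a single observation. Both forms are first-class
(`prediction_interval`), because the source material is ambiguous: its
figure captions describe confidence bands of the mean, but with a
database of n = 123 that band misclassifies nearly half of healthy
individuals (the coverage property test reports both tails), which no
clinically used normal range does and which the published operating
points (specificities around 80-90%) rule out. The *module* default
follows the captions ($\delta = 0$); the *study driver* default uses
$\delta = 1$, the only choice that places synthetic operating points in
the published regime. Classification of an individual scan against a
normal range is inherently an individual-level statement.

A region is abnormal iff its SBR is strictly below the lower limit; a tie
classifies as normal (borderline scans deserve the benefit of the doubt).
Scan rules implement "one bad side makes the scan abnormal":
`striatum_either_side` and `putamen_either_side` for the tight-VOI
quantifier, `southampton_striatal` (per-side large-VOI striatal SBR) for
the large-VOI one. Whether the original large-VOI classification used
per-side or whole-brain values is not stated; per-side with the
either-side rule is the default here, and a bilateral variant would be a
one-line change in `rule_regions()`. Normal ranges are fitted per
(mode, quantifier, calibration, structure, side); side-pooled fitting was
considered and rejected as the default because measurement asymmetry is
informative in disease.

## 5. Evaluation

Sensitivity and specificity are percentages rounded half-away-from-zero
to one decimal (the convention of the published tables — this exact
convention is what lets the acceptance layer reproduce those tables from
the printed FP/FN counts). ROC analysis uses the Mann-Whitney AUC with
ties counting one half, on age-*un*adjusted scan scores, the scan score
being the minimum SBR over the rule's regions (the worse side drives
diagnosis; a property test confirms min-scores dominate mean-scores under
asymmetric disease). Confidence intervals and the paired AUC-difference
test use the DeLong placement-variance estimator, implemented here
directly (no external ROC dependency) and verified against exhaustive
pair counting. McNemar's test is the uncorrected
$\chi^2 = (b - c)^2/(b + c)$ with 1 df by default; the
continuity-corrected variant is switchable, since the original analysis
tool's convention is unknowable.

## 6. What the synthetic world does and does not emulate

The generator reproduces: the negative linear SBR-age relationship with
Gaussian between-subject scatter (intercept 10, slope -0.05/yr, SD 1.0 —
values in the range reported for FP-CIT normal databases); a 43/34
abnormal/normal follow-up cohort with putamen-first, asymmetric loss
(worse-side putamen factor uniform on 0.2-0.7, caudate 0.5-1.0, up to 30%
side asymmetry, resampled until the worse putamen truly lies below the
healthy age line); scanner fleets with differing resolution, scatter
burden and sensitivity; count levels around 3-5 million brain counts.

It does **not** emulate: non-ellipsoidal anatomy, ventricles (except as
an explicit cavity in one property test), spatially varying attenuation
or convergence, sinogram-level reconstruction artefacts, registration
error, or heavy-tailed biological scatter. Consequently a green
end-to-end test establishes that the *pipeline logic and the stated
mechanisms* behave as designed — not that the synthetic operating points
equal the published ones. The published AUCs (0.866-0.924) and p-values
depend on the original 77 patient scans and are deliberately not
acceptance targets; specificity in the synthetic world saturates near
100% because the healthy scatter is exactly Gaussian and the bound is a
2-SD prediction band.

## 7. Numerical and reproducibility choices

* All filtering is DFT-based with circular boundaries; activity sits far
  enough inside the grid (rendering enforces brain extent + 2 x FWHM
  within the field of view) that wrap-around is negligible, and DC-gain-1
  transfers conserve counts exactly — the basis of the count-conservation
  test.
* The generator's default geometry is a 128^3 grid at 2 mm; the study
  driver uses 64^3 at 3 mm (anatomy unchanged) so that the ~640 renders
  of the full grid run in minutes on one CPU. Tests use a still smaller
  grid where only mechanics are at stake.
* Every random draw flows from an explicit seed; renders are pure
  functions of (spec, recon, seed), cohorts of their parameter object,
  and the study driver derives per-call sub-seeds from its master seed,
  so reruns are byte-identical (tested).
* Erosion of tight VOIs is 1 voxel (6-connected); reference regions stay
  >= 10 mm inside the brain surface.
* NIfTI-1 IO is implemented in-package (float32, RAS, single file,
  optional gzip) because no NIfTI reader is available in the target R
  stack; the header layout is pinned byte-for-byte by tests.

## 8. Known limitations

Image-space reconstruction surrogates cannot express artefacts that are
intrinsically tomographic (streaks, spatially varying convergence).
The linear calibration model is exactly the model the renderer
approximates, so calibration recovery here is close to a best case.
The septal-penetration offset enters additively and uniformly; real
extra-brain penetration has structure. Specificity saturation (above)
means McNemar comparisons of specificity are uninformative in the default
synthetic study, while sensitivity comparisons are the meaningful ones.
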