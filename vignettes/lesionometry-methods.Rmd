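---
title: "Methods: tract-based WMH lesionometry from multi-shell diffusion MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tract-based WMH lesionometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the synthetic world the tests run
in, and the numerical choices that were genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The analysis in one paragraph

White matter hyperintensities (WMH) are focal lesions of presumed small
vessel disease origin. Because axons passing through a lesion degenerate
along their whole trajectory, damage is expected in a subject-specific
network of voxels far beyond the lesion itself. The pipeline (i) decomposes
a two-shell diffusion acquisition into three per-voxel tissue signal
fractions — intracellular anisotropic (ICA, axon-like), intracellular
isotropic (ICI, gray-matter-like) and extracellular isotropic (ECI, free
water) — by single-shell 3-tissue constrained spherical deconvolution
(SS3T-CSD); (ii) generates a whole-volume probabilistic tractogram on the
white-matter fiber orientation distribution (FOD), length-filtered at
2.6 mm and pruned 5:1 by SIFT-style density matching; (iii) intersects the
tractogram with the subject's binary WMH mask to build a *lesionometry
ROI*: all non-WMH voxels traversed by at least 10 distinct lesioned
streamlines, summarized by its volume, mean signal fractions and *lesion
load* (WMH volume / ROI volume); and (iv) relates these quantities to
age-adjusted epigenetic age (AgeAccelGrim, the OLS residual of GrimAge on
chronological age) by covariate-adjusted cross-sectional GLMs and
change-score longitudinal models.

## Forward model and phantom

The synthetic phantom uses a three-compartment forward model per voxel,

$$S(b, g) = f_{ICA}\, e^{-b [d_r + (d_a - d_r)(g \cdot v)^2]}
         + f_{ICI}\, e^{-b d_{GM}} + f_{ECI}\, e^{-b d_{CSF}},$$

with $S(0) = 1$, an axially symmetric "zeppelin" tensor for the axonal
compartment and monoexponential isotropic decay for the other two.
Defaults $d_{CSF} = 3.0\times10^{-3}$, $d_{GM} = 0.8\times10^{-3}$,
$d_a = 1.7\times10^{-3}$, $d_r = 0.2\times10^{-3}$ mm$^2$/s are standard
literature values; published lesionometry analyses do not commit to a
forward model, so these are a package choice. Noise is Rician (magnitude of complex
Gaussian), with SNR defined on the b = 0 signal. The default acquisition
is 10 b = 0 volumes plus 64 electrostatically spread directions at each of
b = 1500 and 3000 s/mm$^2$, on a 1.7 mm isotropic grid. The direction
layout is deterministic: a Fibonacci initialization relaxed by projective
electrostatic repulsion, with hemisphere signs chosen greedily so the set
is balanced.

The phantom is a stated world, not a dial: straight axonal bundles of pure
ICA tissue, a GM-like background of (0.1, 0.9, 0), a CSF corner block for
response estimation, and spherical WMH lesions of composition
(0.55, 0.30, 0.15) strictly interior to the bundle. A lesion may carry a
*penumbra*: bundle voxels within a rim beyond the lesion boundary shift
signal fraction from ICA to ECI, emulating Wallerian degeneration along
lesioned tracts. The penumbra is where the generator plants the
subject-specific microstructure effects, because the lesionometry ROI —
which excludes the WMH itself — is exactly this peri-lesional tract
territory.

What the phantom does **not** emulate: crossing fibers (every voxel is
single-fiber), susceptibility/motion/eddy artifacts, partial volume beyond
fraction mixing, B1 bias fields, and spatial autocorrelation of noise. A
green test therefore establishes algorithmic correctness on resolvable
single-fiber geometry, not robustness to the full messiness of in vivo
data.

## Response functions and SS3T-CSD

Responses are estimated from the data: the WM response is the per-shell
zonal spherical-harmonic (SH) expansion of single-fiber voxels after
reorienting each voxel's principal diffusion axis (log-linear tensor fit)
to +z, averaged over at most 50 voxels; GM and CSF responses are per-shell
mean signals. On the noiseless phantom the WM zonal coefficients agree
with the analytic zeppelin expansion to $10^{-3}$ (tested against a
numerical-integration oracle).

The SS3T fit uses only the b = 0 set and the outermost shell. Per voxel it
solves the joint constrained least-squares problem over
$x = (\text{FOD SH coefficients up to } l_{max} = 8,\ w_{ICI},\ w_{ECI})$
with hard constraints: FOD amplitude $\ge 0$ on 300 quasi-uniform
directions, and $w_{ICI}, w_{ECI} \ge 0$. The solver is the exact
Lawson–Hanson reduction (inequality-constrained LS → least-distance
program → NNLS), deterministic and free of iteration schedules. Weights
are kept in b0-signal units, so signal fractions are plain normalizations,
and $w_{ICA} = \text{wm}_{b0}\sqrt{4\pi}\, f_{00}$.

Two numerical issues required explicit resolution:

* **The single-shell isotropic degeneracy.** With one non-zero shell, one
  unit of GM-like signal is *exactly* mimicked by a non-negative
  combination of an isotropic FOD pedestal and CSF. Worse, under hard
  non-negativity the truncated-delta FOD prefers extra pedestal (it
  slackens the amplitude constraints and improves the anisotropic fit), so
  a naive joint fit reports zero ICI in mixed voxels. The package resolves
  this with a second stage: the fiber orientation is taken from the
  stage-1 FOD peak (dense 1000-direction grid), and the compartment
  weights are refit by exact NNLS against the *measured response kernel
  rotated to that axis* plus the two isotropic columns. The reported FOD
  is the response's own non-negative single-fiber template FOD (the
  constrained deconvolution of the kernel by itself), rotated and scaled
  so its $l = 0$ coefficient carries exactly $w_{ICA}$. On the noiseless
  fraction grid (0.1 steps) this recovers each compartment with mean
  absolute error $\le 0.05$; the cost is that genuinely multi-fiber
  voxels, which the phantom does not contain, would be summarized by their
  dominant axis in the output FOD.
* **Rician bias.** At b = 3000 the CSF compartment is at the noise floor,
  and the Rician magnitude bias masquerades as GM-like signal. The fit
  optionally (default on) applies the moment correction
  $\hat S = \sqrt{\max(S^2 - 2\hat\sigma^2, 0)}$ with $\hat\sigma$
  estimated from the spread of the b = 0 repeats — a no-op on noiseless
  data. With it, the median per-fraction error at SNR 30 over random
  compositions stays within 0.10.

## Tractography and SIFT

A first-order probabilistic sampler replaces second-order arc integration:
at each 0.65 mm step the next direction is drawn by rejection sampling
proportional to the trilinearly interpolated FOD amplitude within a 30°
cone around the incoming direction (amplitude cutoff 0.05, maximum length
250 mm). Streamlines grow bidirectionally from seeds drawn uniformly over
the in-mask voxel volume and are rejected below 2.6 mm — the published
length criterion. All randomness flows through R's RNG, so a fixed seed
reproduces a tractogram bit-for-bit.

SIFT-style pruning minimizes
$\sum_v (\mu\, TD(v) - A(v))^2$, where $TD$ is the distinct-streamline
visitation count from exact segment–voxel traversal (Amanatides–Woo, with
voxel $i$ the half-open box $[i, i+1)$) and $A$ the FOD mean ($l = 0$)
amplitude. Removal is greedy (always the streamline whose deletion most
decreases the cost) with the density-matching scale $\mu$ refit after
every removal; with per-removal refitting the cost is non-increasing
through the full 5:1 pruning, which a batched refit does not guarantee.
The default desk-scale counts (20,000 generated, 4,000 kept) preserve the
published 5:1 generation:retention ratio; the published absolute counts
(10M → 2M) are configuration, not desk scale.

## Lesionometry

The ROI is $\{v : TD_{lesioned}(v) \ge 10\} \setminus \text{WMH}$, where
"10 separate tracts" is read as 10 distinct streamlines (each counted once
per voxel, the traversal convention breaking face ties deterministically).
ROI statistics are unweighted voxel means of the three fractions
(tract-weighted means would up-weight the bundle core; the choice is
configurable in principle but unweighted is the default and the tested
path). Lesion load is WMH volume over ROI volume; an empty WMH gives 0, an
empty ROI gives a missing value and flags the subject, never a crash.

## Cohort generator and planted effects

`generate_cohort()` draws ages uniform on 58–81 y, sex with P(male) = 0.3,
GrimAge linear in age and sex with 3.5 y residual scatter (men
+4 y, so sex is strongly associated with AgeAccelGrim, as expected when
sex enters the clock), and computes AgeAccelGrim by `age_accel()`. Exactly
`round(0.418 n)` subjects are retained at follow-up — a simple random
sample, independent of every covariate, so the data are missing completely
at random by construction (98 baseline / 41 follow-up at the default n).

Planted structure, chosen once:

* baseline lesion volume $45 + 2 \cdot \text{AAG} + N(0, 8)$ mm$^3$,
  floored at 25 mm$^3$ so every lesion spans several voxels at 1.7 mm
  (a one-voxel WMH is not resolvable by tract filtering, and real WMH are
  orders of magnitude larger than a voxel);
* baseline penumbra free-water elevation
  $0.12 + 0.012 \cdot \text{AAG} + N(0, 0.02)$ signal fraction;
* follow-up adds $0.04 + 0.012 \cdot \text{AAG} + N(0, 0.012)$ — the
  longitudinal interaction — and lesions grow by $8 + N(0,3)$ mm$^3$
  with **no** AAG dependence by default (reported cohorts find lesion
  *growth* unrelated to AgeAccelGrim even where baseline volume is not;
  a nonzero slope is available via `wmh_growth_slope_aag`);
* a global free-water drift of 0.01 at follow-up, identical for all
  subjects. Because the subject-specific lesion and penumbra leak into the
  whole-mask mean, the generator *balances* each subject's follow-up
  background so the whole-mask mean ECI change equals the common drift
  exactly — this is what "no whole-brain × AgeAccelGrim interaction"
  means as a generative statement, and it makes the whole-brain
  longitudinal null testable rather than accidental.

Effect magnitudes are configurable and deliberately strong relative to
measurement noise at smoke scale; they are not calibrated to any
external cohort: published analyses report test statistics, not effect
sizes in physical units.

## Statistics

`fit_glm()` is OLS with intercept (two-sided t tests); the baseline models
are `response ~ AgeAccelGrim + age + sex + volume term(s)`, with WMH
volume added as an extra volumetric control in WMH-microstructure models.
`longitudinal_model()` realizes the within-subjects ANOVA as change-score
ANCOVA on complete pairs: $\Delta y$ on intercept + term of interest +
centred controls (sex, baseline age, a volume term); centring makes the
intercept the covariate-adjusted mean change, and the F for any term is
the square of its t with 1 numerator df — matching the printed
$F_{1, n-k}$ pattern. Whether volume at one or both timepoints should enter is a judgment
call; one (baseline) volume is the default, both are accepted via the
covariate list. `missingness_tests()` runs
pooled-variance two-sample t tests of each baseline variable by retention.
Sex is coded F = 0, M = 1; p-values are nominal (no multiplicity
correction; a note to that effect accompanies the report output), and every p is reported with its
statistic and df.

## Degenerate inputs and tie-breaks

Odd `lmax`, non-positive b-values, fraction triples off the simplex,
empty tissue masks, rank-deficient direction sets, empty seeding masks,
`keep_count` out of range, constant age, collinear designs and absent
longitudinal pairs all raise immediate, named errors. Background voxels
outside the brain mask get `NA` fractions and are excluded from
statistics. A streamline touching a voxel face belongs to the upper voxel
(half-open convention); the segment-traversal oracle in the tests samples
1000 points per segment (≥ 100× oversampling) because at exactly 100× a
corner-clipping segment can generically miss a voxel the exact traversal
correctly reports — the density makes the *oracle* exact, the comparison
is still exact equality.

## Desk-scale choices and limitations

The cohort pipeline runs each subject × timepoint on a 10³ phantom with a
restricted mask, `lmax = 4`, 800 generated → 160 kept streamlines; one
98-subject replicate takes well under a minute. These sizes are stated
once and used everywhere; tests never shrink them after the fact. Known
limitations: no crossing-fiber support in the output FODs (template-based
stage 2), no anatomically-constrained tractography, voxel-wise rather than
fixel-wise SIFT, no spatial normalization or group-overlap maps, and
GrimAge enters as a scalar — the methylation pipeline behind it is out of
scope.
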