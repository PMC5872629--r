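---
title: "Methods: GFA and tensor metrics for pre/post ROI analysis"
author: "gfadti authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GFA and tensor metrics for pre/post ROI analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfadti)
```

## The scientific problem

Diffusion MRI probes the directional mobility of water in tissue.  In
cerebral white matter, axonal membranes and myelin restrict diffusion
perpendicular to the fiber axis, so directional diffusion summaries act as
proxies for fiber density, axon diameter and myelination.  Rehabilitation
studies use this to ask whether an intervention (here, the motivating use
case is low-frequency rTMS combined with intensive occupational therapy
after stroke) changes white-matter microstructure under the motor cortices,
and whether that change tracks clinical motor recovery.

Two scalar summaries are computed voxelwise:

* **FA (fractional anisotropy)** from the eigenvalues
  $\lambda_1 \ge \lambda_2 \ge \lambda_3$ of a fitted diffusion tensor:
  $$\mathrm{FA} = \sqrt{\tfrac12}\;
    \frac{\sqrt{(\lambda_1-\lambda_2)^2 + (\lambda_2-\lambda_3)^2 +
    (\lambda_3-\lambda_1)^2}}{\sqrt{\lambda_1^2+\lambda_2^2+\lambda_3^2}}.$$
* **GFA (generalized fractional anisotropy)** directly from the
  per-direction apparent diffusion coefficients
  $\Psi(u_i) = -\ln(S_i/\bar S_0)/b_i$, $i = 1 \dots n_s$:
  $$\mathrm{GFA} = \frac{\mathrm{std}(\Psi)}{\mathrm{rms}(\Psi)}
    = \sqrt{\frac{n_s \sum_i (\Psi(u_i) - \langle\Psi\rangle)^2}
                 {(n_s - 1)\sum_i \Psi(u_i)^2}},$$
  the sample standard deviation (with the $n_s - 1$ denominator) of the ADC
  profile over its root mean square.

Both lie in $[0, 1]$ for nonnegative inputs: 0 for isotropic diffusion, 1
in the maximally anisotropic limit.  The single-tensor model underlying FA
cannot represent two fiber populations crossing in one voxel; the fitted
ellipsoid flattens and FA drops.  GFA is computed from the raw directional
ADC profile without a tensor model, which is the motivation for carrying
both metrics through the pipeline and comparing their sensitivity.

Because no patient imaging data are distributed with studies of this kind,
the package is exercised entirely on synthetic inputs with known ground
truth: multi-tensor DWI phantoms, and cohort tables whose effect sizes and
correlations are planted by construction.  Everything downstream of the
generator — metrics, smoothing, ROI reduction, statistics — is the same
code a real study would run.

## Acquisition model and phantom

The simulated acquisition mirrors a clinical 1.5 T DTI protocol: 21
diffusion-weighted axes at $b = 1000\ \mathrm{s/mm^2}$ plus one $b_0$
volume, voxels of $0.9 \times 0.9 \times 5$ mm.  The direction count is
read as 21 motion-probing-gradient axes *plus* one unweighted volume: a
$b_0$ reference is mathematically required to form any ADC, and clinical
protocols acquire at least one.  No published direction table exists for
the scanner, so directions are laid out deterministically on the upper
hemisphere by a golden-angle (Fibonacci) spiral: quasi-uniform, free of
antipodal duplicates, and reproducible without a stored table.  The design
matrix of the minimal 6-direction scheme has full rank (condition number
about 3), so the tensor fit is well posed for every allowed scheme.

Phantom voxels follow the standard multi-tensor forward model
$S = S_0 \sum_k f_k \exp(-b\, g^\top D_k g)$.  The default layout places
four disjoint rectangular blocks (stand-ins for the atlas-derived
white-matter masks under lesioned/nonlesioned BA4 and BA6 of a spatially
normalized study) in one $14 \times 14 \times 5$ grid: three single-fiber
blocks with $\lambda = (1.7, 0.2, 0.2)\times 10^{-3}\ \mathrm{mm^2/s}$ and
one 50/50 perpendicular crossing.  Noise is Rician — the magnitude of a
complex Gaussian — with $\sigma = S_0/30$ (SNR 30 on $b_0$) by default,
a typical clinical echo-planar value.  Spatial normalization itself (SPM
templates, atlas registration) is out of scope: synthetic volumes are
generated directly in a shared space, which is exactly what registration
is meant to produce.

What the phantom does **not** emulate: partial-volume gradients at block
edges, spatially varying $S_0$ or $\sigma$, eddy-current and motion
artifacts, and the geometric distortions of echo-planar imaging.  Passing
tests therefore validate the computational pipeline, not robustness to
scanner artifacts.

## Metric maps, smoothing, ROI reduction

ADC profiles use the mean of all $b_0$ volumes as $\bar S_0$.  Magnitude
noise can push $S_i$ above $\bar S_0$ and make $\Psi < 0$; by default
negative ADCs are clamped to zero (diffusivities are physical, and the
clamp keeps GFA within $[0,1]$), with `clamp = FALSE` available for
comparisons against implementations that do not clamp.  Voxels whose $b_0$
signal is nonpositive, or with nonpositive DW signals, are carried as an
explicit validity mask — never as zeros, since zero is a meaningful metric
value.  The tensor fit is ordinary log-linear least squares on the six
unique tensor elements; weighted and robust variants are deliberately out
of scope.

Smoothing follows the study protocol: a Gaussian kernel of FWHM 6 mm
applied to the metric map (not the raw DWI), with
$\sigma_\text{axis} = \mathrm{FWHM} / (2\sqrt{2\ln 2}) / \text{voxel
size}_\text{axis}$ so anisotropic voxels get anisotropic kernels in voxel
units.  Boundaries use nearest-edge replication, and invalid voxels are
handled by normalized convolution (smoothing the validity weights
alongside the data).  Both choices make a constant map an exact fixed
point, which is the natural correctness anchor for a smoother.  Whether
ROI averaging uses the smoothed or unsmoothed map is exposed as a config
toggle (`smooth_before_roi`), since protocols differ; the default follows
the study ordering (smooth first).

ROI means are arithmetic means of valid voxels per integer label; an ROI
left with no valid voxel raises an error naming the ROI rather than
reporting a silent placeholder.

## Clinical scores

The Fugl-Meyer upper-limb motor score (FMA) is an opaque 0–66 integer.
The Wolf Motor Function Test (WMFT) contributes 15 timed tasks, capped at
120 s; a task not completed is assigned the cap.  Two summaries are
implemented:

* mean performance rate: the mean of $60/t$ over the 15 tasks, with rate 0
  for tasks over 120 s or not completed.  "Within 120 seconds" is read as
  inclusive — exactly 120 s earns $60/120 = 0.5$ — consistent with the cap
  assigning 120 s as a valid maximal time;
* log performance time (lpt): $\ln(\text{mean of the 15 capped times})$,
  the EXCITE-trial convention.  The literal reading (log of mean) is the
  default; mean-of-logs is available as a variant for sensitivity
  analysis.  lpt can never exceed $\ln 120 \approx 4.787$.

## Cohort generator

The cohort module simulates the paired design directly at the summary
level: per subject, per ROI, pre-intervention FA/GFA values and change
scores, plus FMA and WMFT summaries.  Defaults are the published group
values of the 36-patient study arm the package emulates (e.g. lesioned-BA4
GFA $0.181 \pm 0.006 \to 0.186 \pm 0.005$; FMA $45.4 \pm 12.3 \to 50.9 \pm
12.0$; lpt $2.8 \pm 1.2 \to 2.4 \pm 1.3$).  Change-score SDs are not
reported in such tables; they default to the pre-intervention SD, a
conventional assumption corresponding to a within-subject correlation of
about one half.  FMA and lpt change SDs default to 6 points and 0.5
log-seconds respectively, chosen once so that the planted improvements
reach the strong significance the study reports at $n = 36$.

The planted association is the study's headline correlation: Spearman
$\rho^\ast = -0.363$ between the lesioned-BA4 GFA change and the lpt
change.  The two change scores are coupled through a Gaussian copula with
Pearson parameter $r = 2\sin(\pi\rho^\ast/6)$, the closed-form calibration
that makes the Spearman correlation of a bivariate Gaussian equal
$\rho^\ast$.  Pre-intervention lpt is drawn from a normal truncated at
$\ln 120$, so generated task times respect the cap by construction; the
post value is additionally censored at the cap.  That censoring touches a
few percent of subjects and attenuates the realized correlation slightly
(Monte-Carlo mean over 500 replicates is about $-0.354$ for a planted
$-0.363$), which is the realistic behaviour of a capped scale, not a
calibration error.  WMFT task times are back-generated by setting all 15
tasks to $\exp(\mathrm{lpt})$ — the simplest table whose transform
reproduces the drawn lpt exactly.  A consequence worth knowing: with equal
task times the mean *rate* equals $60/\exp(\mathrm{lpt})$, which is far
smaller than published mean rates (those are dominated by fast tasks via
Jensen's inequality).  Rate *changes* still anti-correlate with lpt
changes, which is what the statistics consume.

FMA values are rounded and clipped to 0–66; GFA/FA values are clipped to
$[0,1]$ (the clip never binds at the default means).  All draws are
deterministic under the spec's seed and leave the caller's RNG state
untouched.

## Statistics

Pre/post changes use the Wilcoxon signed-rank test in its classical form:
zero differences discarded (Wilcoxon's rule, as SPSS applies), midranks
for tied absolute differences, statistic $W = \min(W^+, W^-)$.  The
two-sided p-value is exact — from the full convolution-built null
distribution of $W^+$ — whenever the effective $n \le 20$ with no ties;
otherwise a normal approximation with tie correction and continuity
correction is used, matching SPSS output conventions.  Correlations use
Spearman's $\rho$ as the Pearson correlation of midranks with the
$t$-distribution p-value on $n-2$ degrees of freedom; $R^2 = \rho^2$ is
reported alongside because clinical papers print both forms.  Two-sided
p-values throughout; no multiple-testing correction by default (matching
conventional single-test reporting in this literature), with Holm
available as an option.

## Numerical choices and problem sizes

* GFA's $n-1$ in the denominator is read as $n_s - 1$ (only one count
  exists in the formula); the expression then reduces exactly to sample
  SD over RMS, as the verbal definition states.
* All-zero ADC profiles, all-zero eigenvalue triples, and voxels with no
  $b_0$ signal return flagged undefined values (`NA`), never 0.
* Eigenvalues come from `eigen(symmetric = TRUE)` and are returned in
  descending order; the fit is solved by QR with an explicit rank check.
* Tests exercise phantoms of $14 \times 14 \times 5$ voxels, cohorts of
  36 subjects with 200–500 Monte-Carlo replicates, and $10^5$ random ADC
  profiles for the GFA bound — sizes chosen so the full suite runs in well
  under a minute while keeping Monte-Carlo standard errors a few times
  smaller than the tolerances they are checked against.

## Limitations

The generator plants effects at the *summary* level; it does not simulate
per-voxel longitudinal change inside the phantom and then recover it
through the full imaging pipeline (the phantom and cohort halves are
linked by sharing the same metric code, not by a common voxel-level ground
truth).  GFA from 21 directions is a DTI-regime approximation — high
angular resolution acquisitions with hundreds of directions are the
natural habitat of the metric — and the crossing-fiber claim tested here
is the FA drop, not GFA invariance at crossings, which 21-direction ADC
profiles do not exhibit.  Registration, atlas construction and tract
rendering are out of scope by design.
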