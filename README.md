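# gfadti

Generalized fractional anisotropy (GFA) and diffusion-tensor metrics for
ROI-based pre/post neuroimaging analysis, exercised end to end on synthetic
data with known ground truth.

## What it is for

Rehabilitation imaging studies ask whether an intervention changes
white-matter microstructure under specific cortical areas, and whether that
change tracks clinical motor recovery. The quantities involved are
computed voxelwise from diffusion-weighted MRI:

* the per-direction apparent diffusion coefficient profile
  `psi_i = -ln(S_i / S0) / b_i` over the `n_s` gradient axes;
* **GFA**, the sample standard deviation of that profile over its root
  mean square,

  ```
  GFA = std(psi) / rms(psi)
      = sqrt( n_s * sum_i (psi_i - <psi>)^2 / ((n_s - 1) * sum_i psi_i^2) )
  ```

* **FA** from the eigenvalues `l1 >= l2 >= l3` of the log-linear
  least-squares diffusion tensor fit,

  ```
  FA = sqrt(1/2) * sqrt((l1-l2)^2 + (l2-l3)^2 + (l3-l1)^2) / sqrt(l1^2 + l2^2 + l3^2)
  ```

Both lie in [0, 1]; FA drops where fiber populations cross, which is the
motivation for carrying both metrics. Maps are Gaussian-smoothed (FWHM in
mm, anisotropic voxels handled), averaged over integer-labelled ROIs, and
the resulting per-subject summaries are analyzed with the classical
nonparametric toolkit: exact Wilcoxon signed-rank tests for pre/post
change and Spearman rank correlations (with `R^2 = rho^2`) between imaging
change and motor-score change (Fugl-Meyer assessment; Wolf Motor Function
Test performance rate `60/t` and log performance time `ln(mean t)`, with
the 120 s task cap and zero-rate rule).

Because patient imaging of this kind is not publicly deposited, the
package includes first-class synthetic modules: multi-tensor DWI phantoms
(21-direction, b = 1000 s/mm², single/crossing-fiber blocks, Rician noise)
and pre/post cohort tables with planted effect sizes and a
Gaussian-copula-planted Spearman correlation. See the methods vignette
(`vignettes/gfa-roi-pipeline.Rmd`) for the model, parameter defaults and
their rationale.

## Worked example

```r
library(gfadti)

# a noiseless phantom under the clinical acquisition geometry
scheme  <- make_scheme(21, 1000)
phantom <- build_phantom(c(14, 14, 5), scheme, phantom_blocks(), sigma = 0)
mask    <- truth_mask(phantom$truth)
fa  <- metric_map(phantom$dwi, "FA",  mask)
gfa <- metric_map(phantom$dwi, "GFA", mask)
roi_summary(fa, gfa, truth_roi_mask(phantom$truth), subject = "phantom")
#>   subject timepoint roi                fa   gfa n_voxels
#> 1 phantom pre       ba4_lesioned    0.870 0.557       48
#> 2 phantom pre       ba4_nonlesioned 0.870 0.558       48
#> 3 phantom pre       ba6_lesioned    0.497 0.292       48
#> 4 phantom pre       ba6_nonlesioned 0.870 0.551       48
```

The three single-fiber blocks hit the closed-form FA of the planted tensor
(`sqrt(2.25/2.97) = 0.8704` for eigenvalues `(1.7, 0.2, 0.2)e-3 mm²/s`),
and the crossing-fiber block drops to 0.497 — the fitted ellipsoid
flattens where two populations cross.

```r
report <- analyze_cohort(simulate_cohort(cohort_spec(seed = 1)))
report$motor_summary
#>    measure pre_mean pre_sd post_mean post_sd         p
#>        fma   41.861 13.150    45.389  14.472 0.0029537
#>  wmft_rate    7.639 12.748     9.815  11.188 0.0005638
#>   wmft_lpt    2.715  1.079     2.412   1.159 0.0007959
```

One simulated 36-subject cohort at the default (published) group
parameters: motor function improves (FMA up, log performance time down,
all signed-rank p < 0.01), and in the full `report$roi_table` the
lesioned-BA4 GFA increase is detected (p = 1.9e-05 in this draw) with a
negative dGFA–dlpt Spearman correlation (rho = -0.348, R² = 0.121),
reflecting the planted rho* = -0.363.

A command-line front end over the same functions is installed at
`system.file("cli", "gfadti-pipeline.R", package = "gfadti")` with
subcommands `phantom`, `maps`, `roi`, `scores`, `analyze`, `demo`.

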