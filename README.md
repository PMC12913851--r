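# chromodyn

Time-resolved quantification of DNA-damage localization and chromatin
remodeling from two-channel live-cell confocal time-lapses.

When a nucleus stained with a DNA counterstain (Hoechst 33342) is
laser-micro-irradiated inside a rectangular ROI, two things happen that this
package measures frame by frame:

* a damage marker (e.g. a PARP1-RFP chromobody) is recruited into the ROI,
  preferentially into dense, heterochromatic regions;
* the chromatin in the ROI relaxes — counterstain intensity and its spatial
  heterogeneity (coefficient of variation, CV) decay over tens of seconds.

It is aimed at microscopists and image analysts running
micro-irradiation/recruitment experiments who want these observables, and
their kinetics, computed reproducibly from multi-page TIFF stacks — or from
fully ground-truthed synthetic stacks when no data are at hand.

## What is computed

For each post-irradiation frame, within the damage-area mask
(nucleus ∩ ROI):

* **Colocalization fraction** (image cross-correlation spectroscopy). With
  masked fluctuation correlations
  `G(ξ,η) = <δa·δb>(ξ,η) / (<a>·<b>)`, the colocalized fraction of the
  damage channel is `f1 = Gcc(0) / Gac,2(0)` — the CCF zero-lag amplitude
  over the counterstain ACF amplitude extrapolated to zero lag (Gaussian
  fit excluding the shot-noise spike at r = 0). `f1` is 1 for complete
  colocalization, 0 for none, −1 for anti-correlation.
* **DNA density** at the damage foci: mean of `I/Imax`-normalized
  counterstain intensity over nucleus ∩ foci (foci = pixels ≥ 80 % of the
  damage-channel frame maximum).
* **Intensity and CV**: mean, and `CV = σ/μ`, of the background-subtracted
  counterstain in the damage area (rolling-ball radius 100 px).
* **Kinetics**: one-phase association fit of the damage trace over the
  first 60 s (`T_on`), and one-phase decay fits (`T_off`) of the damage,
  intensity and CV traces.

A synthetic time-lapse generator (`synth_nucleus()`, `synth_timelapse()`,
`synth_condition()`) emulates the full experiment — heterochromatin
texture, Poisson photon counting, the 5 × 1.3 s / 2 × 1.3 s / 50 × 3 s
acquisition schedule, biased focus placement, and programmable
recruitment/relaxation constants — so every stage is testable against
known ground truth.

## Worked example

Simulate a control-condition experiment and analyze it end to end:

```r
library(chromodyn)
demo <- run_demo(seed = 2, condition = "control")
demo
#> Synthetic demo: condition 'control', seed 2
#>        parameter true_s fitted_s rel_error
#>             t_on      6     5.73   -0.0450
#>  t_off_intensity     30    29.45   -0.0185
#>         t_off_cv     30    30.48    0.0159
#> chromodyn analysis (two-channel): 55 frames, 55 analyzed
#>   dna_mean_t_off   tau =  29.45 s  (R2 = 1.000)
#>   cv_t_off         tau =  30.48 s  (R2 = 0.990)
#>   damage_t_on      tau =   5.73 s  (R2 = 0.960)
#>   damage_t_off     tau =  54.71 s  (R2 = 0.991)
```

The table compares the generator's true time constants with the values
refitted by the pipeline: recruitment (`t_on`, seconds), counterstain
intensity decay and CV decay (`t_off`, seconds) are each recovered within
a few percent. `demo$fit$metrics` holds the per-frame table (time stamps,
`f1`, DNA density, means, CV and normalized traces);
`write_report(demo$fit, "out")` writes CSV tables, mask TIFFs, a frame
log and a JSON provenance block.

Real data enter the same way: build a `timelapse_stack()` from your
frames (or `read_stack_tiff()`), define the irradiation `roi_rect()`, and
call `chromodyn(stack, roi)`. Counterstain-only experiments (no
transfection) are supported: a stack with only a `dna` channel role skips
`f1`/DNA density and still reports intensity, CV and their `T_off`.

A thin command-line front end is included at `inst/scripts/chromodyn`
(subcommands `simulate`, `analyze`, `demo`).

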