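---
title: "Quantifying DNA-damage localization and chromatin remodeling from counterstain time-lapse imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DNA-damage localization and chromatin remodeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromodyn)
```

## The measurement problem

Laser micro-irradiation of a nucleus stained with a DNA counterstain
(Hoechst 33342) creates localized DNA damage inside a defined rectangular
region of interest (ROI) while live-cell confocal imaging runs. Two
channels are recorded in photon-counting mode: a damage marker (for
example a PARP1 chromobody fusion) and the counterstain. From such a
time-lapse the package quantifies two things:

1. **Where the damage sits relative to chromatin compaction** — the
   colocalization of the damage signal with dense (heterochromatic)
   chromatin, and the DNA density at the damage foci; and
2. **How chromatin remodels** — the decay of counterstain intensity and of
   its coefficient of variation (CV) inside the damaged region, the
   signature of chromatin relaxation, together with the recruitment
   kinetics of the damage marker.

The acquisition convention places `t = 0` at the onset of the bleach
(irradiation) exposure. The default schedule is 5 pre-bleach frames at
1.3 s, 2 bleach iterations of 1.3 s that expose but emit no frames, and
50 post-bleach frames at 3 s, so the first analyzed post-irradiation
frame falls at 2.6 s and the last at 149.6 s.

## Image products

Four products are derived per frame before any metric is computed:

* **Nucleus count masks.** The counterstain channel is thresholded with
  the iterative intermeans (isodata) algorithm, components are labelled
  (8-connected by default) and filtered by a minimum area (500 px), and
  identities are linked across frames by maximal overlap so each nucleus
  keeps one label through time.
* **Damage-area count masks.** The nucleus masks restricted to the
  irradiation ROI; this is the region of analysis for colocalization,
  intensity and CV.
* **Damage-foci binary masks.** Pixels of the damage channel at or above
  80 % of the per-frame maximum. The per-frame (rather than stack-wide)
  maximum is assumed; an all-zero frame yields an empty, flagged mask so
  the time series continues.
* **Intensity images.** The counterstain channel after 3 × 3 mean
  smoothing and rolling-ball background subtraction (radius 100 px,
  approximately the largest heterochromatin feature), clipped at zero.
  The rolling ball is applied to the counterstain channel only.

The rolling ball is implemented natively: for large radii the frame is
shrunk by block minima, a non-flat ball-cap grayscale opening runs at the
reduced radius, and the background is enlarged back by bilinear
interpolation and capped at the image — the standard large-radius
strategy for this algorithm. Tests check it against a direct flat-disc
grayscale opening on small frames.

## The colocalization estimator

For images $a$ and $b$ restricted to an analysis mask $M$, the package
computes the normalized spatial correlation

$$G(\xi,\eta) \;=\; \frac{\langle \delta a \,\delta b\rangle(\xi,\eta)}
{\langle a\rangle_M \,\langle b\rangle_M},$$

where fluctuations $\delta x = x - \langle x\rangle_M$ are zero outside
the mask and the lagged product sum at each $(\xi,\eta)$ is divided by
the number of in-mask pixel pairs at that lag, obtained from the mask's
own correlation. This fluctuation normalization is the single source of
truth for all correlation quantities in the package; it is computed by
zero-padded FFT and is identical (to $10^{-8}$) to brute-force pair
summation.

The colocalized fraction of channel 1 is

$$f_1 = \frac{G_{cc}(0)}{G_{ac,2}(0)},$$

the ratio of the cross-correlation amplitude at zero lag to the
autocorrelation amplitude of channel 2 extrapolated to zero lag, and
symmetrically for $f_2$. The two amplitudes are treated differently on
purpose:

* the **CCF central value is used as measured** (optionally averaged over
  the central 3 × 3 lags; off by default) because detector shot noise is
  uncorrelated between channels and adds no spike to the CCF;
* the **ACF amplitudes are fitted**, by radially averaging the surface
  and fitting $g(r) = g_0 e^{-r^2/w^2} + c$ with the $r = 0$ bin
  excluded, because shot noise adds an uncorrelated spike exactly at zero
  lag. Radial averaging groups lags of equal exact radius (no integer
  binning), so a noiseless Gaussian surface is recovered exactly.
  Negative amplitudes (anti-correlation) are allowed.

$f_1$ is clipped to $[-1, 1]$: 1 is complete colocalization, 0 none,
$-1$ complete anti-correlation. Masks below 100 px refuse analysis
rather than return noise; when the damage-area mask holds several
labels, the largest object is analyzed (one irradiated nucleus per ROI
by design). Frames with failed fits carry missing values, never zeros —
zero is a meaningful value of $f_1$.

## DNA density, intensity and CV

Per frame, with $I_{\max}$ the maximum of the intensity image over the
nucleus mask:

$$I_{\text{norm}}(x,y) = I(x,y) / I_{\max}, \qquad
\text{DNA density} = \langle I_{\text{norm}}\rangle_{\text{nucleus}\,\cap\,\text{foci}},$$

$$\mathrm{CV} = \sigma/\mu$$

with $\mu$, $\sigma$ the mean and population (divide-by-$n$) standard
deviation of the counterstain intensity over the damage-area mask. The
population form differs from the sample form by under 0.1 % at the
region sizes involved. Because $I_{\max}$ is taken after smoothing and
background subtraction, single hot pixels have limited leverage; an
optional high-percentile mode was considered and rejected to keep the
definition literal. DNA density is invariant to positive rescaling of
the frame, and equals the in-mask mean of $I_{\text{norm}}$ when the
foci cover the nucleus uniformly — both properties are tested.

Traces are normalized to the first post-bleach time point by default (a
peak-normalization mode exists for recruitment traces). Pre-bleach
frames are reported but the normalization reference is always
post-bleach.

## Kinetic fits

Recruitment is fitted by the one-phase association model
$y(t) = y_0 + (P - y_0)\,(1 - e^{-(t-t_1)/\tau})$ over a fixed window,
by default from the first post-bleach frame to 60 s — the short-term
accumulation phase — giving $T_{on}$. Relaxation is fitted by the
one-phase decay $y(t) = P + (y_s - P)\,e^{-(t-t_s)/\tau}$, giving
$T_{off}$; counterstain intensity and CV traces start the fit at the
first post-bleach frame, damage-marker traces at the trace maximum
(3-point moving average, so single noisy frames cannot define the
peak). Whether published decay fits start at the first post frame or at
the maximum is ambiguous for DNA metrics; first-post is the default
here and is configurable.

Fitting uses bounded Levenberg–Marquardt least squares with
$\tau \in (0.1, 1000]$ s. Start values come from trace quantiles
(baseline = first value, plateau = extremum, $\tau$ = window/5), with a
small fallback grid of $\tau$ starts because bounded LM can report a
singular gradient from an unlucky start. A $\tau$ pinned at its bounds
is reported as a failed fit, not an estimate. Exact invariances hold and
are tested: rescaling time by $c$ rescales $\tau$ by $c$; rescaling the
trace amplitude leaves $\tau$ unchanged.

## The synthetic time-lapse generator

No deposited imaging data exist for this protocol, so the package ships
a generator whose outputs carry full ground truth; every pipeline stage
is validated against it.

* **Nucleus.** An elliptical mask with relative chromatin density
  $1 + (\text{contrast}-1)\sum_k \mathcal{N}(\mathbf{x}_k, \sigma_b)$:
  Gaussian heterochromatin blobs (default $\sigma_b$ = 3–4 px,
  contrast 3) on a euchromatin base. The heterochromatin mask is the
  top quartile of in-nucleus density.
* **Counterstain channel.** Expected rate = `mean_counts` (default 50
  photons/px, a realistic photon-counting level) times the density map.
  After `t = 0`, inside ROI ∩ nucleus the mean decays multiplicatively
  with constant `t_off_intensity` toward $1 - \text{relax\_amplitude}$
  of its level, and the in-region texture is progressively blurred.
* **CV calibration.** The paper-level observable is the CV decay; no
  generative model of relaxation is prescribed, so the blur sigma for
  each frame is calibrated numerically: the predicted *measured* CV —
  including the Poisson shot-noise term, since the expected sample
  variance of counts equals the spatial variance of rates plus the mean
  rate — is matched to the target
  $\mathrm{CV}(t) = \mathrm{CV}_\infty + (\mathrm{CV}_0 -
  \mathrm{CV}_\infty)e^{-t/t_{off,cv}}$ by inverting a precomputed
  sigma-to-variance curve. Blur inside the region is renormalized to
  conserve the region mean, so the intensity trace stays exactly
  exponential. When the target falls below the shot-noise floor the
  blur clamps at its calibrated maximum.
* **Damage channel.** A uniform nucleoplasmic base (20 % of
  `mean_counts`) plus Gaussian foci placed at local density maxima
  inside the ROI; each focus is drawn from heterochromatin candidates
  with probability `damage_bias` (default 0.9). The focal amplitude
  follows $1 - e^{-t/t_{on}}$ and decays after `decay_start_s` (default
  53.6 s, the recruitment-peak time of the control condition; `Inf`
  emulates inhibitor-trapped, sustained binding). As the chromatin
  relaxes, the focal pattern spreads with the same calibrated blur,
  with its in-region mass conserved — so the region-mean trace follows
  the association model exactly while the *pattern* decouples from the
  chromatin texture, which is what drives the measured $f_1$ downward.
* **Noise.** Every pixel is an independent Poisson draw around its
  expected rate; identical seeds give bit-identical stacks, and no
  global random state leaks (`withr::with_seed`).

The default `recruit_amplitude` is 0.6 (peak focal rate = 0.6 ×
`mean_counts` over the base), chosen so that the emulated $f_1$ lies
within the reportable $[-1, 1]$ range at the trace endpoints, matching
the scale on which the real observable lives. With very bright foci the
ratio estimator legitimately exceeds 1 and clipping saturates the early
trace — visible as a plateau at 1 in the middle of control traces. This
is a known limitation of the emulation, not of the estimator.

Two condition presets bundle these choices: `control`
($T_{on}$ = 6 s, relaxation amplitude 0.3, decay from 53.6 s) and
`parp_inhibited` ($T_{on}$ = 18 s, no relaxation, sustained plateau),
mirroring untreated versus PARP-inhibitor-treated cells. The
inhibitor contrast is graded, not binary: intermediate
`relax_amplitude` values emulate intermediate doses.

### What the generator does and does not emulate

It reproduces: heterochromatin texture and its intensity statistics,
Poisson photon counting, the acquisition schedule, biased focus
placement, association/decay kinetics of all reported traces, and the
edge (18 × 4 µm) and internal (6 × 4 µm) ROI geometries at 72 nm
pixels. It does **not** model the optical PSF beyond Gaussian blobs,
nucleoli, cell motion or focus drift, counterstain photobleaching (off
by default; a bleach-fraction parameter exists for robustness tests),
or spatial variation of damage efficiency along the ROI. Passing tests
therefore demonstrate correctness of the *measurement* chain under
realistic counting statistics, not robustness to every real-microscope
artifact.

### Problem sizes

Full-protocol geometry is 512 × 512 px at 72 nm. The validation
ensembles in the test suite and acceptance script use 192 × 192 or
128 × 128 frames with the internal 6 × 4 µm ROI preset, which keeps a
whole ensemble of 55-frame stacks in the seconds-to-minutes range while
leaving hundreds of photons of dynamic range and thousands of pixels in
the analysis region; recovery accuracy at these sizes was
indistinguishable from larger frames in our checks.

## Numerical choices and degenerate inputs

* Connectivity is 8 by default (EBImage's 4-connected labelling is
  extended by a diagonal merge); minimum nucleus area 500 px.
* ROIs are 0-based, half-open, row-major; physical sizes convert with
  round-half-up at the stated pixel size.
* Correlation masks under 100 px, all-zero frames, zero in-mask means,
  empty foci ∩ nucleus intersections and non-positive normalization
  references all produce typed errors or flagged missing values, never
  silent zeros.
* The association window includes the recruitment-decay boundary when
  `decay_start_s` < 60 s; recovery ensembles that probe estimator bias
  therefore use sustained recruitment, while condition contrasts use
  the full control preset.
* All tunables live in `chromodyn_config()` and round-trip through
  YAML; reports embed the full configuration for provenance.

## Known limitations

Beyond the generator gaps above: touching nuclei are not split
(no watershed); the isodata threshold assumes a roughly bimodal
histogram; $f_1$ clipping saturates when focal contrast is extreme; and
the damage-channel $T_{off}$ fit window (peak to 149.6 s) is short
relative to slow decay constants, so that estimate carries more
variance than the counterstain fits.
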