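---
title: "Quantifying macrophage mitochondrial redox state from optical redox imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying macrophage mitochondrial redox state from optical redox imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoximg)
```

## The measurement

Optical redox imaging (ORI) records the intrinsic fluorescence of two
mitochondrial coenzyme pools in live, unstained cells: NADH (blue-excited
emission) and FAD-containing flavoproteins (Fp). Only the reduced
nicotinamide (NADH) and the oxidized flavin (FAD) forms fluoresce, so the
two intensities move in opposite directions as mitochondria shift between
reduced and oxidized states, and the dimensionless redox ratio

$$\mathrm{RR} = \frac{F_p}{\mathrm{NADH} + F_p} \in (0, 1)$$

rises as the mitochondrial matrix becomes more oxidized. Alongside the two
intrinsic channels the package handles a MitoSOX red channel (mitochondrial
superoxide) and the green/red pair of a ratiometric lipid-peroxidation
sensor. The intended application is ex vivo lung macrophages — cultured
alveolar macrophage lines and macrophages from tracheal aspirates (TA) of
ventilated preterm infants — but nothing in the quantification is specific
to that system.

## The quantification model

Each field of view (FOV) is processed independently, per channel:

1. **Background estimation.** The mean and sample SD (n−1) of a cell-free
   region define the background level and the *noise*. At least 100 pixels
   are required; a zero SD is rejected as degenerate because the SNR
   threshold below would be undefined.
2. **Background subtraction.** The background mean is subtracted everywhere
   and negative values are clipped to zero. Clipped pixels are below noise
   and can never pass the threshold, and clipping guarantees the redox
   ratio stays inside (0, 1). The operation is intentionally not
   idempotent.
3. **SNR thresholding.** A pixel is retained iff its corrected value is at
   least `snr × noise`, with `snr = 7.5` for the ORI channels and `5` for
   MitoSOX. The comparison is `>=` — a pixel exactly at the threshold is
   retained; some convention must be fixed, and this one is pinned by
   tests. No morphological cleanup is applied: the method is deliberately
   global and non-segmenting.
4. **Ratio image.** The redox ratio is computed pixel by pixel on the
   *intersection* of the NADH and Fp masks. A pixel passing only one
   channel's threshold has an unreliable denominator, so it is excluded;
   the union and Fp-only alternatives were considered and rejected.
5. **Aggregation.** Per FOV, each index reports the mean and SD over its
   retained pixels; the redox-ratio index is the **mean of pixel-wise
   ratios**, not the ratio of channel means (the latter is emitted as the
   `ratio_of_means` diagnostic only — for heterogeneous cell populations
   the two differ). Sample-level values are *unweighted* means of FOV
   means (SD across FOVs, n−1), so a sparse FOV counts as much as a dense
   one; this matches per-FOV averaging practice and is pinned by a test
   that distinguishes it from pixel-pooled means.

Indices whose mask is empty are reported as *absent*, never as zero — an
FOV of red blood cells has no ORI signal, not a zero redox ratio.

### Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `ori_snr` | 7.5 | noise SDs | retention threshold for NADH/Fp/lipid channels |
| `mitosox_snr` | 5.0 | noise SDs | MitoSOX is dimmer; a lower threshold retains stained pixels |
| background ROI | explicit | — | supplied as a rectangle or mask; automatic lowest-decile fallback warns |
| `pixel_size_um` | 0.293 | µm/px | metadata only; no quantity here depends on it |

The background ROI is supplied explicitly because delimiting "cell-free"
background is an acquisition-level decision; silent automation would hide
it. The fallback (lowest intensity decile, with a warning) keeps batch runs
usable when no ROI was recorded.

## The synthetic-scene generator

No imaging data ship with the package, so every downstream stage is
validated against scenes with known ground truth, generated by
`generate_scene()`:

- **Cells** are axis-aligned ellipses with uniform random semi-axes,
  placed uniformly inside the image minus a guaranteed cell-free border
  strip (default 32 px) that serves as the background ROI. Overlap is
  allowed; each pixel belongs to the first-placed cell. The analysis is
  global, so shape realism is secondary to having an exact mask oracle.
- **Macrophages** add `level × texture` to each of their pixels, where the
  texture is lognormal with mean 1 and configurable CV — fluorescence is
  nonnegative and right-skewed, and a multiplicative texture keeps the
  per-cell expected mean exactly at `level`.
- **RBC-type objects** add nothing above background in NADH, Fp and
  MitoSOX: red blood cells lack mitochondria. They exist to verify the
  null behaviour of thresholding.
- **Noise** is additive, Gaussian and homoscedastic, matching the
  pipeline's "noise = SD of background" definition. Poisson/photon realism
  is out of scope, as are PSF blur, bleed-through, photobleaching and
  focus drift — passing recovery tests therefore demonstrates correctness
  of the *computation*, not robustness to those optical effects.
- **Determinism.** The placement RNG is driven by `seed`, the
  texture/noise RNG by `noise_seed`; identical parameters give
  bit-identical scenes, while dose series and titration pairs reuse the
  placement with fresh noise.

Default levels (NADH 600, Fp 350, MitoSOX 300 a.u. over background
100 ± 8) put quantified FOV means inside the ranges observed for TA
macrophages (Fp a few hundred, NADH several hundred a.u.); they are
plausible, not calibrated to any real dataset.

Experiment-level generators compose scenes: `generate_dose_series()`
(linear NADH decrease and Fp increase with oxidant dose, clamped at zero),
`generate_titration_pair()` (uncoupled/oxidized vs inhibited/reduced
extremes, with the physiological ordering enforced), and
`generate_cohort()` (clinical covariates plus paired group A/B indices
with configurable covariate slopes, noise, and between-preparation
relation).

## Assay analyses

- **Dose-response** (`fit_dose_response`): OLS of replicate index means on
  dose with the two-sided slope t-test. The replicate unit (dish or FOV)
  is the caller's declaration, never inferred, because it legitimately
  differs between experiment types.
- **Titration** (`compute_titration`): dynamic ranges
  `ΔNADH = NADH(reduced) − NADH(oxidized)` and
  `ΔFp = Fp(oxidized) − Fp(reduced)`. Both are positive for the expected
  physiology; negative values are allowed but flagged as inverted, and
  swapping the extremes negates both. Percent changes against a control
  titration are `100·(treated − control)/control`.
- **Lipid peroxidation** (`lipid_peroxidation_index`): green/red ratio of
  masked channel means, using the ORI threshold; scale-invariant to a
  common gain.
- **Group comparisons** (`compare_conditions`): one-way ANOVA plus
  Dunnett many-to-one contrasts against a user-named control, with
  optional per-condition challenge contrasts by t-test.

## The statistical kernel

t-tests (classical pooled Student by default, Welch behind a flag, paired
via differences), one-way ANOVA, and simple linear regression are thin
wrappers over base R with one added contract: zero-variance inputs return
a typed *degenerate* result (statistic 0 / p 1 when means agree, p 0
otherwise) instead of propagating `NaN`.

Dunnett's adjustment is computed by seeded Monte-Carlo: the contrast
statistics are jointly multivariate-t with correlation
$\rho_{ij} = \lambda_i\lambda_j$, $\lambda_i = \sqrt{n_i/(n_i+n_0)}$, and
the adjusted p of contrast $i$ is $P(\max_j |T_j| \ge |t_i|)$, estimated
from 10⁵ draws of the max statistic (a common factor plus independent
components, scaled by a shared chi-square). Monte-Carlo was chosen over
quadrature because it is directly verifiable by family-wise-error
simulation and exactly reproducible by seed. The estimate is clamped into
the analytic envelope `[p, min(1, k·p)]`, which always contains the exact
Dunnett p — this removes MC noise at the boundaries and makes the
single-contrast case collapse exactly to the raw p. At 10⁵ draws the MC
standard error of an adjusted p is below 0.002.

All tests are two-sided; significance stars follow the usual convention
(\*, \*\*, \*\*\*, \*\*\*\* at 0.05, 0.01, 0.001, 0.0001).

## Clinical cohort stage

`load_clinical()` validates each record (GA, PMA ≥ GA, FiO₂ ∈ [21, 100] %,
MAP > 0) and recomputes the respiratory severity score
`RSS = FiO₂%/100 × MAP`. Display rounding is *half-up* on the
multiply-first expression `fio2 × map / 100`: products of printed values
such as 35 % × 17 cmH₂O must print 6.0, and IEEE `round()` half-to-even on
`0.35 × 17` yields 5.9. FiO₂ is stored in percent as recorded and converted
to a fraction only inside the score.

`correlate()` runs simple OLS of any index on any clinical covariate (or
index on index), paired by patient, for preparation group A (loose cells),
B (DTT-released), or the A/B average; patients missing a variable are
dropped with a logged count, never silently.
`compare_preparations()` gives paired t-tests per index, per-patient
percent differences `100·(B − A)/A` (direction pinned — swapping groups is
not a sign flip), and OLS of B on A. `average_preparations()` averages the
two preparations per patient, passing through and flagging singletons.
No multiple-testing correction is applied across the clinical regression
family, which mirrors exploratory practice for such panels; a
Benjamini–Hochberg column is emitted as a clearly-labelled diagnostic.

## Numerical conventions and degenerate inputs

- Sample SDs use n−1 everywhere (FOV counts per sample are small).
- Threshold comparison `>=`; boundary pixels retained.
- Negative corrected intensities clipped at 0.
- Empty masks → absent indices plus a warning; degenerate statistics are
  typed, never `NaN`.
- CSV outputs pin numerics to 6 significant digits, so identical runs are
  byte-identical, and carry a header comment with package version and
  config MD5.

## Validation problem sizes

The shipped test-suite and acceptance script validate with: per-pixel
oracle equivalence on twenty 64×64 scenes (relative tolerance 10⁻¹⁰);
recovery of generator truth on twenty 256×256 low-noise scenes (NADH/Fp
within 5 %, ratio within 0.02); six-dose series on 128×128 scenes over
twenty seeds (slope within 2 SE of truth, sign contracts on Fp and ratio);
titration recovery within 3 SE over ten seeds; type-I error of t-test,
ANOVA and regression at 10⁴ null replicates each (0.05 ± 0.01); and
Dunnett family-wise error over 2000 five-group null families (≤ 0.06).
These sizes give stable Monte-Carlo margins while keeping a full run in a
couple of minutes.

## Limitations

- The generator's idealisations (Gaussian noise, no PSF, no
  bleed-through) mean green tests certify the arithmetic and its
  contracts, not performance on difficult real backgrounds.
- The pipeline is non-segmenting by design; single-cell statistics are
  out of scope.
- MitoSOX FOVs are quantified independently of the ORI FOVs (cells detach
  during staining), so no pixel-level registration between ROS and redox
  indices is attempted.
- Printed cohort-scale findings (e.g. specific R² values between NADH and
  gestational age) depend on unreleased microscope data; the package
  reproduces the *machinery* and validates it on synthetic analogues with
  known truth.
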