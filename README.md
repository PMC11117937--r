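# redoximg

Quantification and analysis of **optical redox imaging (ORI)** — the
label-free fluorescence of intrinsic NADH and FAD-containing flavoproteins
(Fp) — in live macrophages, aimed at cultured alveolar macrophage models
and macrophages recovered from tracheal aspirates of ventilated preterm
infants.

Only NADH and FAD fluoresce (NAD⁺ and FADH₂ do not), so the two channels
move oppositely as mitochondria shift between reduced and oxidized states,
and the **redox ratio**

```
RR = Fp / (NADH + Fp)   ∈ (0, 1),  higher = more oxidized
```

is a per-pixel index of mitochondrial redox state. The package implements
the full quantification chain and the statistical analyses built on it:

- **quant** — background estimation from a cell-free ROI (noise = its SD),
  background subtraction with clipping at zero, SNR thresholding
  (7.5 × noise for ORI channels, 5 × for MitoSOX), pixel-wise redox-ratio
  images on the intersection of the NADH/Fp masks, masked per-FOV
  means/SDs, and unweighted FOV-to-sample aggregation.
- **assays** — linear dose–response fits for oxidant challenge,
  FCCP / rotenone + antimycin A redox-titration dynamic ranges
  (ΔNADH, ΔFp), the ratiometric green/red lipid-peroxidation index, and
  many-to-one condition comparisons (ANOVA + Dunnett against a control).
- **clinical** — validated clinical tables with recomputed respiratory
  severity score (RSS = FiO₂%/100 × MAP), index-vs-covariate regressions,
  paired comparison and averaging of the two cell-preparation groups
  (A = loose cells, B = DTT-released).
- **stats** — Student/Welch/paired t-tests, one-way ANOVA, simple linear
  regression, and a seeded Monte-Carlo implementation of Dunnett's
  many-to-one adjustment, all with typed degenerate results instead of
  `NaN` on zero-variance input.
- **synthetic** — a scene generator with exact ground truth (elliptical
  macrophages with lognormal texture, mitochondria-free RBC objects,
  Gaussian background, guaranteed cell-free border ROI) plus dose-series,
  titration-pair and clinical-cohort generators, so the whole pipeline is
  testable without microscope data.

## Worked example

```r
library(redoximg)

# a synthetic field of view with known truth: NADH 600, Fp 350,
# MitoSOX 300 a.u. above background 100 +/- 8
sc <- generate_scene(scene_params(seed = 42))
q  <- quantify_fov(sc$channels, background_roi(sc))
q
#> <fov_quant> fov 'scene42'
#>        index        mean           sd n_pixels
#>         nadh 600.3648230 121.97715854    10076
#>           fp 350.9138625  71.14416615    10076
#>      mitosox 300.2431519  61.29853234    10076
#>  redox_ratio   0.3713246   0.06557086    10076
```

The masked means land on the generated levels (600 / 350 / 300 a.u.), and
the redox ratio ≈ 0.37 matches Fp/(NADH+Fp) = 350/950 up to the small
Jensen effect of within-cell texture on the pixel-wise mean. `n_pixels` is
the retained (above-threshold) pixel count; an FOV with an empty mask
reports the index as *absent*, not zero.

```r
# clinical table: RSS is recomputed from FiO2 and MAP and cross-checked
tab <- load_clinical(system.file("extdata", "clinical_table.csv",
                                 package = "redoximg"))
tab[1:3, c("patient_id", "ga_weeks", "fio2_pct", "map", "rss_display")]
#>   patient_id ga_weeks fio2_pct map rss_display
#> 1        p-1     26.3       30  28         8.4
#> 2        p-2     35.0       21  10         2.1
#> 3        p-3     24.6       48  20         9.6

# synthetic cohort (truth: 40 a.u. NADH per week of gestational age)
co <- generate_cohort(seed = 7)
correlate(co$clinical, co$summaries, "ga_weeks", "nadh", group = "averaged")
#> <regression> nadh = 41.97 * ga_weeks + -693.3 (n = 17)
#>   R^2 = 0.7881, slope p = 1.982e-06 ****
```

The fitted slope (41.97 a.u./week) recovers the generator's 40 a.u./week
within sampling noise; `slope_p` is the two-sided t-test of zero slope.

A thin CLI for simulation and batch quantification lives at
`inst/scripts/redoximg.R` (`simulate` / `quantify --config cfg.yaml`);
configs are YAML/JSON validated by `validate_config()`.

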