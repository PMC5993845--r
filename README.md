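# sbrnorm

Quantification, cross-scanner harmonization and normative modeling for
dopamine-transporter ([123I]FP-CIT) SPECT of the striatum.

Nuclear-medicine centers judge a DAT scan against a normative database of
healthy controls, but the specific binding ratio (SBR) they measure depends
strongly on the scanner and reconstruction condition, and declines with age.
`sbrnorm` implements the three layers that make a multicenter reference
database usable:

1. **Southampton SBR quantification.** The oversized-VOI estimator

   SBR = (C_StrVOI − C_bg · N_StrVOI) / (C_bg · V_str),

   with the striatal volume V_str fixed to 11.2 mL, a striatal VOI large
   enough to contain all striatal counts, and the background count C_bg taken
   from a 44-mm slab centred on the striatal activity peak. The estimator is
   insensitive to VOI size and system resolution by construction. The
   interhemispheric asymmetry index is AI = |R − L| / (R + L) × 200.

2. **Striatal-phantom cross-calibration.** For each (scanner, reconstruction
   condition) a line `measured = a·true + b` is fitted over phantom fillings
   of known concentration ratio (8:1, ~6:1, 4:1, ~3:1, uniform; true SBR =
   ratio − 1), and subject SBRs are harmonized by the inverse map
   `(measured − b)/a`. Agreement across conditions is summarised by the
   absolute-agreement intraclass correlation ICC(2,1).

3. **Normative modeling.** Ordinary least squares of the average striatal
   SBR (and of the AI) on age, sex and scan start time — default
   coefficients `SBR = 10.610 − 0.063·age + 0.263·start + 0.461·[female]` —
   with exact t-based confidence and prediction intervals, decade-by-sex
   summary tables, Type III ANOVA effect tests, and z-scoring of new
   subjects against the lower 95% prediction limit.

Because the underlying clinical scans are not redistributable, the package
includes a **digital striatal phantom** (rasterized volume-matched to
11.2 mL per hemisphere) and a **synthetic cohort generator** whose records
lie on the normative planes above with configurable noise — every pipeline
stage runs end to end against known ground truth.

## Worked example

```r
library(sbrnorm)

# 1. digital phantom: nominal 8:1 / 4:1 filling over a 5 kBq/mL background
spec <- build_phantom_spec(8, 4, background_conc = 5)
vol  <- rasterize_phantom(spec, voxel_size = 2)

# 2. image it on an emulated scanner (9 mm PSF, biased condition, noise)
sc  <- scanner_model("demo", voxel_size = 2, psf_fwhm = 9,
                     condition_bias = list(ChangACSC = c(gain = 1.445, offset = 2.138)),
                     noise_scale = 5e6)
img <- apply_scanner(vol, sc, "ChangACSC", seed = 1)

# 3. Southampton quantification
quantify(img)
#> <striatal_measurement> SBR right 12.593, left 6.764, AI 60.22

# 4. calibrate with a curve fitted from the phantom series
series <- generate_phantom_series(sc, "ChangACSC", seed = 1)
curve  <- fit_calibration_from_series(series)[["demo|ChangACSC"]]
curve
#> <calibration_curve> (demo, ChangACSC): measured = 1.4772 x true + 2.1837 (r = 0.9997, n = 6)
apply_calibration(c(12.593, 6.764), curve)
#> [1] 7.05 3.10        # true values: 7 and 3

# 5. normative model on a synthetic cohort; z-score a new subject
model <- fit_normative_model(generate_cohort(5000, seed = 1), "average_sbr")
model
#> <normative_model> outcome: average_sbr  n = 5000
#>   intercept     10.4195  (t = 68.264, p < 1e-15)
#>   age           -0.0612  (t = -49.803, p < 1e-15)
#>   start_time     0.2732  (t = 7.124, p = 1.2e-12)
#>   sex_female     0.5031  (t = 13.097, p < 1e-15)
#>   residual SD 1.3524
zscore_subject(model, list(age = 64, sex = "M", scan_start_time = 3.4),
               observed = 4.5)
#> z = -2.17, below lower 95% PI: TRUE
```

The raw measurement (12.6 / 6.8) is badly inflated by the condition bias;
calibration returns it to the true scale (7.05 / 3.10), and the normative
model recovers the generating age slope (−0.0612 vs −0.063) and flags a
reduced scan against the age/sex-adjusted prediction band.

## Analysis workflow

The `analysis/` directory holds the numbered drivers that reproduce the full
study sequence on synthetic data, writing tables under `results/`:

| script | what it does |
| --- | --- |
| `01_simulate_phantoms.R` | phantom fillings imaged on each scanner x condition; NIfTI volumes + manifest |
| `02_quantify_phantoms.R` | Southampton quantification; measured-vs-true table |
| `03_fit_calibration.R`   | per-condition calibration curves (JSON) and round-trip check |
| `04_simulate_cohort.R`   | 510-record cohort, measurement bias, harmonization, ICC before/after |
| `05_normative_models.R`  | regressions, ANOVA, decade summary, prediction intervals, z-scoring |

Run them in order with `Rscript analysis/01_simulate_phantoms.R` etc.; the
whole sequence takes well under a minute.

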