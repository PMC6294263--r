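# cthazard

Cardiac hazard scoring for calcium-transient screens in human iPSC-derived
cardiomyocytes (hiPSC-CMs).

Early cardiac safety screening increasingly relies on spontaneously beating
hiPSC-CM monolayers imaged with calcium-sensitive dyes: each well of a
96-well plate yields a fluorescence time series of periodic calcium
transients whose shape and rhythm respond to cardio-active compounds.
`cthazard` is for safety pharmacologists and assay scientists who need to
turn those plates of raw traces into a defensible, concentration-dependent
hazard call per compound.

The pipeline implements four stages:

1. **Feature extraction** — beat detection and per-well medians (over a
   1-minute window) of the three beating parameters: CTD90 (transient
   duration at 90% of decay, a QT surrogate), beat rate (BR), and amplitude
   (Amp); plus beat stop (BR < 5/min at 30 min), EAD-like extra calcium
   spikes, and fibrillation-like small rapid transients.
2. **Effect normalization and QC** — per-well percent effects
   `Δ% = 100·(x₃₀ − x₀)/x₀`, plate-treatment medians, vehicle correction
   `ΔΔ% = Δ%(drug) − Δ%(vehicle)`, well exclusions (no beating,
   non-synchronous, baseline BR outside 30–90/min) and plate exclusions
   (>10% offending wells, or insensitive positive controls).
3. **Tolerance-interval cutoffs** — two-sided nonparametric (Wilks)
   tolerance intervals from sample extremes, whose coverage follows a
   Beta(n−1, 2) law; vehicle TIs define the no-effect zone, control-drug
   TIs (vehicle-offset-corrected) anchor the strong zones.
4. **Weighted scoring** — points per parameter zone and per beat-stop /
   fibrillation incidence zone, summed and mapped to labels
   **no / low / high** (green / yellow / red), with any EAD incidence
   overriding to **very high** (black).

A seeded plate simulator (logistic-upstroke / exponential-decay beat
kernels, truncated-normal baseline heterogeneity, hyperbolic
concentration-effect models, synthetic EAD / fibrillation / arrest
phenotypes) makes the whole pipeline testable without laboratory data.

## Worked example

Simulate a control-anchored plate carrying a hERG-blocker-like test
compound, then run the full pipeline with the packaged default scoring
matrix:

```r
library(cthazard)

models <- control_effect_models()                       # dofetilide, isoprenaline, ...
models$JNJX1 <- drug_effect_model(ctd90_emax = 0.8,     # strong CTD90 prolonger
                                  ctd90_ec50 = 0.01)
layout <- default_plate_layout(test_compounds = "JNJX1",
                               test_concentration_uM = 0.5)
plate <- generate_plate(layout, models, seed = 2026)
res <- run_pipeline(plate)
res$qc
#> <plate_qc_report> PASS | 1.0% wells outside BR criteria | 1 well exclusions
res$study_effects[, c("compound", "dd_ctd90", "dd_br", "dd_amp")]
#>       compound  dd_ctd90      dd_br     dd_amp
#> 1   dofetilide  30.96650 -0.5574136 -0.9686203
#> 2 isoprenaline -22.95255 65.3846154 27.3381995
#> 3   nimodipine -30.98708 25.3725088 -57.7786494
#> 4        JNJX1  38.79630 -1.9764957 -1.6328779
res$hazard
#>  compound concentration_uM total_score label color override_applied
#>     JNJX1              0.5           3  high   red            FALSE
```

The plate passes QC: one well was excluded at baseline, and all three
positive controls met their sensitivity criteria (dofetilide prolonged
CTD90 by +31 net percent, isoprenaline raised BR by +65%, nimodipine
shortened CTD90 by −31%). The test compound's +38.8% net CTD90
prolongation falls in the strong-prolongation zone of the default matrix
(beyond +30.7), earning 3 points and a **high** (red) hazard label at
0.5 µM; with no EAD incidence the very-high override does not apply.

The default matrix itself (cutoffs derived from a packaged synthetic
calibration study; weights and label ranges are package configuration):

```r
default_scoring_matrix()
#> <scoring_matrix>
#>   ctd90 no (-6.5, +6.5)  strong beyond (-20.5, +30.7)  points 1/3 (mild/strong)
#>   br    no (-8.9, +8.9)  strong beyond (-32.5, +43.9)  points 1/2 (mild/strong)
#>   amp   no (-6.6, +6.6)  strong beyond (-34.3, +20.8)  points 1/2 (mild/strong)
#>   beat stop: (0, 50%] -> 1, (50%, 100%) -> 2, 100% -> 4; fibrillation -> 4
#>   labels: 0 no | 1-2 low | >=3 high | EAD -> very_high
```

Sites with their own vehicle and control data should re-derive cutoffs with
`derive_cutoffs()` / `calibrate_scoring_matrix()` and ship the result as a
YAML config (`write_scoring_matrix()`).

## Command line

```sh
Rscript inst/cli/cthazard.R simulate --seed 1 --out plate1 --test JNJX1:0.5
Rscript inst/cli/cthazard.R score --plate plate1 --out results1
Rscript inst/cli/cthazard.R derive-cutoffs --seed 1 --out matrix.yaml
Rscript inst/cli/cthazard.R qc-report --plate plate1
```

`simulate` output is valid `score` input without manual edits; all
commands exit nonzero on error.

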