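# tracequant

Quantitative analysis of in-vivo stable-isotope tracing experiments:
**de novo lipogenesis (DNL)** from heavy-water (²H₂O) labelling of
palmitate, and **whole-body fatty-acid oxidation (FAO)** from ¹³CO₂
breath traces after an oral ¹³C-palmitate dose — plus the LC–MS
machinery around them: mass-isotopomer assembly from long-format peak
tables, natural-abundance correction by non-negative least squares,
acetone-exchange body-water calibration, calibration-curve
concentration quantitation, and the group-statistics layer (1.5×IQR
outlier flagging, Tukey HSD, pooled Student t, Benjamini–Hochberg FDR).

It is written for metabolism labs running diet-intervention mouse
studies (e.g. fructose/fiber designs with control, treated, and
delayed-treatment groups) who need the tracer arithmetic to be
reproducible, auditable and tested.

## The core calculations

For a corrected palmitate mass-isotopomer distribution with labelled
fractions ²H₁, ²H₂, ²H₃ and body-water enrichment *BW*:

```
²H enrichment  E = ²H₁ + 2·²H₂ + 3·²H₃
exchangeable H n :  ²H₂/²H₁ = ((n−1)/2) · BW/(1−BW)      (inverted per sample)
DNL fraction     = E / (BW · n) ;  DNL rate = DNL / hours since dose
```

Body water comes from inverting an OLS standard curve of ²H₁-acetone
fraction against known heavy-water dilutions. Measured MIDs are first
corrected for natural isotope abundance by solving
`min ||A·x − m||₂, x ≥ 0` where column *j* of *A* is the natural
binomial MID of the `n−j` unlabelled atoms shifted by *j*.

For FAO, each animal's ¹³CO₂/CO₂ trace is baseline-corrected against
the 1.1% natural ¹³C abundance, summarized as the OLS slope from dose
to the earliest maximum, and normalized per time point to circulating
¹³C-palmitate enrichment interpolated onto the CO₂ time grid.

## Worked example

Simulate a three-group cohort (the package's generator draws the
mixture model the estimator assumes: unlabelled old palmitate plus
binomially labelled new palmitate) and run the full pipeline:

```r
library(tracequant)
cohort <- simulate_dnl_cohort(synthetic_design(seed = 42))
write_dnl_inputs(cohort, "demo")
yaml::write_yaml(list(pipeline = "dnl",
  paths = list(peak_table = "peaks.csv", sample_meta = "sample_meta.csv",
               body_water_standards = "body_water_standards.csv"),
  output_dir = "demo/out", seed = 42), "demo/run.yaml")
res <- run_dnl_pipeline("demo/run.yaml")
head(res$results, 3)
#>   sample_id group h_enrichment body_water n_exchangeable dnl_fraction dnl_rate_per_hour
#> 1     CF_01    CF       0.2552      0.025          23.07       0.4425           0.02950
#> 2     CF_02    CF       0.2567      0.025          23.27       0.4412           0.02941
#> 3     CF_03    CF       0.2893      0.025          20.95       0.5525           0.03683
res$stats
#>   group1 group2 estimate adjusted_p
#> 1     IF     CF  -0.2418   6.77e-15
#> 2    CIF     CF  -0.1937   5.45e-13
#> 3    CIF     IF   0.0481   6.79e-03
```

Each row is one animal: its deuterium enrichment `E`, calibrated
body-water fraction, per-animal estimate of the exchangeable hydrogens
`n` (true value 22 in the simulation; scatter reflects the 5% intensity
noise), the fraction of the palmitate pool newly synthesized
(true values 0.5/0.25/0.3 for CF/IF/CIF), and the hourly rate over the
15 h dose-to-collection window. The Tukey table shows the treated
groups' lipogenesis significantly below control. `demo/out/` holds
every intermediate stage (`01_peak_records.csv` …
`08_group_stats.csv`), a plain-text summary and a run log, so every
reported number traces to a file.

The FAO side is analogous: `simulate_co2_traces()` →
`write_fao_inputs()` → `run_fao_pipeline()`, reporting per-animal
slope-to-maximum, time of maximum, and substrate-normalized oxidation
with group comparisons.

A thin CLI wraps the same functions
(`inst/cli/tracequant.R dnl|fao|simulate …`; exit codes 2 = validation
error, 3 = stage failure).

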