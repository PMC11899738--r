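# ftirlignin

Relative lignin quantification from ATR-FTIR second-derivative spectra, for
plant scientists studying how stressors (pollutants, antibiotics, metals)
alter cell-wall lignification — plus the two satellite analyses such studies
lean on: four-parameter logistic (4PL) toxicity curves and Gene Ontology
fold-enrichment arithmetic.

## What it computes

Classical lignin assays are destructive and slow. ATR-FTIR second-derivative
spectroscopy instead tracks lignin through its aromatic fingerprint bands
(e.g. the 1417/1423, 1464/1472, 1515/1521 and 1617/1623 cm⁻¹ doublets). The
pipeline is:

1. **Pretreatment** — replicate averaging, basic ATR correction (ν̃/ν̃₀
   scaling), unit vector normalization, Savitzky–Golay second derivative
   (15-point window, 2nd order, edge points invalidated), extended
   multiplicative scatter correction (EMSC: `x = a + b·ref + poly + e`,
   replaced by `ref + e/b`), windowed to ~800–1800 cm⁻¹.
2. **Calibration** — candidate peaks must appear in a pure-lignin standard,
   be absent from pure cellulose, and match a sample-side peak. Per peak, a
   standard curve (second-derivative height *h* vs lignin weight fraction
   *f*) over a binary mixture series is gated at Pearson **r ≥ 0.75,
   p < 0.05** (exact t transform, n − 2 df).
3. **Quantification** — per selected peak, the exposed-vs-control relative
   change `100·(h̄_exposed/h̄_control − 1)`, tested by a tiered scheme:
   Shapiro–Wilk + Lilliefors-corrected KS normality → Kruskal–Wallis if
   either rejects, else Levene → Student or Welch two-tailed t.
4. **Dose–response** — `y = bottom + (top − bottom)/(1 + (x/EC50)^hill)`
   by multi-start nonlinear least squares with bootstrap EC50 uncertainty;
   Fisher-exact germination summaries.
5. **Enrichment** — DEG gates (fold change > 2 / < 0.5, adjusted p < 0.05),
   hypergeometric upper-tail p, Bonferroni adjustment, and the
   enrichment ≥ 1.5 reporting gate.

A synthetic-data module generates mixture standards, plant cohorts,
dose–response tables and gene universes with known ground truth, so every
stage is testable without instrument data. See the methods vignette
(`vignettes/ftir-lignin-methods.Rmd`) for the models, the
projective-normalization algebra behind the generator defaults, and known
limitations.

## Worked example

```r
library(ftirlignin)

inst      <- instrument_model()                       # 800-1800 cm-1, 0.5 cm-1
standards <- generate_mixture_series(n_mixtures = 13, instrument = inst, seed = 1)
cohort    <- generate_cohort(cohort_spec(seed = 2), instrument = inst)
std <- run_pretreatment(standards)
sam <- run_pretreatment(cohort)

selection <- select_peaks(build_standard_curves(
  find_lignin_specific_peaks(std, sam), std))
selection
#> <selected_peak_set> 8 peaks (gate: r >= 0.75, p < 0.05)
#>  peak_center    slope pearson_r   p_value
#>         1417 0.004665    0.9935 9.602e-12
#>         ...
#>         1515 0.010389    0.9990 3.729e-16

estimate <- compare_groups(compute_peak_heights(sam, selection$peaks))
estimate
#> <lignin_change_estimate> 8 peaks, 8 significant at alpha = 0.05
#>  peak_center relative_change_percent      test_used    test_p significant
#>         1417                   21.61      student_t 8.330e-04        TRUE
#>         1423                   28.00      student_t 3.802e-05        TRUE
#>         ...
#>         1623                   28.12 kruskal_wallis 2.008e-05        TRUE
#> significant relative change range: 21.6 to 30.0 %
```

The cohort was generated with a planted +25 % lignin change (16 exposed vs
33 control plants, triplicate scans, 1 % noise); all eight planted doublet
peaks are rediscovered, pass the correlation gate, and the per-peak
estimates bracket the planted change. Dose–response and enrichment stages:

```r
d   <- generate_dose_response(dose_response_truth(noise_sd = 10), seed = 3)
fit_4pl(d$dose, d$response, n_bootstrap = 500, seed = 4)
#> <dose_response_fit> EC50 = 9.36 +/- 2.3 | hill = 1.51 | bottom = -10.5, top = 96.8 | converged

fold_enrichment_table(data.frame(term = "systemic acquired resistance",
                                 size = 67, observed = 13),
                      deg_count = 564, universe_size = 29295)
#>   observed expected_2dp fold_enrichment_2dp        raw_p passes_gate
#>         13         1.29               10.08 4.271784e-10        TRUE
```

## Command line

```sh
Rscript -e 'ftirlignin::lignin_cli()' generate --out run1 --seed 3
Rscript -e 'ftirlignin::lignin_cli()' analyze  --out run1 --seed 3
```

Subcommands: `generate`, `preprocess`, `calibrate`, `quantify`, `analyze`,
`doseresponse`, `enrich`. Options are `--key value` pairs; `--config
file.json` supplies the same keys with flags winning. Each run writes its
outputs, a `run_manifest.csv` with md5 content hashes, and `run.log`.

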