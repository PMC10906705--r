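# aerosolwatch

Quantifies airborne particle production during clinical procedures from
six-channel optical particle-counter time series, for infection-control
research comparing procedure types — the motivating case is capsule-sponge
("Cytosponge") esophageal sampling versus esophagogastroduodenoscopy (EGD).

The counter reports particle counts in six diameter channels (0.5–25 µm)
every 7 seconds at 100 L/min. Channels ≤ 5 µm are **aerosols** (airborne for
hours, inhalable), channels > 5 µm are **droplets** (settle fast,
contaminate surfaces). The package implements two complementary analyses:

* **Whole-procedure** — counts are duration-normalised to a 20-minute
  equivalent and compared as geometric-mean fold changes
  `exp(mean log a − mean log b)` under a log-normal count model, via Welch
  t-tests on log counts (arm vs arm) and paired t-tests on log differences
  (procedure vs each patient's own 5-minute pre-procedure reference
  window). A *spike* variant first subtracts a running-median background so
  slow room drift does not masquerade as procedure output.
* **Event-based** — for each annotated event (insertion, removal,
  intubation, extubation, throat spray, burp) the excess over a local
  median baseline is extracted; event types are compared against sampled
  *null-reference* windows and across arms by percentile bootstrap on the
  ratio of mean positive excess, with log-normal/normal mixture fits
  describing the signed excess distribution.

Cohort machinery (an in-package exact 2×2 test with the minimum-likelihood
two-sided rule, Welch t, burp-rate standardisation) and a fully
ground-truthed synthetic study generator round out the pipeline, so every
estimator is validated end to end without access to clinical recordings.

## Worked example

```r
library(aerosolwatch)

cfg <- synthetic_config(seed = 42)   # 37 EGD vs 18 Cytosponge, known truth
study <- generate_study(cfg)
res <- run_study(study, seed = 43, n_boot = 5000)

subset(res$comparisons, fraction == "aerosol" & (variant %in% "raw" | is.na(variant)))
```

```
                              comparison fraction variant  ratio ci_low ci_high  p_value n_a n_b       method
1                      EGD_vs_Cytosponge  aerosol     raw  1.625  1.151    2.29 7.42e-03  37  18        log_t
2                 procedure_vs_reference  aerosol     raw 17.241 12.523   23.74 8.28e-13  18  18 log_t_paired
4                      insertion_vs_null  aerosol    <NA>  1.021  0.307    2.28 9.95e-01  18  54    bootstrap
5                        removal_vs_null  aerosol    <NA> 21.545  8.425   46.86 4.00e-04  18  54    bootstrap
6                           burp_vs_null  aerosol    <NA>  2.024  0.675    4.33 1.86e-01  11  54    bootstrap
9            EGD_burp_vs_Cytosponge_burp  aerosol    <NA>  4.205  1.903   13.25 8.00e-04  22  11    bootstrap
```

Reading: in this particular simulated study EGD produced 1.63× more aerosol
per unit time than Cytosponge (95% CI 1.15–2.29, covering the generator's
true ratio of 2.16); Cytosponge removal produced 21.5× the null-reference
excess (CI 8.4–46.9, truth 14.6), while insertion was indistinguishable
from null (1.02×, truth 1). Single-study estimates scatter around the
truth exactly as the CIs say they should — the test suite verifies
calibration and recovery over hundreds of replicate studies. Fold changes,
CI bounds, p-values and group sizes are one tidy row per comparison;
`res$cohort` holds the demographics table, `res$mixture` the
excess-distribution mixture fits, and `plot_comparisons(res)` draws the
forest plot. `write_study_results(res, dir)` emits CSV/JSON. A thin
command-line wrapper lives at `inst/scripts/run_study.R` (`--simulate` to
generate a study directory, `--input` to analyse one).

Numbers above were produced by the code shown (the fixed seeds reproduce
them exactly).

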