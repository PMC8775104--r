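# megtonus

Regional tonic neuroelectric activity biomarkers from MEG current counts.

A referee-consensus source solver turns MEG recordings into large
collections of validated dipole current events (location, tangent-plane
direction, region label). `megtonus` implements the analysis chain that
turns those events into reliable, symptom-sensitive regional brain
measures:

- **Dark-count screening** — even empty-room recordings yield falsely
  validated currents ("dark counts") whose regional profile contaminates
  human recordings. A random-forest classifier per subject and region,
  trained on four local geometric features of each current
  (f1 = cos(direction, gray/white-interface normal),
  f2 = cos(radial, normal), f3 = distance to the interface,
  f4 = cortical thickness), decides inclusion/exclusion of each current
  against the same-day empty-room population. Training sets are capped at
  5000 currents per class with a 110% balance rule. The legacy
  density-level correction
  ρ<sub>corrected</sub> = ρ − corr · ρ<sub>empty</sub> is included as the
  comparison baseline.
- **Volume-normalized densities** —
  ρ = (count_region / count_total) ÷ (vol_region / vol_total), equal to 1
  everywhere under spatially uniform currents and invariant to solver
  yield and record length.
- **Normative z-score atlas** — per-region means and SDs over a normative
  cohort's baseline resting densities; individuals are standardized as
  z = (ρ − mean) / sd.
- **Test-retest reliability** — per-region Pearson correlation and mean
  signed difference between occasions (same-sitting rest vs task;
  baseline vs follow-up), with a Welch t comparison of correction methods.
- **Stepwise linear discriminant classification** — symptom
  presence/absence from the 2 × 68-style regional z-scores via Wilks'
  lambda partial-F forward selection with removal, jackknifed
  (leave-one-out) accuracies, exact binomial ("coin flip") and χ²
  p-values, signed ↑/↓ region tables, and iterative region-exclusion
  reruns for cohort separation.
- **Cortex vs adjacent white matter** — per-pair χ² of observed counts
  against volume-based expectations at p < 10⁻⁸.
- **Synthetic cohort generator** — the real datasets are access-restricted,
  so a first-class generator emulates solver output: multinomial regional
  counts with subject-stable activation, session noise, symptom-linked
  shifts, and geometrically atypical contaminant currents, on a perturbed
  ellipsoid toy brain with paired cortex/white-rim sectors.

See `vignettes/regional-tonus-methods.Rmd` for the models, parameter
defaults, and design decisions.

## Worked example

Simulate a small contaminated two-session cohort, screen it against its
empty-room recordings, and measure long-term test-retest reliability:

```r
library(megtonus)

model <- build_toy_brain(n_pairs = 4, n_subcortical = 2, subdivisions = 2)
cfg <- cohort_config(n_subjects = 6, sessions = c("baseline", "followup"),
                     conditions = c("rest", "empty"),
                     events_per_recording = 5000, dark_fraction = 0.25,
                     seed = 42)
sim <- simulate_cohort(cfg, model)
scr <- screen_cohort(sim$events, model, "rest_vs_empty",
                     training_spec(min_class_size = 60), seed = 42)
sum(scr$report$success)
#> [1] 48        # all 48 subject x region screens succeeded

rest <- scr$filtered_events[scr$filtered_events$condition == "rest", ]
density <- compute_density(count_events(rest, model$regions))
atlas <- build_atlas(density)
head(atlas, 3)
#>   region_id  mean_rho    sd_rho n degenerate
#> 1         1 0.9205294 0.2303409 6      FALSE
#> 2         2 0.7298350 0.1582703 6      FALSE
#> 3         3 0.9506215 0.4234733 6      FALSE

z <- to_zscores(density, atlas)
rel <- test_retest(z[z$session == "baseline", ],
                   z[z$session == "followup", ])
head(rel, 3)
#>   region_id n  pearson_r  mean_diff
#> 1         1 6 -0.1236975 -0.1947844
#> 2         2 6  0.4927961  0.7751673
#> 3         3 6  0.8283865  0.0997397
mean(rel$pearson_r)
#> [1] 0.56
```

`atlas` is the normative table (per-region mean and SD of ρ, here from six
subjects, so the per-region correlations are noisy); `rel` gives each
region's baseline-vs-follow-up correlation across subjects and the mean
z-score drift, the quantity used to judge whether a regional measure is
stable enough to be clinically useful. The full pipeline — including task
recordings, symptom classification, and the cortex/white-matter
differential test — runs end to end with `run_pipeline(pipeline_config(...),
outdir)` or the CLI wrapper:

```sh
Rscript inst/cli/megtonus --seed 1 --outdir run1
```

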