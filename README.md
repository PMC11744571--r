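# brainbreaks

Statistical pipeline for acute exercise-break crossover studies that measure,
before and after an intervention embedded in prolonged sitting, three levels
of the microvascular–brain–behavior chain:

- **retinal microvasculature** — central retinal arteriolar/venular
  equivalents (CRAE/CRVE) and the arteriole-to-venule ratio (AVR) from the
  six largest vessel widths, via the revised Knudtson iterative pairing
  (`k·sqrt(w1² + w2²)`, k = 0.88 arterioles / 0.95 venules);
- **cortical hemodynamics** — fNIRS preprocessing (coefficient-of-variation
  channel QC, optical density, zero-phase 0.01–0.08 Hz Butterworth,
  modified Beer–Lambert law with DPF 6, spatial-PCA denoising, nine-ROI
  averaging), canonical-HRF GLMs fitted by autoregressive iteratively
  reweighted least squares (BIC-selected AR pre-whitening + bisquare
  weights), and effective connectivity by VAR models with BIC order
  selection, pairwise-conditional Granger causality
  `GC(i→j) = ln(σ²_reduced/σ²_full)` with F-tests and FDR over the 72
  ordered ROI pairs, summarized as causal density;
- **executive function** — dual-task Stroop scoring: mean correct-trial RT,
  error rate, inverse efficiency score `IES = RT/(1 − ER)`, z-normalized
  against the pre-intervention pool.

Group inference uses ML-estimated linear mixed models
(condition × timepoint (× block) + sex + age + BMI, participant random
intercept) with estimated-marginal-means post–pre difference-in-differences
contrasts, assumption diagnostics with automatic remediation, and
covariate-adjusted linear mediation (X = ΔAVR, M = Δ task causal density,
Y = ΔRT) with 10,000-sample bias-corrected bootstrap CIs.

Individual-level data for studies of this design are typically available
only on request, so the package ships a synthetic-data module whose packaged
`paper_effects()` profile encodes the study's printed effect sizes. Every
estimator is validated by parameter recovery: inject a known effect,
run the pipeline, check the estimate comes back within Monte-Carlo
tolerance.

## Worked example

Mediation of the microvascular–behavior link through task-based causal
density, on synthetic change scores generated under the packaged profile
(paths a = 1.0, b = −0.82, c′ = −0.51, n = 71):

```r
library(brainbreaks)
profile <- paper_effects()
d <- generate_mediation_dataset(profile$mediation_paths, n = 71,
                                noise_sd = 0.1, covariates = TRUE,
                                seed = 20260919)
fit <- fit_mediation(d, covariates = TRUE, n_boot = 10000, seed = 20260919)
fit$paths
#>      path estimate     se      t        p ci_lower ci_upper
#>         a    0.979 0.0119  82.27 3.10e-68    0.955    1.006
#>         b   -0.783 0.1331  -5.89 1.52e-07   -1.083   -0.486
#>   c_prime   -0.567 0.1309  -4.33 5.19e-05   -0.860   -0.283
#>         c   -1.334 0.0158 -84.41 5.80e-69   -1.360   -1.308
#>  indirect   -0.767 0.1306  -5.87 4.32e-09   -1.054   -0.477
```

The total effect (`c = −1.334`) decomposes exactly into the direct path
(`c′`) plus the indirect path (`a·b`); the bias-corrected bootstrap CI of
the indirect effect excludes zero, i.e. the mediation is significant. The
retinal side of the same chain:

```r
compute_indices(rep(10, 6), rep(10, 6))
#> CRAE 17.48, CRVE 21.38, AVR 0.818 (standard convention: CRAE/CRVE)
```

## The analysis workflow

Numbered drivers under `analysis/` run the full synthetic study and write
tidy tables under `results/`:

| script | stage |
|---|---|
| `01_simulate_study.R` | generate the 71-subject SIT/MIC/VIC crossover |
| `02_score_behavior.R` | Stroop scoring + z-normalization |
| `03_retinal_indices.R` | Knudtson CRAE/CRVE/AVR + grader ICC |
| `04_fnirs_glm.R` | forward-modeled recordings → AR-IRLS activation + FDR |
| `05_connectivity.R` | VAR/Granger networks → causal density |
| `06_mixed_models.R` | LMMs, emmeans DiD contrasts, diagnostics |
| `07_mediation.R` | correlation screen + bootstrap mediation |

Each is a thin narrative over exported package functions, e.g.
`Rscript analysis/06_mixed_models.R` prints the contrast table with its
FDR-adjusted p-values and the assumption-diagnostic battery.

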