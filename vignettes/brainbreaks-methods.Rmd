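---
title: "Methods: models, calibration and design choices in brainbreaks"
author: "brainbreaks authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, calibration and design choices in brainbreaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`brainbreaks` implements the statistical pipeline of an acute exercise-break
crossover study in which participants complete a control (uninterrupted
sitting) condition and one or two cycling-break conditions, with
pre/post-intervention measurements at three levels: retinal microvasculature
(fundus vessel calibers), cortical hemodynamics (fNIRS activation and
effective connectivity), and executive function (a dual-task Stroop task).
Because individual-level study data of this kind are typically not publicly
deposited, the package pairs every estimator with a synthetic-data generator
that reproduces the statistical structure of the design, so the whole chain
can be validated by parameter recovery: inject a known effect, run the
pipeline, and check that the estimate comes back.

# Retinal vessel summarization

The six largest arterioles and six largest venules measured around the optic
disc are reduced to the central retinal arteriolar/venular equivalents (CRAE,
CRVE) by the revised Knudtson procedure: repeatedly sort the current widths,
combine the largest with the smallest as
$\hat w = k\sqrt{w_1^2 + w_2^2}$ (branching coefficient $k = 0.88$ for
arterioles, $0.95$ for venules), carry the median element forward unpaired on
odd counts, and stop at a single number. Six inputs always pass through a
three-element intermediate round, which is why the odd-count rule matters.

Two conventions for the arteriole-to-venule ratio circulate: the standard
CRAE/CRVE (consistent with the name and with the Knudtson source) and the
literal CRVE/CRAE occasionally seen in prose. The default is the standard
ratio; `compute_indices(..., convention = "paper_literal")` selects the
other, and every output row records which was used, so downstream tables are
auditable without guessing. Inputs with fewer than six vessels per side are
computed anyway and flagged (`quality_flag`), since real gradings
occasionally drop vessels. Grader reproducibility is quantified by the
two-way mixed-effects absolute-agreement single-measure ICC, computed from
ANOVA mean squares.

When several fundus images per eye are available the package computes
indices per image and averages them (rather than pooling vessels before
reduction); both routes are simple compositions of `compute_indices`.

# Stroop scoring and normalization

Each block contributes 36 test trials (three sequences of twelve) in a
50/25/25 congruent/incongruent/neutral mix. Scoring per
subject-condition-timepoint-block cell: mean reaction time over correct
trials only; error rate = errors/trials, with omitted responses (no keypress
within the 3000 ms window) counted as errors and contributing no RT; inverse
efficiency score IES = RT/(1 − ER). Cells with no correct trial are flagged
rather than scored.

Measures are z-normalized as $z = (x - \bar x_{\text{pool}})/s_{\text{pool}}$.
The normalization pool is all subjects' *pre-intervention* cells, per measure
and per block, applied to both timepoints. This choice (the scoring source
does not pin one down) keeps post-intervention change interpretable on a
stable baseline scale; per-condition and global pools are available.

# fNIRS preprocessing

Raw two-wavelength (760/850 nm) intensities pass through:

1. **Channel QC** — coefficient of variation per channel per wavelength;
   exclusion iff CV ≥ 15% at either wavelength (the boundary itself
   excludes).
2. **Optical density** — $OD(t) = -\log_{10}(I(t)/\bar I)$ per channel.
3. **Band-pass** — 3rd-order Butterworth, 0.01–0.08 Hz, applied
   forward–backward. Zero-phase filtering is a consequential choice: a
   causal filter would introduce frequency-dependent lags that masquerade as
   directed lead–lag structure in the Granger stage.
4. **Modified Beer–Lambert law** — $\Delta c = E^{-1}\,\Delta OD/(d\cdot DPF)$
   with differential pathlength factor 6 and inter-optode distance 3 cm.
   Extinction coefficients at 760/850 nm are shipped in
   `inst/extdata/extinction_coefficients.csv` (Gratzer/Prahl compilation,
   1/(mM·cm)) and are overridable; they are a required constant that study
   reports typically delegate to their acquisition toolbox.
5. **Spatial PCA denoising** — the leading spatial component(s) are
   regressed out of every channel to suppress global systemic physiology;
   default one component for resting segments, configurable by count or
   variance fraction ("first few" is the only guidance the field's reports
   give).
6. **ROI averaging** — unweighted mean of retained member channels per
   region. The packaged montage maps 49 channels into nine regions (medial
   frontal; left/right superior frontal, middle frontal, precentral,
   parietal). ROIs left with no retained channel are dropped with a warning
   flag.

All steps except QC and PCA are linear, so their order is immaterial;
channels are filtered before ROI averaging, and PCA acts on channel-space
hemoglobin.

# Task-evoked activation (AR-IRLS GLM)

The design convolves each block indicator with the canonical double-gamma
HRF (response gamma with shape 6, undershoot shape 16, ratio 1/6, unit peak)
plus intercept and polynomial drift (order 3). Fitting alternates:

1. AR(p) modeling of the current residuals with p chosen by BIC over
   0..41 (about four seconds of lags at 10.2 Hz), via Levinson–Durbin;
2. pre-whitening of response and design by the AR filter;
3. robust bisquare-weighted least squares (tuning constant 4.685) on the
   whitened data;

until the maximum coefficient change is below 1e-6 or 20 iterations.
Pre-whitening corrects serial correlation; the robust step down-weights
motion spikes. With all weights at 1 the estimator reduces to pre-whitened
least squares, and with white residuals it reduces to OLS — both are tested.
Group level: channel betas are averaged within ROI per subject, then
one-sample t-tests per ROI-condition cell with Benjamini–Hochberg adjustment
across cells.

# Effective connectivity (VAR / Granger causality / causal density)

ROI HbO (or HbR) series enter a VAR(p) fitted by per-equation least squares
(conditional ML under Gaussian innovations). The order minimizes the
multivariate BIC over 1..20 — about two seconds of lags at 10.2 Hz, enough
for hemodynamic delay structure while keeping parameters far below the 3060
samples of a five-minute resting segment — with all candidate orders scored
on a common sample. Stability (companion spectral radius < 1) is enforced;
Ljung–Box whiteness p-values per equation are recorded but non-fatal.

For each ordered pair (i → j), pairwise-conditional Granger causality
compares the full equation for j against the reduced regression omitting i's
lags while conditioning on all other ROIs:
$GC_{i\to j} = \ln(\hat\sigma^2_{\text{reduced}}/\hat\sigma^2_{\text{full}})$,
with the corresponding F-test for significance and Benjamini–Hochberg
adjustment across the 72 ordered pairs of nine ROIs. For a bivariate system
$y_t = 0.5\,x_{t-1} + \eta_t$ with unit innovation variances the population
value is $\ln(1.25) = 0.2231$, which the estimator approaches as the series
grows — this closed form anchors the tests.

Both a magnitude and a test are kept per edge because reported edge-level
differences in this literature are on the GC-magnitude scale (hundredths),
which is incompatible with raw F statistics; storing both reconciles the
scale with the named test. Causal density summarizes the network: the
*unweighted* density is the fraction of the 72 ordered pairs significant
after FDR at q = 0.05 (the default network summary), and the *weighted*
density (mean GC magnitude over all ordered pairs) is always emitted
alongside.

# Group inference

Every outcome is modeled as a linear mixed model, ML-estimated: fixed
effects condition × timepoint (× Stroop block for behavioral and activation
outcomes) plus sex, age and BMI; random intercept per participant;
treatment coding with control condition / pre-intervention / baseline-block
references. Under this coding the condition × timepoint interaction
coefficient of a two-condition design *is* the post–pre
difference-in-differences, which is also how the estimated-marginal-means
contrast is formed — the equivalence is tested algebraically on balanced
data. Degrees of freedom use the Satterthwaite approximation; FDR families
are the contrasts within one outcome.

Diagnostics follow the usual battery — Shapiro–Wilk on residuals,
Breusch–Pagan against fitted values, and a Durbin–Watson statistic computed
on within-subject ordered residuals with a normal approximation for its
p-value (the standard regression-based test does not apply directly to a
mixed model). On failure at α = 0.05 the outcome is refit under a
variance-stabilizing transform (log when strictly positive, else rank-based
inverse-normal); if diagnostics still fail, subject-level case-resampling
bootstrap CIs (2000 resamples by default) are reported and the remediation
path recorded.

# Mediation

The three-regression linear mediation (M ~ X + Z; Y ~ X + M + Z; Y ~ X + Z,
identical covariate set Z = sex/age/BMI) yields paths a, b, c′ and total
effect c, with indirect effect a·b. Because all three fits are OLS with the
same covariates, c = c′ + a·b holds to machine precision on any dataset —
a property used as a permanent invariant test. Inference is a
*bias-corrected* percentile bootstrap (10,000 case resamples at the subject
level, covariates resampled with their cases): the percentile cutpoints are
shifted by the median-bias correction $z_0 = \Phi^{-1}(\#\{\hat\theta^* <
\hat\theta\}/B)$. The accelerated (BCa) variant is intentionally not the
default, matching the bias-corrected wording of the procedure the package
emulates. Change scores pool the exercise conditions against control by
default; per-condition scores are a documented toggle. A partial-correlation
screen (controlling the same covariates, FDR across pairs) selects candidate
triples before fitting.

# The synthetic-data generator and its calibration

The generator is first-class, tested code. It emulates: a crossover of
n = 71 participants (the study cohort size) with covariates drawn from the
cohort's demographics (~51% female, age 20.9 ± 1.9, sex-specific BMI);
trial-level Stroop data (truncated-normal RTs in (200, 3000) ms, Bernoulli
errors, the 50/25/25 congruency mix); vessel widths rescaled so their
Knudtson reduction hits cell-level target calibers (CRAE ≈ 150 µm,
CRVE ≈ 200 µm — µm is assumed throughout, as vessel-caliber reports rarely
state units next to the coefficients); per-cell causal-density observations;
and fNIRS recordings forward-modeled from a latent stable VAR at ROI level,
HRF-convolved task responses, the same Beer–Lambert relation the inverse
uses, and cardiac/respiratory/Mayer-wave/drift/white noise in OD. Master
seeds split into per-subject streams by a counter scheme, so a subject's
data do not depend on how many subjects are generated.

**Why the behavioral calibration is non-trivial.** The packaged effect
profile states z-scale difference-in-differences for RT (−0.13), ER (−0.36)
and IES (−0.20) (moderate exercise vs control; the vigorous condition adds
−0.09/−0.17/−0.13). But IES is *computed* from RT and ER by the scoring
pipeline — it cannot be injected independently. Writing $r = \bar R\,
\sigma_{ER}/((1-p)\,\sigma_{RT})$ for the ratio of the ER and RT
contributions to the IES pool SD (delta method; $\bar R$ = mean RT, $p$ =
base error rate), the implied IES effect is
$(z_{RT} + z_{ER}\, r)/\sqrt{1+r^2}$. The calibration solves this for $r$
and then for the RT pool SD. The solution is constrained from below by the
binomial noise floor of the error rate at 36 trials per cell
($\sigma_{ER} \ge \sqrt{p(1-p)/36}$), which forces a between-subject RT SD
near 135 ms — large but within the range seen in dual-task Stroop cells.
With base error rate 0.05 and block mean RTs of 650/710/790 ms the implied
per-block IES effects average −0.200 to three decimals. The same
calibration computes the expected reciprocal correct-trial count exactly
from the binomial law, so trial-averaging noise is part of the pool SD and
the z-scale recovery is unbiased rather than attenuated.

Covariate *generating* effects on behavioral and retinal outcomes default to
zero so this analytic calibration stays exact; covariates are still drawn
and included as model regressors (their mediation-stage effects are nonzero
when enabled). Condition effects are applied only at post-intervention — in
a crossover, conditions are indistinguishable before the intervention — and
a small practice effect (−5 ms) on the time main effect adds realism without
touching the DiD estimand.

**What the generator does not emulate.** Real fNIRS motion artifacts beyond
heavy-tailed noise; optode-scalp coupling drift; menstrual-phase, nutrition
or fitness covariates; RT/ER dependence within trial (speed–accuracy
coupling is between-cell only); learning curves beyond the single practice
term. Passing recovery tests therefore demonstrates estimator correctness
under the stated statistical structure, not robustness to every artifact of
real recordings.

# Validation experiment sizes

The recovery experiments run at the study's n = 71 with fixed seed sets:
20 seeds for mediation (10,000 bootstrap resamples each), retinal and
causal-density recovery, and 60 seeds for the behavioral contrasts. Sixty
was chosen a priori from a power calculation: the z-ER contrast has a
per-seed Monte-Carlo SD near 0.13 (dominated by the irreducible binomial
trial noise at 36 trials/cell), so a 20-seed mean has SE ≈ 0.03 — the same
size as the acceptance band — while 60 seeds bring the SE to ≈ 0.017.
Calibration checks (null-network FDR control, bootstrap CI coverage, type-I
error) run at reduced series lengths and bootstrap counts chosen so the
whole suite completes in a few minutes; the properties they verify are
size-invariant. The retinal targets (±0.3 µm on 4.46/6.34 µm at cell
residual SD 3 µm, 20 seeds) retain a Monte-Carlo SE of ≈ 0.16 µm, so
occasional misses at the band edge are expected behavior of the experiment,
not estimator bias — the 200-seed mean of the raw generator DiD is unbiased.

# Known limitations

- Granger causality is fitted on band-passed, PCA-cleaned series; heavy
  filtering can distort lag structure, which is why the GC oracle tests run
  on unfiltered simulated series and the zero-phase filter is mandatory in
  the pipeline.
- The AR-IRLS sandwich uses the robust-fit covariance on whitened data;
  it does not propagate AR-order selection uncertainty.
- The Durbin–Watson p-value is a large-sample normal approximation.
- The bias-corrected bootstrap can under-cover slightly for very small
  indirect effects at n ≈ 71; the coverage test budgets 3 Monte-Carlo SEs
  plus a 3-point tolerance around the nominal level.
- Multi-df interactions in three-condition designs do not reduce to a single
  coefficient; the recovery experiments therefore use two-condition reduced
  designs where the treatment-coded interaction is the estimand, and report
  the three-condition case through emmeans contrasts instead.
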