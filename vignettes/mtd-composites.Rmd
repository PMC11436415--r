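---
title: "Remote cognitive composites and imaging-biomarker associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Remote cognitive composites and imaging-biomarker associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtdrive)
```

## The measurement model

Mayo Test Drive (MTD) is a remote, self-administered cognitive screening
battery with two subtests, and this package implements its derived
variables and composites exactly as they are defined operationally.

**Stricker Learning Span (SLS).** A computer-adaptive word-list learning
test: five learning trials, each followed by four-choice recognition of
every presented word, and a delay trial presenting all unique words seen
on any learning trial. Trial 1 presents 8 words; subsequent spans adapt
to performance within 2–23 words. Derived scores:

* *Trials 1–5 Total* — words correctly recognized over the learning trials;
* *Delay* — words correct on the delay trial;
* *Sum of Trials* = Trials 1–5 Total + Delay (primary outcome);
* *Maximum Learning Span* — the largest span reached on trials 1–5.

**Symbols Test.** 48 symbol-matching items (four sequential 12-item
trials). *SYM* is the mean response time in seconds over correct items
only — undefined (missing, never zero) when no item is correct. Because
accuracy is strongly ceiling-skewed (most takers score 48/48), accuracy
enters through a step-function weight `w(n_correct)`:

| correct | < 35 | 35–41 | 42 | 43 | 44 | 45 | 46 | 47–48 |
|---------|------|-------|----|----|------|-----|------|-------|
| weight  | 1    | 2     | 3  | 4  | 4.25 | 4.5 | 4.75 | 5     |

and the accuracy-weighted speed score is

$$\mathrm{SYMaw} = \max(0,\; 10 - \mathrm{SYM}) \times w(n_\text{correct}),$$

floored at 0 for SYM of 10 s or more. The 10-second anchor reflects that
essentially all takers average under 10 s per correct item.

**Composites.**

* *MTD-SBCr* (raw) = SLS Sum of Trials + SYMaw. Being a raw score, it is
  interpretable without a study-specific reference sample.
* *MTD-SBCz* (z) averages reference-standardized z-scores of SLS Maximum
  Learning Span, SLS Trials 1–5 Total, SLS Delay and SYM (SYM
  sign-flipped so higher is better), and the average is then itself
  re-standardized against the reference subgroup. The reference subgroup
  is the cognitively unimpaired (CU) participants, so MTD-SBCz has mean
  0 and SD 1 among CU by construction — the convention also used for the
  in-person Mayo-PACC and global-cognition composites.

All z-scoring uses the reference-subgroup mean and *sample* SD (n − 1),
and composites are missing whenever any constituent is missing
(complete-case per variable).

## Biomarker preparation

* PET SUVRs (amyloid meta-ROI, tau meta-ROI, tau entorhinal-ROI) are
  natural-log transformed, then z-scored against the reference subgroup
  (`ln_z()`). The order is fixed: log first, then z.
* Hippocampal volume is residualized on intracranial volume with
  sex-specific least-squares lines fit on the *reference subgroup only*
  and applied to everyone of that sex; residuals are z-scored. No log
  step is applied to the residuals — they are signed, so a log transform
  is undefined; we resolve that ambiguity by standardizing the raw
  residuals. Fitting the normative line on the reference subgroup avoids
  contaminating the slope with atrophy-driven variance.
* WMH volume is expressed as percent of ICV (×100), log transformed to
  correct right skew, then z-scored. The ×100 constant cancels in the
  z-score, so downstream estimates are unaffected by that choice.

## The statistical battery

`fit_adjusted_association()` is the primary model: OLS of the z-scored
outcome on the z-scored predictor plus age, sex and education, both
variables standardized against the reference subgroup before fitting so
estimates are comparable across outcome–biomarker pairs. The CI uses
the t distribution on the residual degrees of freedom; complete cases
per model.

`hedges_g()` / `hedges_g_from_summary()` implement the bias-corrected
standardized mean difference

$$g = J\,\frac{m_2 - m_1}{s_p},\qquad
  J = 1 - \frac{3}{4\,\mathrm{df} - 1},\qquad
  \mathrm{df} = n_1 + n_2 - 2,$$

with pooled SD $s_p$ and the normal-approximation interval
$g \pm 1.96\sqrt{(n_1+n_2)/(n_1 n_2) + g^2/(2\,\mathrm{df})}$. This
exact combination of correction factor and CI reproduces the published
effect-size column of the validation cohort from its printed group
summaries (`mcsa_group_summaries`); the raw-data and summary paths are
the same code and agree to machine precision. Published CI bounds for
four in-person measures (Mayo-PACC, Global-z, Trail Making Test B,
Digit Symbol) do not reproduce from the printed SDs because their
missingness concentrates in the impaired subgroup and the published
group n-split is not disclosed; the package documents rather than hides
this.

Spearman's rho is the Pearson correlation of average (mid) ranks with a
t-approximation p-value — the conventional tie handling of large
statistical systems. Group comparisons use the pooled-variance Student
t-test by default (Welch behind `var_equal = FALSE`), Pearson
chi-square without continuity correction, and Fisher's exact two-sided
test (sum of hypergeometric probabilities not exceeding the observed
table's). p-values are reported raw; no multiplicity adjustment is
applied anywhere.

## The synthetic cohort generator

Participant-level data for the validation cohort are not distributable,
so `generate_cohort()` produces cohorts with the same statistical
skeleton, letting every stage of the pipeline be exercised end to end.

```{r cohort}
cfg <- cohort_config(n = 684, seed = 1)
cohort <- generate_cohort(cfg)
scored <- score_cohort(cohort)
round(colMeans(scored[scored$diagnosis == "CU",
                      c("sls_sum_of_trials", "sym", "symaw", "mtd_sbcr")],
               na.rm = TRUE), 3)
```

**What it emulates.** A 94/5/1 CU/MCI/dementia case mix; per-diagnosis
age (CU 69.9 ± 11.1; impaired centered so the combined MCI/dementia
group means 77.8), education and sex distributions; correlated latent
memory and speed abilities (correlation 0.4, both declining with age at
−0.3 and −0.25 SD per decade) that drive item-level test behavior; and
imaging biomarkers whose per-diagnosis natural-scale means/SDs match the
validation cohort's characteristics table by log-normal moment
inversion.

**Adaptation rule.** The real test's exact span-update schedule is
published elsewhere; we use the simplest rule consistent with its
stated envelope (starts at 8, reaches 2–23 by trial five, and can stay,
rise or fall): +4 after a perfect trial, +1 at ≥ 75% correct, 0 above
50%, −2 otherwise, clamped to [2, 23]. A perfect performer's spans are
8, 12, 16, 20, 23. The rule lives in one function so alternatives are
pluggable. Recognition is four-choice, so per-item accuracy is floored
at 0.25 (forced guessing); item difficulty rises mildly with serial
position (0.03 logits per position). Word lists are nested, so the
delay trial presents `max(trial_spans)` unique words.

**Calibration.** The free constants (item difficulty offset −2.65,
latent-ability SDs and per-diagnosis shifts, response-time location
1.095/slope 0.312/dispersion 0.35 on the log scale, accuracy baseline
3.7 logits) were set once, by simulation at n = 20000, to reproduce the
validation cohort's CU means and SDs: SLS Sum of Trials 75.8 (17.2),
SYM 3.34 s (1.07), SYMaw 31.8 (6.1), and the impaired-group decrements.
Tests check the CU calibration at n = 10000 against the published
means (Sum of Trials within ±1.0, SYM within ±0.15 s, amyloid SUVR
within ±0.05) and the 94% CU fraction within ±0.02.

**Biomarker–cognition coupling.** Coupling biomarkers to the *latent*
abilities would attenuate the standardized adjusted association by the
scored test's measurement error, which is not known in closed form. The
generator instead couples each biomarker's standardized log-scale (or
residual-scale, for HV) variation to the covariate-residualized,
CU-standardized *realized* MTD-SBCr, with the loading chosen so the
covariate-adjusted standardized coefficient equals the configured
target (defaults −0.15 to −0.24, and +0.24 for HV) in expectation —
exactly, not attenuated. With a mixed case mix the per-diagnosis
biomarker location shifts add further association on top of the
configured within-cohort effect, just as diagnosis mix does in real
data; parameter-recovery tests therefore run on CU-only cohorts, where
the configured coefficient is the estimand. At n = 2000 the estimator
is unbiased to below 0.002 with near-nominal CI coverage, and the
type-I error of the adjusted model at a null effect is within
Monte-Carlo noise of 0.05.

**What it does not emulate.** Real item content and practice effects,
device and testing-environment variability, informative missingness
(generated sessions are complete), non-normal ability distributions,
and longitudinal change. Passing tests therefore demonstrate the
correctness of scoring, transformation and estimation machinery — not
that the generator is a substitute for the real cohort's data quirks.

## Numerical choices and degenerate inputs

* Sample SD (n − 1) everywhere; a zero-variance or n < 2 reference is a
  hard error naming the variable.
* Zero correct Symbols items give missing SYM/SYMaw with a warning.
* Non-positive values reaching a log transform become per-record
  missing with a warning; `wmh >= icv` likewise.
* Fewer than 3 reference records in a sex stratum aborts the ICV
  adjustment.
* `fit_adjusted_association()` requires ≥ 10 complete cases and a
  non-constant predictor, and errors on rank-deficient designs.
* Constant vectors give missing Spearman rho with a warning; |rho| = 1
  yields p = 0 (the t statistic diverges).

## Problem sizes used by the test suite

Structural and calibration checks use single cohorts of n = 2000 and
n = 10000; the composite-agreement check (rank correlation of MTD-SBCr
and MTD-SBCz above 0.9; about 0.99 observed) uses n = 5000; CI coverage
of a configured −0.20 effect uses 100 replicates at n = 2000; type-I
error uses 1000 replicates at n = 500. These sizes give Monte-Carlo
error comfortably inside the asserted tolerances while keeping a full
run of the suite around twenty seconds.

## Known limitations

The generator's adaptation rule is an emulation, not the proprietary
schedule, so absolute span trajectories should not be compared to real
sessions item by item. The accuracy-weight table, composite definitions
and effect-size conventions are faithful to the published scoring
rules; where a published quantity could not be reproduced from the
published summaries (the z-composite's own effect size, and the CI
bounds of four in-person measures with group-skewed missingness) the
discrepancy is documented in the test suite rather than absorbed.
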