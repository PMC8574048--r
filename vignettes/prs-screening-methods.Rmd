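---
title: "Methods: polygenic risk scores in FIT-based colorectal screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic risk scores in FIT-based colorectal screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prscreen)
```

## The problem

Fecal immunochemical test (FIT)-based colorectal cancer screening refers
FIT-positive participants (≥ 20 µg Hb/g feces) to colonoscopy, where
findings are graded along the adenoma–carcinoma sequence. `prscreen`
evaluates whether a germline polygenic risk score (PRS) built from a panel
of independent GWAS variants discriminates along that pathway and whether
it adds anything as a population pre-screen or as a second test after a
positive FIT. The ordered outcome has seven levels: population controls,
screening controls (normal colonoscopy), low-, intermediate- and high-risk
lesions (LRL/IRL/HRL), screen-detected CRC, and clinically diagnosed CRC.
The primary case/control contrast inside the screening programme takes
IRL + HRL + screen-detected CRC as cases and screening controls + LRL as
controls; a high-risk sensitivity contrast moves IRL to the controls.

## Scores, QC and adjustment

Each variant contributes its effect-allele dosage `d` in [0, 2] (hard calls
or imputed dosages). The unweighted PRS is the plain risk-allele count
`sum_j d_ij`; the weighted score multiplies by published per-allele
log-odds. The unweighted count is the primary analysis score — published
weights estimated partly on overlapping discovery samples would leak
information — so the weighted score mainly drives the simulator's liability
(see below), which usefully keeps the two scores distinguishable in tests.

QC follows standard genotype-panel practice, with defaults HWE p < 1e−4
(1-df chi-square on hard calls, rounded ties-to-even), observed MAF < 0.001,
variant missingness > 5%, imputation info R² < 0.3, sample missingness
> 1%. Two deliberately exposed switches cover genuinely ambiguous
conventions: `qc_variants(hwe_samples=)` restricts the HWE test to a subset
(e.g. controls only), and `compute_scores(use_hard_calls=)` scores rounded
calls instead of dosages. Missing dosages are mean-imputed as `2 * p_j`
(the score-file convention): every sample stays scorable, the expectation
is unbiased, and the imputation count is reported per sample.
Strand-ambiguous (A/T, C/G) variants are kept with a warning and the
panel's stated orientation is trusted — frequency-based flipping is easy to
get wrong and the panel is the authority here.

Ancestry principal components come from a singular value decomposition of
the genotype matrix with each column centered and scaled by
`sqrt(2 p (1-p))`; zero-variance variants are dropped, missing entries are
set to the column mean, and component signs follow a deterministic
largest-loading-positive rule so runs are reproducible. Ancestry labels use
nearest centroids against a labelled reference — a deterministic, testable
surrogate for visual cluster inspection; the shipped reference is synthetic
(three well-separated clusters) and exists for testing, not inference about
real populations. Ties break by label order and are flagged.

The adjusted PRS is the residual of
`prs ~ sex + age + PC1..PC5 + array + family_history` **plus the grand
mean**, keeping group summaries on the interpretable allele-count scale
(e.g. means near 130 for a 133-variant panel) rather than centered at zero.
Unknown family history stays as its own factor level; single-level factors
are dropped with a warning rather than failing the fit.

One behaviour worth knowing: when the PCs are estimated on the analysis
sample itself, the leading components absorb a small share of the
case-control contrast, shrinking the adjusted-score gap by roughly 0.1
allele in calibrated simulations. This is inherent to within-sample PC
adjustment, not a defect of the implementation; the package's acceptance
checks show the cross-validated AUC still lands in the expected interval.

## Evaluation machinery

*Trend.* The Mann-Kendall test uses `S = sum_{i<j} sign(x_j - x_i)`, the
tie-corrected variance, and a continuity-corrected normal approximation,
two-sided. It is implemented here directly (no trend-test package is a
dependency) and is checked against the Kendall-correlation formulation in
`stats::cor.test`.

*Discrimination.* AUC is the Mann-Whitney concordance (ties one half), with
DeLong variance for intervals and paired comparisons, delegated to
**pROC** — the field-standard implementation — behind the package's own
interfaces; tests verify equality with brute-force all-pairs counting.
Cross-validated AUC uses stratified folds (cases and controls split
separately, so no fold can lose a class), a logistic model on the training
split, and one ROC on the pooled out-of-fold predictions: pooling is more
stable than averaging five fold-AUCs at cohort sizes near 1,600. The CV
model uses the score alone by default; covariates can be added as extra
predictor columns. Degenerate DeLong comparisons (identical placements,
e.g. a score versus its monotone transform) return p = 1 by convention.

*Predictive values.* Test-positive means `score >= threshold`; PPV/NPV get
Wilson score intervals (well-behaved at the small, extreme counts typical
of FIT-negative strata). The population curve reweights the FIT-stratum
curves as `w_pos * value_pos + w_neg * value_neg` with weights 0.06/0.94 —
the FIT-positive/-negative composition of a screening round — undoing the
design's oversampling of FIT-positives; a count-reweighting estimator is
available behind a flag. Percentile anchors (p10–p90) are computed on the
combined analysis stratum, since neither the case nor the control
distribution has a privileged claim to define them.

*Risk stratification.* Decile cut points come from the control
distribution; bins are left-closed/right-open with the top bin closed, so a
score exactly on a cut goes up — a fixed, documented tie rule. Odds ratios
against decile 1 come from unconditional logistic regression with Wald
intervals; an empty case-decile is flagged and reported missing rather than
extrapolated.

## What the generator emulates

`sim_config()` defaults define one fixed study condition, not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| `m_variants` | 133 | panel size |
| `raf_range` | [0.1, 0.9] | risk-allele frequencies, uniform |
| `weight_range` | [0.05, 0.2] | per-allele log-odds magnitudes |
| `target_auc` | 0.56 | screening-subset AUC the calibration aims at |
| `liability_noise_sd` | 1 | non-genetic liability SD |
| `category_prevalences` | (0.200, 0.521, 0.143, 0.085, 0.029, 0.003, 0.019) | population mix of the 7 groups |
| `fit_positive_prob` | (—, 0.035, 0.06, 0.15, 0.30, 0.985, —) | FIT sensitivity by group |
| `fitneg_retention` | 0.0207 | FIT-negatives sampled into colonoscopy |
| `n_population` | 24,000 | simulated screening round |

Genotypes are independent `Binomial(2, p)` draws (HWE by construction), so
the PRS has mean `2 Σ p_j` and variance `Σ 2 p_j (1-p_j)`; with 133
frequencies uniform on [0.1, 0.9] the implied SD is ≈ 7.2 risk alleles.
Liability is the centered weighted score plus `N(0, 1)` noise; the seven
categories are cut at the liability ranks matching the prevalences, so
counts are exact and severity is monotone in expected score. FIT positivity
is category-conditional Bernoulli (the ≥ 20 µg Hb/g dichotomy is all the
analysis uses; no continuous hemoglobin model). The screening sample keeps
all FIT-positives and ~2% of FIT-negatives, yielding ≈ 1,600 colonoscopy
participants, ≈ 77% FIT-positive, ≈ 640 cases / 960 controls, and stratum
weights ≈ 0.065/0.935 — the two-phase design the weighting machinery is
meant to undo. The FIT sensitivities and prevalences were chosen once so
that the FIT-positive colonoscopy mix (≈ 36/17/25/17/6% across
control/LRL/IRL/HRL/CRC) and the ~6% population positivity are jointly
realistic; CRC sensitivity 0.985 makes FIT-negative cancers the rare events
they are in practice.

Calibration inverts the binormal identity `AUC = Φ(Δ / (σ√2))` in closed
form: the expected case-control PRS gap is a ratio of truncated-normal
slice means weighted by the sampled category mix, linear in the covariance
between the unweighted and weighted scores, so the required effect scale
has an explicit solution (an unattainable target raises an error rather
than saturating silently). Covariates are drawn independent of genotype by
default; `batch_effect` injects a dosage artifact on one array to exercise
the adjustment, spread across variants and clipped to [0, 2] (clipping
makes the realized offset slightly smaller than nominal, which the tests
account for).

**What passing tests do not show:** the generator has no linkage
disequilibrium, no population structure unless constructed, no
genotype-covariate confounding by default, normal-ish score distributions
by design, and exactly exchangeable samples. Results on real cohorts — with
related samples, batch-frequency interactions, informative missingness or
miscalibrated published weights — can be worse in ways these simulations
cannot reveal.

## Numerical conventions and degenerate inputs

- Monomorphic sites fit HWE trivially (p = 1); an all-missing variant fails
  on missingness alone rather than producing NaN statistics.
- Hard calls round ties-to-even (base `round`), stated rather than assumed.
- Zero pooled variance in the t test: p = 1 for equal means, p = 0 flagged
  `degenerate` otherwise; Bonferroni caps at 1.
- All-tied Mann-Kendall input: S = 0, p = 1.
- `S == 0` takes z = 0 (no continuity correction at the null point).
- Empty test-positive or test-negative sets report missing PPV/NPV instead
  of 0/0.
- Quasi-separation in per-variant logistics (|beta| > 10 or SE > 10, or a
  non-converged IRLS) is flagged per variant, not fatal.
- Every stochastic routine takes an explicit integer seed; fold assignments
  are hashed into the result and the pipeline manifest, so a rerun with the
  same config is bit-identical.

## Problem sizes

The test suite exercises moment checks at 20,000–50,000 samples, DeLong
null calibration at 2,000 replicates, per-variant type-I error at 10,000
null variants, decile-OR reproduction at 200 study-scale replicates, and
full-pipeline AUC reproduction over 20 seeds at the ~1,600-participant
screening scale — sizes chosen so each property is measured well inside its
Monte-Carlo tolerance while the whole suite stays comfortably runnable on a
laptop.

## Known limitations

Chromosome X is treated as diploid for everyone (no sex-specific dosage
rule); kinship and sex-concordance checks are out of scope (they need raw
intensity data); the ancestry reference is synthetic; the PCA is a joint
decomposition of the analysis sample rather than projection onto external
reference axes; and the count-reweighting predictive-value estimator
deliberately omits interval estimates, since the weighted average is the
primary estimator.
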