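---
title: "KS*: combining the Kaiser score with breast vascular assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{KS*: combining the Kaiser score with breast vascular assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ksvasc)
```

## The diagnostic problem

The Kaiser score (KS) is an evidence-based clinical decision rule for breast
MRI: a flowchart over five lesion features — root sign (spiculations),
delayed-phase enhancement kinetics (persistent / plateau / washout), margin
(circumscribed or not), internal enhancement pattern (homogeneous or not) and
ipsilateral edema — that maps every lesion to an ordinal score from 1 to 11,
higher meaning more probably malignant. KS scores translate to BI-RADS
categories as 1–4 → BI-RADS 2/3, 5–7 → BI-RADS 4, 8–11 → BI-RADS 5, with
"score > 4" the usual biopsy threshold.

KS evaluates the lesion itself and carries no information about the blood
supply of the surrounding breast, although malignancy is strongly associated
with two angiogenesis signs visible on the same examination:

* **increased ipsilateral breast vascularity** — at least two more
  *qualifying* vessels (length ≥ 3 cm **and** diameter ≥ 2 mm, both
  inclusive) in the lesion-bearing breast than in the contralateral breast,
  counted on maximum-intensity projections;
* the **adjacent vessel sign (AVS)** — a vessel entering the lesion or
  touching its edge on subtraction images.

The composite score implemented here, **KS\***, raises KS by 3 when a lesion
scoring at most 7 shows *both* signs simultaneously:

$$
KS^{*} \;=\;
\begin{cases}
KS + 3 & \text{if } KS \le 7 \text{ and vascularity} \uparrow \text{ and AVS}^{+}\\
KS & \text{otherwise.}
\end{cases}
$$

Lesions scoring 8–11 already map to BI-RADS 5, so adding points there could
not change management; the rule therefore leaves them untouched, and
$KS^{*} \le 7 + 3 = 10 \le 11$ without clipping. A lesion with exactly one
positive sign is unchanged — the rule requires the conjunction. Note the rule
is deliberately *non-monotone across the eligibility boundary*: a
double-positive lesion scoring 7 becomes 10 while one scoring 8 stays at 8.
It never lowers a score or a BI-RADS band.

## The decision tree as configuration

The package treats the flowchart as data: a `score_tree` is a list of path
records over the five features (with wildcards) plus a leaf score, validated
for *totality* (every one of the 48 feature combinations reaches a leaf),
*determinism* (no combination reaches two different scores) and range
(leaves in 1..11). Two trees ship with the package:

* `ks_tree_t1()` — the fully specified reference tree that all unit tests
  bind to; total, deterministic, all eleven scores reachable.
* `ks_tree_kaiser_synthetic()` — a **synthetic reconstruction** of the
  published Kaiser flowchart. The original flowchart is not redistributed
  here; this tree is constrained only to reproduce four published worked
  examples (irregular margin + persistent enhancement → 3; irregular margin
  + plateau → 5; root sign without edema → 7; persistent non-mass
  enhancement → 6). It is the pipeline default, but a transcription of the
  published flowchart should replace it for any clinical use.

Margins arrive in several vocabularies; `"irregular"` and `"spiculated"`
both normalize to `not_circumscribed` (the root sign is a separate feature).
Lesion type (mass / non-mass) is carried on each record for subgrouping but
does not enter the scoring rules, which are identical for both types.

## The synthetic cohort generator

No patient-level data are distributed with the study this package evaluates,
so every downstream stage is driven by a seeded generator
(`generate_cohort()`) whose defaults (`default_cohort_spec()`) emulate the
published cohort structure:

* 223 lesions, mass with probability 164/223; malignant with probability
  85/164 (mass) or 19/59 (non-mass) — 104/223 malignant overall;
* per-class joint distribution of the two vascular signs parameterized by
  the triple (P(vascularity), P(AVS), P(both)): malignant
  (72/104, 86/104, 64/104), benign (28/119, 28/119, 16/119). Each triple is
  checked against the Fréchet bounds
  $\max(0, p_v + p_a - 1) \le p_{both} \le \min(p_v, p_a)$;
* per-class Kaiser-score distributions. The study published no score
  histogram, only the operating point of "score > 4" (sensitivity 0.942,
  specificity 0.588) and the AUCs (0.858 for KS, 0.877 for KS\*). The two
  11-category pmfs in the defaults were therefore obtained by constrained
  optimisation: block sums fixed so the operating point holds exactly in
  population, remaining mass smoothed and tuned so the population AUC of KS
  is 0.858 and — after applying the KS\* upgrade with the class-specific
  double-positive rates above — the population AUC of KS\* is 0.877. They
  are a committed calibration, *not* the study's observed histograms;
* contralateral qualifying-vessel counts over 0–4 vessels with pmf
  (0.30, 0.35, 0.20, 0.10, 0.05) — a realistic MIP count range; ipsilateral
  counts are materialized consistently with the drawn vascularity flag
  (difference ≥ 2 when positive, ≤ 1 when negative, with a small Poisson
  excess, mean 0.7, beyond the minimum);
* a simulated second reading that contradicts each assessment independently:
  flip probability 0.018 for AVS (chosen so the inter-reader kappa
  concentrates near the published 0.964 at AVS prevalence ≈ 114/223), 0.05
  for vascularity (kappa ≈ 0.90) and 0.05 per Kaiser feature (unanchored; a
  realistic disagreement rate).

One root seed drives everything; replicate $k$ of a simulation study uses
`base_seed + k` (`replicate_study()`).

### Conditional independence and its limits

By default the drawn score and the vascular-sign pair are independent *given
the truth class*. The only published coupling evidence (18 upgraded lesions,
14 malignant) is too thin to identify a dependence structure, but under
conditional independence the defaults upgrade more lesions (about 28 per 223
— roughly 15 malignant and 13 benign) than the 18 observed, and the KS\*
specificity at "score > 4" dips below the published 58.8% (about 53%); the
published count suggests positive coupling between a high score and vascular
involvement within the malignant class. The direction of every comparative
result (AUC(KS\*) > AUC(KS); upgraded lesions enriched for malignancy) is
preserved. A single `coupling` parameter (a Gaussian-copula correlation
between the latent severity driving the score and the one driving the sign
pair) is available for sensitivity analyses; conjunction probabilities per
lesion-type subgroup were not published, so the pooled per-class joints are
reused in both subgroups.

What passing tests on these cohorts shows is that the *machinery* —
scoring, adjustment, metrics, ROC/AUC, DeLong, kappa — is correct and that
the generator reproduces its configured structure. It does not validate the
clinical performance of KS\* on real patients, and features of real data
(reader-specific biases, lesion-size effects, correlated features within a
patient) are deliberately not modelled.

## Evaluation statistics

* **2×2 metrics** (`confusion_metrics()`) keep exact fractions
  (numerator/denominator) next to a one-decimal percent display;
  `round_percent()` rounds *half up* on the exact rational in integer
  arithmetic, matching the display convention of the published tables. A
  zero-denominator metric is undefined (`NA`), never 0.
* **ROC/AUC**: operating points use "positive iff score > c" with malignant
  positive; the AUC (`auc_mann_whitney()`) is the Mann–Whitney statistic
  with midrank tie handling (ψ = ½ on ties), which the 11-level ordinal
  score makes essential, and equals the trapezoidal area under the
  operating points (asserted to 1e-12 in the tests).
* **DeLong**: structural components give the AUC variance
  ($S_{10}/m + S_{01}/n$) and, for two scores on the same lesions, the
  covariance and the paired z-test (`delong_paired_test()`). A zero-variance
  comparison of identical AUCs returns z = 0, p = 1; with unequal AUCs it is
  an error. The single-AUC 95% CI is the normal interval on the DeLong SE,
  truncated to [0, 1]; the CI construction used by the original analysis
  software is unknown, so those printed interval digits are not reproduced.
* **Cohen's kappa** (`cohen_kappa()`) uses the large-sample SE of the point
  estimate (Fleiss–Cohen–Everitt), not the null SE, and the reader-study
  bands: < 0.4 bad, 0.4–0.7 good, > 0.7 excellent. Two constant, identical
  raters get κ = 1. Only categorical (here binary) assessments are banded;
  no weighted kappa is provided.
* **Chi-square** (`chi2_2x2()`) is the uncorrected Pearson statistic by
  default — the published subgroup p-value of 0.036 for the AVS-specificity
  comparison (65/79 vs 26/40) is reproduced by the uncorrected statistic
  (χ² ≈ 4.41) and not by the Yates-corrected one; a flag enables the
  correction. A zero row or column marginal leaves the test undefined.
* No multiplicity adjustment is applied anywhere (two-sided p < 0.05
  throughout), mirroring standard practice for this study design.

## Pipeline and determinism

`run_pipeline()` reads a cohort CSV (schema documented in
`?read_cohort_csv`) or simulates one, scores it, and emits a report bundle:
inter-reader kappas, per-subgroup (all / mass / non-mass) metrics for each
sign and their conjunction with exact fractions, chi-square subgroup
comparisons, AUC ± CI for KS and KS\* with the paired DeLong test, the
operating point of "score > cutoff" for both scores, and an audit of
upgraded lesions (cross-tabulated by truth and lesion type, plus those whose
upgrade crossed the cutoff). Identical configuration and seed produce
byte-identical serialized bundles; every percentage in a bundle equals
`round_percent()` of its own fraction. A subgroup with fewer than two
lesions in either class is skipped from the AUC table with a warning, never
silently imputed. A thin command-line front end
(`inst/cli/ksvasc.R`: `simulate`, `score`, `evaluate`, `report`,
`replicate`) wraps these functions for shell use.

## Numerical choices and problem sizes

Test and demonstration problem sizes were chosen to make Monte-Carlo noise
negligible relative to the tolerances asserted: parameter recovery uses one
cohort of n = 10,000 (binomial SE ≤ 0.007 for every rate checked at ±0.02),
direction-of-effect uses 200 replicates of the study-sized n = 223 (SE of
the mean AUC difference ≈ 0.001), the bootstrap check of the DeLong variance
uses 2,000 stratified resamples at n = 200, and the permutation check of the
paired test uses 5,000 pairing permutations. The whole suite runs in well
under a minute.

## Known limitations

* The shipped "canonical" tree is a caption-constrained reconstruction, not
  the published flowchart (see above).
* Conditional independence inflates the upgrade count relative to the
  published 18/223 and slightly lowers the population KS\* specificity at
  the biopsy threshold; comparative directions are unaffected.
* Kappa is two-category only; the 11-point score's reliability is not
  banded.
* Vessel measurements enter as numbers (mm); there is no image processing,
  and no re-derivation of the Kaiser tree from training data.
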