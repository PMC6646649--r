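---
title: "Methods: sequential CAD reader-study analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequential CAD reader-study analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cadreader)
```

## The study design being analysed

`cadreader` analyses sequential-design multi-reader multi-case (MRMC)
studies of AI-based computer-aided detection (AI-CAD) in screening
mammography. Each of $R$ radiologists reads each of $C$ cases twice: first
unaided (the *pre* phase), then again with the CAD's marks and their 0–100
suspicion scores visible (the *post* phase), with the option to add or drop
recalls. The case set is enriched: a known set of biopsy-proven cancers
(typically retrospectively visible "missed" cancers from prior mammograms)
plus confirmed-normal exams. Ground truth per cancer case — laterality,
quadrant, and pixel boxes around the lesion drawn by validating
radiologists — travels with the case table.

Three tables fully describe a study, and `study_matrix()` validates them
jointly: a case roster, a complete $R \times C \times 2$ cube of binary
recall decisions with claimed locations, and the CAD marks. Every
downstream statistic is a pure function of this container, so a written
study reloads to identical results.

## Per-reader detection metrics

**Cancer detection rate (CDR).** Here CDR is the fraction of the enriched
set's cancer cases a reader correctly recalls — a per-case sensitivity, not
the per-thousand screening rate the same acronym means in clinical audit. A
recall only counts as a true positive when the claimed laterality *and*
quadrant match the truth; a recall pointing at the wrong place is scored as
a false-negative recall. This localization-aware rule is the study's
scoring rule and the default everywhere; every function that uses it takes
`localization = FALSE` for the location-agnostic variant, because summary
counts of "recalled cases" in conversion tables may reasonably be read
either way.

**False-positive recalls.** Over the normal cases we count recalls per
phase, conversions (`fp_increase`, recalled only after CAD review) and
reversals (`fp_reduction`, dropped after CAD review). The accounting
identity $fp_{post} = fp_{pre} + \text{increase} - \text{reduction}$ is
asserted on every computation.

**Conversion-and-ignore accounting.** Cancer cases are split by leading
lesion class — `calc` when the leading component is microcalcifications,
`mass` otherwise (mixed types follow their leading component, which is a
validating-radiologist judgment carried as data: the first token of
`lesion_components`). For each reader and class we count unaided recalls,
flagged misses the reader converted, and flagged misses the reader ignored.
"Flagged" requires a mark that geometrically overlaps a truth box on the
same view with strictly positive intersection area; edge-touching boxes do
not overlap. A box is `(x, y, w, h)` in 0-based pixels, x rightward, y
downward.

All internal arithmetic is unrounded. Display values go through one
routine, `display_pct()`/`round_half_away()`, which rounds half away from
zero — the convention that reproduces published summary percentages such as
139/317 → 44% and 90/139 → 65%. (One published per-reader relative change
prints as 62% where the unrounded value is 61.9%; the package reports the
unrounded value and lets display rounding produce the printed figure.)

## Pooled readers-as-a-group ROC

A single reader gives a binary score, so no individual ROC exists. The
group, however, yields an ordinal score per case: the **aggregate score**,
the sum of the $R$ binary recalls, an integer in $[0, R]$. By default the
raw case-level recalls are summed (the aggregate score is described as a
sum of recall decisions); `localization = TRUE` sums localization-aware
true positives instead.

`roc_from_scores()` sweeps a recall threshold from a sentinel above the
maximum score (the $(0,0)$ corner) down to the minimum (the $(1,1)$
corner), calling a case positive when its score is $\ge t$, and integrates
by the trapezoidal rule. Ties produce diagonal chords; a constant score
yields the chance diagonal with AUC 0.5. Two properties are enforced by
randomized tests: the trapezoidal AUC equals the tie-corrected Mann–Whitney
statistic
$\big(\#\text{concordant} + \tfrac12\#\text{tied}\big)/(n_+ n_-)$ on every
input, and the curve is invariant under strictly increasing score
transforms.

The CAD's stand-alone curve uses the per-case maximum mark score (0 for an
unmarked case) as the ordinal score.

**The theoretical reader.** A counterfactual in which no flag is ever
ignored: post-phase recall becomes the unaided recall OR "the case carries
at least one mark", for cancers and normals alike, and a recall is never
removed. Converted recalls point at the truth location when a truth-hitting
mark exists, otherwise at the highest-scoring mark's breast with an
uncommitted central quadrant. Per reader, the theoretical operating point
dominates the unaided one in both TPR and FPR by construction (a tested
invariant). Note one deliberate subtlety: the *pooled* ROC of theoretical
readers can be worse than the unaided pooled ROC, because all readers agree
on every flagged case, so aggregate scores saturate at $R$ for flagged
normals and cancers alike and the ordinal gradation collapses. The
theoretical construct is an operating-point statement, not a pooled-AUC
statement, and the report exposes both so the degeneracy is visible.

## Resampling inference

`bootstrap_auc_change()` assesses the percentage change
$100\,(\mathrm{AUC}_{post} - \mathrm{AUC}_{pre})/\mathrm{AUC}_{pre}$ of the
pooled AUC on two independent axes:

* **case axis** — resample the $C$ cases with replacement, keeping every
  reader; captures variation in case difficulty;
* **reader axis** — resample the $R$ readers with replacement; a reader
  drawn twice contributes their recall row twice to the aggregate sums, so
  scores stay in $[0, R]$; captures variation in reader skill.

Each replicate rebuilds both phases' aggregate scores and AUCs. The
replicate distribution is summarized by $\mu$, $\sigma$, the
normal-approximation interval $[\mu - z\sigma, \mu + z\sigma]$ with
$z = 2.58$ at the default two-sided 99% level (the conventional two-decimal
value, kept exactly rather than 2.5758), and a percentile interval
alongside. Case-axis replicates that contain a single truth class — or a
degenerate zero baseline AUC — are redrawn, not skipped, and the redraw
count is reported; at 90 cancers / 32 normals the event is vanishingly
rare, but it matters for tiny studies and for the exhaustive-enumeration
test oracle, which conditions on the same event. The generator is seeded
explicitly, records its seed in the result, and restores the caller's RNG
state; identical seeds give bit-identical results.

Density-stratified per-reader CDR deltas feed a two-sided one-sample
Student's $t$ test of zero mean, $t = \bar d / (s_d/\sqrt{n})$ on $n-1$
degrees of freedom, with the tail probability evaluated through the
regularized incomplete beta function underlying the $t$ distribution
(`stats::pt`). Zero-variance samples return $p \in \{0, 1\}$ with a
warning instead of an error, since tiny strata can be constant.

## Cohort ledger

The subject-group ladder of a retrospective prior-mammogram study is
reproduced by `build_ledger()`: biopsied patients split by outcome (cancer
/ benign / both, with the both-count subtracted once in the total
identity), cancer patients with **prior** exams — strictly more than 270
days (nine months) before biopsy; a 270-day gap is not a prior —
retrospective-finding vs de novo patients, and the actionable /
non-actionable / excluded split of the retrospective group. Actionability
is a validating-radiologist label carried as input data, never inferred.
Partition identities are asserted on every run. The **Earliest Actionable**
exam per patient is the oldest actionable prior; date ties break
lexicographically on `exam_id` with a warning. Lead time is reported *to
biopsy* in years of 365.25 days, and labelled as such, because the
alternative anchor (the diagnosis-time mammogram) is not part of the
schema.

## The synthetic-data generator

`simulate_study()` exists so that every stage of the pipeline is testable
without clinical data. Its defaults encode the study conditions the
pipeline was built around: 90 cancers and 32 normals, 7 readers, breast
density mix 4/43/37/6, the bundled lesion-combination mix (17
calcification-led, 73 mass-led; laid out exactly when the case count
matches the mix total, sampled by weight otherwise), and a CAD with 98%
case-level sensitivity on the cancers.

The decision model, per reader $r$ and case:

* unaided recall is Bernoulli in the reader's sensitivity (cancers) or
  false-positive probability (normals); the claimed location is correct
  with probability `localization_accuracy` (default 1);
* after CAD review, an unaided recall on an unmarked case reverses with
  probability $\rho_r$; an unaided miss converts with probability $c_r$
  when a truth-hitting mark exists, else with probability $f_r$ when any
  false mark exists, else stays a miss.

Default reader parameters are calibrated to the published per-reader
marginal tables: sensitivities 0.42–0.71, false-positive probabilities
4/32–9/32, and $c_r$, $f_r$, $\rho_r$ fitted by inverting the expected
conversion, false-increase and reversal counts (`calibrate_compliance()`
solves the monotone expectation by bisection). Mark scores are truncated
normals clipped to $[0, 100]$ (mean 80, sd 12 for truth-hitting marks;
mean 55, sd 15 for false marks — chosen to straddle published example
scores of 75–98 for true findings), and false-mark counts are Poisson (0.3
per cancer, 0.7 per normal — a realistic sub-one-mark-per-case rate for a
modern AI-CAD at high specificity). These shapes are modelling choices, and
all of them are configuration, never hard-coded. False marks are placed on
the breast contralateral to the truth, which guarantees they never overlap
a truth box without a rejection loop. Three RNG streams (cases, marks,
readers) are sub-seeded from the master seed, so changing reader parameters
never perturbs the sampled cases or marks.

**What the generator does and does not emulate.** It reproduces the
per-reader marginal behaviour (sensitivity, false-positive rate,
compliance, reversals) and the case-mix structure. It does *not* model
correlation between readers beyond the case label: readers are
conditionally independent given the case, with no per-case difficulty
random effect. Real studies have both — some cancers are hard for
everyone — which lowers the pooled aggregate-score AUC relative to the
independent-reader model. Consequently the simulated pooled AUCs
(≈0.85–0.90 unaided) sit above a comparable real study's (≈0.76), the
improvement headroom is smaller, and a single simulated 122-case study's
99% bootstrap interval for the AUC change excludes zero only about half the
time, even though the mean effect is robustly positive on both axes.
Passing tests on synthetic data therefore demonstrate correctness of the
accounting, the ROC/bootstrap machinery and the calibration — not that any
particular single study will reach 99% significance, which at this sample
size is genuinely borderline.

## Numerical and testing choices

* Tolerances: AUC/rank-statistic identities are checked to 1e-12; Monte
  Carlo agreement uses 3–4 Monte Carlo standard errors; parameter recovery
  uses ±0.02 at 5000 simulated cancers (binomial SE ≈ 0.007).
* Degenerate inputs: single-class ROC, zero-baseline percentage changes,
  zero-variance $t$ samples, empty cohorts and empty strata each have a
  defined, tested behaviour (error, `NA`-with-warning, or omission with
  warning, as documented per function).
* The test suite and the acceptance script run the full published scale —
  122 cases, 7 readers, two 10,000-replicate bootstraps — which completes
  in well under a minute; unit tests use smaller studies (6–40 cases)
  where the check is structural rather than statistical, and 1500–5000
  cases where a rate must be estimated precisely.
* The exhaustive bootstrap oracle enumerates all multinomial resamples of a
  6-case study (462 compositions) conditional on both classes being
  present, mirroring the redraw rule.

## Known limitations

* No variance-component MRMC model (Obuchowski–Rockette /
  Dorfman–Berbaum–Metz) and no BCa intervals; the two bootstrap axes are
  resampled separately, not jointly.
* Per-case (not per-lesion) analysis; no FROC.
* The localization rule matches laterality and quadrant tokens; it does not
  intersect claimed boxes, because readers' claims are recorded as
  side/quadrant only.
* The cohort ledger reports lead time to biopsy; if the downstream use
  needs lead time to diagnosis imaging, supply that date as `biopsy_date`.
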