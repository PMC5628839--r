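---
title: "Grouped out-of-bag detection, fusion and visualization: methods"
author: "pdvoice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grouped out-of-bag detection, fusion and visualization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery it
implements: the detection model and its assumptions, the conventions fixed
where several were defensible, the synthetic cohort the tests run on, and
what passing those tests does and does not establish about real data.

## 1. The detection model

### Why subjects, not recordings, are the sampling unit

Voice cohorts are repeated-measures designs: a subject contributes several
recordings (here, three sustained-vowel phonations; one speech sentence
that is further split into voiced and unvoiced parts). Recordings of the
same speaker are far more similar to each other than to anyone else's —
vocal tract anatomy, habitual pitch and loudness act as a strong subject
random effect. A classifier validated on recording-level resampling can
therefore score well by *recognizing the speaker* whose sibling recordings
it trained on, and report an error rate that has little to do with
detecting disease in an unseen person.

`draw_plan()` makes the subject the bootstrap unit: for each tree, within
every class-by-gender stratum, it draws with replacement as many subjects
as the stratum contains. All recordings of a drawn subject enter the
in-bag multiset (with the subject's multiplicity); subjects never drawn
are out-of-bag (OOB) for that tree, together with *all* their recordings.
Two consequences:

* every bootstrap sample preserves the cohort's class and gender
  composition exactly (stratification), and
* OOB evaluation is subject-disjoint from training, i.e. it behaves like
  leave-one-subject-out rather than leave-one-recording-out.

The naive per-recording bootstrap remains available
(`draw_plan(unit = "recording")`, `fit_detector(unit = "recording")`)
solely to demonstrate the bias it induces: on a null cohort (no class
effect) with a strong subject effect, the naive OOB EER collapses far
below 50% — pure speaker memorization — while the grouped plan stays
statistically indistinguishable from chance. The acceptance suite checks
exactly this contrast.

With S subjects in a stratum, a subject is omitted from one tree's sample
with probability (1 − 1/S)^S → e⁻¹, so each recording is OOB for roughly
37% of the B trees; the tests verify this rate. A stratum with a single
subject is degenerate — that subject is drawn every time and never
receives an OOB score — and the plan warns when it happens.

### Trees and scores

Trees are unpruned binary CART: at each node, `q` candidate features are
freshly sampled, the split minimizing the Gini impurity sum of the two
children is taken (thresholds at midpoints between adjacent distinct
values; the first-encountered best split wins, making ties
deterministic), and growth continues until leaves are pure or
unsplittable. Leaves store the in-bag class counts `n(t, ·, c)`.

For a recording `x`, the class frequency at its leaf in tree `t` is
`f(t, x, c) = n(t, x, c) / Σ_j n(t, x, c_j)`; the two class frequencies
sum to one at every leaf. The detector's soft score averages the
posterior difference over the `b` trees for which `x` is OOB:

d(x) = (1/b) Σᵢ f(tᵢ, x, PD) − (1/b) Σᵢ f(tᵢ, x, HC) ∈ [−1, 1],

equivalently `2·(mean OOB PD-frequency) − 1`, an identity the tests check
to machine precision. Soft scores, rather than hard votes, are what make
threshold-free evaluation (DET curves, EER, Cllr) possible; a hard-vote
variant exists only inside the permutation importance, where each tree
votes by the sign of its leaf frequency difference (ties counted as HC).

### Choosing q

`fit_detector()` fits one forest per candidate `q` on the same bootstrap
plan and keeps the one with the lowest OOB minimum Cllr, breaking ties
toward the smallest `q`. The default grid is {⌊√p⌋, ⌊2√p⌋, ⌊p/2⌋} —
the conventional square-root rule, a doubled variant, and a
half-dimension setting that approaches bagged CART. `q = p` disables
feature subsampling entirely and is allowed as a boundary case.

### Reproducibility

One master seed drives everything. The bootstrap plan consumes R's RNG
once at `draw_plan()`; each tree then receives its own deterministic
splitmix64 generator seeded by a documented counter scheme
(`seed·10⁶ + tree index`), so any single tree can be regrown in isolation
and results are identical across platforms independent of R's RNG state.
The same scheme seeds the per-tree permutations of the importance
computation.

## 2. Detection metrics

### ROC convex hull and EER

All score thresholds generate the empirical ROC staircase; its convex
hull (computed by a monotone-chain sweep) is the set of operating points
reachable by randomized thresholding, and equals the ROC of the
PAV-calibrated scores. The equal error rate is the hull's crossing with
the `P_miss = P_fa` diagonal, linearly interpolated inside the crossing
segment; if the hull touches the diagonal along a segment the touching
value is unique by convexity. EER is reported in percent; 50% is the
uselessness bound.

### Minimum Cllr

The cost of the log-likelihood ratio, in bits, for LLRs `l`:

Cllr = 1/(2N_tar) Σ_tar log₂(1 + e^(−l)) + 1/(2N_non) Σ_non log₂(1 + e^(l)).

`min_cllr()` minimizes this over all *monotone* score-to-LLR mappings.
The minimizer is the isotonic (pool-adjacent-violators) fit of the ideal
posteriors; per level set with `a` targets and `b` non-targets the
optimal LLR is `log(a/N_tar) − log(b/N_non)`. Conventions fixed here:

* **Tied scores are merged into weighted blocks before pooling**, so equal
  scores always receive equal LLRs (the violation test uses integer
  arithmetic and is exact).
* **Pure blocks take their limiting LLR of ±∞, contributing zero cost.**
  A level set containing only targets is costless in the limit, and a
  target can never be assigned −∞ (its block would then contain a
  target, hence a finite LLR), so the minimum is always finite. This
  convention makes the two degenerate anchors exact: perfectly separated
  scores give Cllr → 0 and an all-equal (uninformative) score set gives
  Cllr = 1 exactly, the cost of LLR ≡ 0. For *reporting* LLRs,
  `pav_llrs()` clamps infinite block values to ±40.

Both metrics are invariant under strictly increasing score transforms,
and no fixed monotone calibration can beat `min_cllr` — both are property
tests. The test-suite oracle recovers the PAV level sets independently,
from the greatest convex minorant of the cumulative-sum diagram via
`chull()`, and minimizes each block's cost numerically; implementation
and oracle agree to 10⁻⁹ on hundreds of random score sets.

### DET coordinates

`det_points()` maps hull vertices through the standard-normal quantile
function. Probabilities of exactly 0 or 1 are clipped to
`eps = 10⁻⁶` (documented, adjustable) before the probit transform.

## 3. Statistical functionals

`summarize_functionals()` compresses frame-level descriptor trajectories
into the 13 summary statistics used for the hand-crafted feature sets:
min, max, mean, median, lower/upper quartile, trimean
`(2·median + Q_lo + Q_up)/4`, standard deviation, inter-quartile range,
lower range `median − Q_lo`, upper range `Q_up − median`, skewness, and
kurtosis. Conventions: quartiles by linear interpolation of the empirical
CDF (quantile type 7); kurtosis is reported as *excess* kurtosis; both
skewness and kurtosis of a zero-variance trajectory are defined as 0 so
degenerate inputs do not propagate `NaN`s. The identities
`lower range + upper range = IQR`, the quartile ordering, and permutation
invariance over frames are property-tested.

## 4. The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the pipeline
assumes, not the acoustics. For subject *s*, recording *r*, feature *j*:

x_rj = δ·1[s is PD]·1[j ≤ n_informative] + u_sj + ε_rj,

with `u_sj ~ N(0, σ_s²)` drawn once per subject and feature and shared
across all of that subject's recordings *and across modalities of the
same channel* — this is precisely the speaker-identity signal that makes
the leakage demonstration possible — and `ε_rj ~ N(0, σ_e²)` fresh per
recording. The within-subject correlation of any feature is therefore
σ_s²/(σ_s² + σ_e²), which a property test verifies on a large cohort.

Choices worth knowing:

* Informative features are the *first* `n_informative` columns of each
  set, so importance tests can assert their recovery.
* Gender is assigned independently of class and has no feature effect by
  default (a `gender_effect` knob exists, default 0); stratification is
  exercised without confounding.
* The PD subject count is deterministic (`round(n·prop_pd)`); gender is
  Bernoulli.
* Feature sets are generated independently of one another by default;
  nothing in the generator couples them.
* Missingness is modeled at the (subject, channel, modality) cell level:
  affected rows are absent from *all* feature sets of that cell, and no
  table ever contains `NA` cells.
* The default cohort mirrors the reference study population: 99 subjects,
  64 PD, mixed gender, three phonation recordings and one
  speech/voiced/unvoiced recording per subject.

What passing tests on this generator does **not** show: real audio
features are non-Gaussian, heteroscedastic, correlated across sets and
features, and class effects are not a uniform mean shift on a known
sparse support. The generator validates the *pipeline logic* (grouping,
stratification, scoring, fusion plumbing, metric calibration), not
real-data performance claims.

## 5. Decision-level fusion

`assemble_meta()` concatenates the per-(feature set, modality) OOB scores
into a meta-feature table. Two open design points were resolved as
follows:

* **Fusion unit.** When phonation is part of the combination, the fusion
  unit is the phonation *recording*: each of a subject's phonation takes
  becomes a row, and the subject-level speech/voiced/unvoiced scores are
  broadcast to those rows. This keeps per-recording resolution for the
  modality that has it and is the only assembly under which the fused
  cohort's recording count equals the phonation recording count, which is
  how multi-modality fusion cohorts are usually tabulated. Without
  phonation, there is one row per subject-level recording.
* **Repetitions.** `fuse(meta, config, R)` re-randomizes only the
  meta-forest across the `R` repetitions (repetition *r* uses seed
  `seed + r − 1`); the base OOB scores stay fixed. Re-fitting all base
  forests per repetition would multiply cost roughly by the number of
  base tables while the dominant repetition variance is the
  meta-forest's own resampling.

Subjects missing any fused modality are dropped (with a reported count);
dropping a subject never changes other rows. The meta table has exactly
|feature sets| × |modalities in combo| columns, and every cell is a
defined OOB score in [−1, 1].

## 6. Proximity and the 2D map

`proximity()` runs every meta-row down every tree and counts the fraction
of trees in which two rows share a terminal node, over *all* trees — the
co-leaf count is a similarity statement about the fitted forest, not a
validation quantity, so no OOB restriction applies. Φ is symmetric with
unit diagonal; `D = 1 − Φ` has zero self-distance and entries in [0, 1]
but is not necessarily metric (no triangle inequality is claimed).

`embed_proximity()` feeds `D` to a t-SNE embedding implemented in the
package: exact O(n²) gradients, Gaussian input kernel on squared
distances with per-point bandwidths bisected to match the configured
perplexity (default 60, warned about unless `1 ≤ perplexity < n/3`),
early exaggeration ×12 for the first 250 of the configured iterations
(default 1000), momentum 0.5 → 0.8, adaptive per-coordinate gains, and a
seeded Gaussian initial layout, so identical seeds give identical
coordinates. An exact implementation was written because the contract is
the objective (KL divergence between neighbor distributions) plus seed
determinism, and the cohort sizes involved (hundreds of recordings) make
the O(n²) form entirely adequate. The final KL divergence is returned,
and the post-exaggeration KL trace is exposed; a property test checks it
is non-increasing across checkpoints.

`project_new_case()` is the deployment-mode counterpart: an unseen
recording is OOB for every tree by construction, so its base scores
average the leaf-frequency difference over *all* trees; its meta-row is
run down the meta-forest, its proximity row computed against all
existing rows, Φ augmented to (n+1)×(n+1), and the embedding re-run with
the new case as a distinct point.

## 7. Problem sizes and profiles

Two profiles are used throughout. The study-scale profile (B = 5000
trees, R = 99 fusion repetitions) matches the full protocol of the kind
of cohort analysis the package targets. The desk-scale profile —
B = 500, R = 9, cohorts of ~100–120 subjects with 100 features — is what
the test suite and `scripts/acceptance.R` run; these sizes were chosen so
that the whole verification cycle completes in minutes on a laptop while
keeping Monte-Carlo noise on EER to a couple of points (the acceptance
checks use 5-seed means or medians where single-run noise would
dominate). The calibration cohort fixes δ = 1, σ_s = σ_e = 1, 20
informative of 100 features; the leakage cohort raises σ_s to 3 so the
speaker effect dwarfs recording noise, which is the regime where naive
resampling fails most visibly.

## 8. Known limitations

* Two classes only (HC vs PD); no regression forests, class weighting, or
  missing-value handling inside a table — missingness must be expressed
  as absent rows.
* The score is the OOB posterior difference; no probability calibration
  for deployment is provided (min Cllr quantifies the *potential* of the
  scores under the best monotone calibration, not the calibration of any
  shipped mapping).
* Proximities are computed on all trees; a classical OOB-pair-restricted
  variant is not implemented.
* The t-SNE is exact O(n²); cohorts beyond a few thousand recordings
  would need a Barnes-Hut or interpolation-based optimizer.
* The generator's Gaussian, set-independent design is deliberately
  simplistic; see section 4 for what that implies about test coverage.
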