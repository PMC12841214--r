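---
title: "Deriving and evaluating a three-stratum fall-risk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and evaluating a three-stratum fall-risk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallrisk)
```

## The problem and the model

Post-stroke patients are routinely screened for fall risk with
single-score clinical scales. Instrumented Timed-Up-and-Go (ITUG)
testing instead produces ~100 continuous mobility features per subject.
With cohorts of modest size (here: 142 subjects of whom 54 are fallers,
15 of them synthetic), a feature space larger than the sample and strong
class imbalance, a single supervised fit is unstable: which features look
discriminative depends heavily on which non-fallers happen to be in the
training sample. `fallrisk` therefore builds its scale in two steps that
trade a single optimal fit for reproducibility across population
resamplings, followed by a stratification and an exact evaluation.

### Step 1 — consensus feature selection

From a training split with $n_F$ fallers and $n_{NF}$ non-fallers
(canonically 39 and 54), `run_selection()` draws `n_iterations` distinct
balanced subsets: the fallers stay fixed, $n_F$ non-fallers are drawn
without replacement, and no two draws use the same non-faller set
(enforced by fingerprinting; the number of requested draws is checked
against $\binom{n_{NF}}{n_F}$ up front). Each subset trains a
support-vector machine; the subset contributes to consensus only if the
classifier's accuracy on a held-out validation split *strictly* exceeds
`accuracy_gate` (0.80). In retained subsets every feature is tested for
a group difference, and features flagged in at least
`consensus_fraction` (50%) of the iterations are selected, ranked by how
often they were flagged ("discerning power").

The accuracy gate is a safeguard, not a performance claim: it only lets
population configurations with demonstrable out-of-sample separability
vote on feature relevance. The per-feature tests are internal
discriminators, not population-level inference — no multiple-testing
correction is applied, deliberately, because the consensus across
resamplings is the error control.

Assumptions: features are continuous; subjects are exchangeable within
label; the validation split is disjoint from training (the package's
split handling and the augmentation rules below make the stronger
guarantee that it is also free of near-duplicates of training subjects).

### Step 2 — tertile thresholds

For each selected feature, `derive_thresholds()` ranks the $n$ training
values in the risk-increasing direction — ascending for
`higher_is_riskier` features (e.g. TUG duration), descending for
`lower_is_riskier` ones (e.g. gait speed) — and stores the *observed*
values at ranks $\lceil n/3 \rceil$ and $\lceil 2n/3 \rceil$; for
$n = 93$ these are ranks 31 and 62, splitting the training set into
three rank-tertiles of 31. We read "31st and 62nd percentiles" as ranks
rather than an interpolation formula precisely because only the rank
reading reproduces three sets of 31; thresholds are consequently always
actual training values, never interpolated.

The risk direction comes from the feature registry when a
`direction_hint` is recorded; otherwise it is inferred by comparing
training group means (faller mean higher ⇒ `higher_is_riskier`), with an
exact tie resolving to `higher_is_riskier` under a warning. Means rather
than medians keep the inference consistent with the $t$-test branch of
the marking step; the choice only matters for features with negligible
group separation, which rarely survive consensus.

### Step 3 — stratification

`assign_feature_stratum()` maps a value to a stratum with closed extreme
intervals, exactly as threshold tables are conventionally printed
(low $x \ge a$ / medium $b < x < a$ / high $x \le b$ for a
`lower_is_riskier` rule): boundary values belong to the extreme strata,
medium is open on both sides, and every finite value maps to exactly one
stratum. One consequence worth stating: re-applying a freshly built rule
to its own training values places the rank-62 subject — whose value *is*
the high boundary — in the high stratum, so the realized training strata
on tie-free data are (31, 30, 32) even though the defining rank partition
is (31, 31, 31). In the degenerate case of equal thresholds the high
stratum takes precedence. `combine_strata()` takes the mode of the $M$
per-feature strata; any tie among maxima resolves to the highest-risk
tied stratum (an 11-low/11-high split at $M = 22$ is high). All features
vote with equal weight; selection frequency orders the scale but does not
weight it.

Missing features at classification are an error by default
(`min_features = NULL` requires complete records); a permissive minimum
takes the mode over available features and records `n_features_used`.

### Step 4 — exact evaluation

`fisher_freeman_halton()` computes the exact two-sided $p$-value for a
2×3 (generally 2×$c$) fall-status × stratum table by complete
enumeration of tables with the observed margins under the multivariate
hypergeometric null, summing the probabilities of all tables no more
probable than the observed one. This probability-ordering ("two-sided")
convention is the one standard software uses for exact $r \times c$
tests, and it reduces exactly to the two-sided 2×2 hypergeometric test
when a column margin is zero. Probabilities are compared with a relative
tolerance of $10^{-7}$ so that mathematically tied tables split only by
floating-point noise are included; the enumeration works in log-space via
`lchoose`. At the package's table sizes (grand total 32) the enumeration
touches a few hundred tables, so no network algorithm is needed.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure the pipeline assumes, not any
particular real dataset: 39 fallers and 88 non-fallers over 108 features
(8 "clinical" scores named after the comparator scales, with realistic
locations and spreads for a post-stroke rehabilitation population, plus
100 generic ITUG features); `n_informative` features (default 22,
matching the size of the discriminative feature set the method is
designed to find) carry a group-mean shift of `effect_size` (default
Cohen's $d = 1$, a moderate-to-large mobility difference) in a random
direction recorded in the registry; all other features are exchangeable
between groups. Optional knobs add an equicorrelated block on the
informative features (`within_class_correlation`) and log-normal
marginals (`heavy_tail_fraction`); both default to 0.

`augment_fallers()` implements minority-class augmentation: `k` (default
15) distinct real fallers are copied with independent zero-mean Gaussian
noise, SD = `noise_scale` × the faller-group sample SD per feature.
The reference description fixes only that the noise is Gaussian and
variance-based; `noise_scale = 0.1` is our choice — small enough to
preserve the class geometry, non-zero to avoid exact duplicates — and no
numeric claim in the package depends on it. The faller group (not the
whole cohort) is the SD reference because augmentation targets the faller
manifold; zero-variance features are copied exactly; values are not
clipped, so a synthetic subject can carry a negative value for a
physically non-negative quantity — accepted and documented rather than
truncated.

Two structural rules prevent information leakage:

* synthetic subjects are pinned to the training split, and
* once splits are assigned, augmentation templates are drawn from
  *training* fallers only.

The second rule is our design decision and matters more than it looks.
If templates may come from anywhere, a validation faller can have a
near-copy (noise SD 10% of a feature SD) inside the training set; we
measured that under a pure-noise cohort this lifts mean SVM validation
accuracy to ≈ 0.83 and lets ~85% of subsets through the 0.80 gate — the
gate then rewards memorization of leaked duplicates instead of
generalization. `run_pipeline()` and the CLI therefore assign splits
first (24 real training fallers + 15 synthetic = 39) and augment second.
On an unsplit cohort any real faller can serve as a template, which keeps
the plain 127 → 142 augmentation arithmetic available.

What the generator does **not** emulate: the biomechanical covariance of
real ITUG measures (features are conditionally independent by default),
measurement error models, or any calibration to real cohort moments.
Passing tests on synthetic data therefore demonstrate the pipeline's
statistical machinery — calibration, recovery, invariants — not clinical
validity on real patients.

## The consensus denominator

The selection rule divides each feature's relevance count by a
denominator to compare against `consensus_fraction`. Two readings exist:
all `n_iterations`, or only the retained subsets. The package defaults to
**all iterations**. The retained-subsets reading has a failure mode we
consider disqualifying: in a signal-free cohort the gate passes the odd
subset by luck (the validation split is small), and a single retained
subset then promotes every feature that cleared $\alpha$ in it — about
5% of all features — to "100% consensus". Dividing by all iterations
makes a feature's score the product of gate pass rate and marking rate,
so consensus requires both sustained separability and sustained feature
relevance; with strong signal, where nearly every subset passes the gate,
the two denominators coincide. `consensus_denominator = "retained"`
remains available.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_iterations` | 1000 | balanced subsets drawn |
| `subset_nonfallers` | = #training fallers | non-fallers per subset (balance) |
| `accuracy_gate` | 0.80 | strict validation-accuracy retention threshold |
| `alpha_relevance` | 0.05 | per-feature group-test level |
| `alpha_normality` | 0.05 | Shapiro–Wilk routing level (our choice) |
| `consensus_fraction` | 0.50 | minimum relevance fraction for selection |
| `cost` | 1 | SVM regularization; RBF width = 1/#features on standardized data |
| `k` | 15 | synthetic fallers appended |
| `noise_scale` | 0.1 | augmentation noise, in faller-group SDs |

SVM details (unstated in the reference description, fixed here): RBF
kernel, $C = 1$, kernel width $1/\text{\#features}$ after
standardization, standardization statistics estimated on the training
subset and applied unchanged to validation; zero-variance subset features
standardize to zero with a warning. The group test is Welch's $t$
(unequal variances) when both groups pass Shapiro–Wilk at
`alpha_normality`, a rank-sum test otherwise — including when only one
group is non-normal (the conservative routing) or when one group is
constant; features constant in both groups are never marked, since the
tests are undefined.

## Numerical conventions and degenerate inputs

* Cohort CSVs serialize doubles at 17 significant digits, so
  read ∘ write is bit-exact.
* Subset draws are indexed substreams of one master seed: iteration $i$'s
  subset depends only on (seed, $i$), not on execution order; all run
  objects are bit-reproducible given the seed.
* Count reconstruction from printed percentages
  (`reconstruct_counts()`) minimizes the maximum absolute deviation from
  $n \cdot p/100$ over integer compositions of $n$, breaking ties toward
  the largest-remainder apportionment, and refuses targets more than one
  count away.
* Exact-test inputs must be non-negative integers; an all-zero row or a
  single informative column yields $p = 1$ (unique table given margins).
* `derive_thresholds()` requires $n \ge 3$; `combine_strata()` rejects
  empty inputs; non-finite feature values are rejected at stratification.

## Validation against the published comparator table

The package bundles the published stratum distribution of a 32-subject
post-stroke test cohort (22 non-fallers, 10 fallers) across eight
clinical comparator scales, as row percentages with one decimal and the
published exact-test $p$-values
(`reference_clinical_stratification()`). `reproduce_reference_evaluation()`
reconstructs the integer counts from the percentages — the
reconstruction is unique for every row, with all targets within 0.03 of
an integer vector — and reruns the exact test. Six of the eight
published $p$-values are reproduced to the printed precision (FES-I to
within one unit in the last digit, 0.891 vs 0.890). The recomputed
POMA-B (0.482 vs 0.228) and 10 MWT (0.166 vs 0.625) values differ far
beyond rounding; no standard convention we tried (Pearson $\chi^2$ with
or without continuity correction, Monte-Carlo exact, zero-column-dropped
2×2 variants) reproduces those two printed values from those printed
percentages, so we record the inconsistency as a property of the
published table and report the recomputed values, which agree with an
independent brute-force enumeration oracle to $10^{-12}$.

## Problem sizes used by the test suite

The suite validates the exact test against the brute-force oracle on all
18,563 two-row tables with grand total ≤ 12, runs the planted-recovery
experiment at 200 iterations (10 informative features at $d = 1.2$ among
100, canonical 93/17/32 splits), the null-calibration regime at
$d = 0$ over ten seeds at 200 iterations, and the marking-rate
calibration over 500 null feature-subset trials at the canonical subset
size 39 + 39. These sizes are the package's chosen verification scale:
large enough that Monte-Carlo bands (±2–3 SE) are informative, small
enough that the whole suite runs in a couple of minutes.

## Known limitations

* The pipeline conditions on one fixed faller sample; consensus
  fractions are therefore correlated across subsets, and a feature that
  happens to separate groups in the given cohort will be consistently
  selected even if the separation is a cohort-level accident. Consensus
  controls resampling noise, not cohort-level selection bias; external
  validation needs an independent cohort.
* Thresholds are single order statistics and inherit their sampling
  noise; no confidence statement accompanies a stratum assignment.
* The exact test treats strata as nominal; the ordinal structure
  (low < medium < high) is used only by the tie rule, not by the test.
* The generator's independence assumptions make selection easier than on
  real, correlated ITUG features; recovery rates on synthetic data are
  upper bounds in that respect.
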