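---
title: "Methods: movie-watching FC, demographic effects and clip decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: movie-watching FC, demographic effects and clip decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moviefc)
```

`moviefc` analyses parcellated movie-watching fMRI in three stages:
connectivity construction, per-edge mixed-effects testing, and
fingerprint-based clip decoding. This vignette documents the models, the
tunable parameters, the numerical conventions, and what the synthetic
generator does and does not emulate.

## Connectivity construction

A subject × clip time series is a T × R matrix of region-averaged BOLD
signals (1 TR = 1 s in the motivating protocol). `compute_fc()` forms all
pairwise Pearson correlations and applies the Fisher transform
z = atanh(r) to stabilise variance. Two numerical conventions matter:

* **Clipping bound.** atanh(±1) is infinite, so r is clipped to
  ±(1 − 1e−7) before the transform; clipped edges are reported in
  `clipped_edges`. The bound corresponds to |z| ≈ 8.4, far beyond any
  finite-T correlation of interest.
* **Degenerate columns.** A constant region (zero temporal variance) has
  undefined correlations; these edges get r := 0 and are listed in
  `degenerate_edges` rather than silently dropped.

`threshold_by_sparsity()` implements proportional thresholding: the top
⌊s·E⌋ upper-triangle edges by **signed** z are retained with their
continuous values, the rest are zeroed, and the matrix is mirrored. The
sparsity s is 0.25 by default with 0.2 and 0.3 as robustness settings.
Signed ranking (largest positive first) rather than |z| is the convention
in proportional-threshold FC studies and keeps the directional readout of
the effects stage interpretable; `rank_by = "absolute"` is available. Ties
are broken by ascending edge id, which makes the retained set — and
everything downstream of it — fully deterministic.

Edges are indexed 0-based, row-major over the upper triangle (fixed once in
`edge_index()`), because ACSC ranks, feature ids and file exports all
depend on one canonical ordering. A caveat worth knowing: re-thresholding
an already-thresholded adjacency is a fixed point only when every retained
edge is positive (zeroed edges would otherwise outrank retained negative
ones under signed ranking). At s ≤ 0.3 on FC-like input the retained
quartile is positive in practice, and the property-style test exercises
exactly that regime.

## Per-edge mixed-effects model

Each edge's FC value (by default the thresholded adjacency value, zeros
included, matching the convention that the thresholded matrix feeds all
downstream analyses; pass an unthresholded stack for the continuous-z
variant) is modelled as

```
fc ~ sex + age + clip + sex:age + sex:clip + age:clip + motion + (1 | subject)
```

with clip the within-subject factor, sex and age between-subject, and mean
head motion a between-subject covariate. Age enters as an ordinal numeric
covariate (levels 1–3), so its main effect is a monotone trend — the
readout "FC increases/decreases with age" — rather than an unordered
3-level contrast.

**Fitting.** Every dataset this package produces is balanced (each subject
sees each clip exactly once), and for balanced designs the random-intercept
model decomposes exactly into two orthogonal strata:

* between-subject: subject means regressed on `1 + sex + age + sex:age +
  motion`, testing sex, age, sex:age and motion against the
  subject-residual mean square with df₂ = n − 5;
* within-subject: deviations from subject means regressed on
  `clip + sex:clip + age:clip` (sum-to-zero codings), testing the clip
  terms against the within-residual mean square with
  df₂ = (C − 1)(n − 3).

This is the classical split-plot analysis with containment denominator
degrees of freedom, computed as Type III (drop-term) F-tests by vectorised
linear algebra across all edges simultaneously — the whole-connectome fit
costs a few matrix products. `method = "lmer"` fits the same model per edge
via `lmerTest` (Satterthwaite df) and serves as the independent cross-check
in the test suite, where the two routes agree to ~1e−4 in F on balanced
data; it falls back to OLS with the subject term omitted (and flags the
edge) if the random-intercept fit is singular.

Effect size is partial eta squared recovered from the F statistic,
η²p = F·df₁/(F·df₁ + df₂). Directions are attached to the sex and age main
effects only (+ = greater in females / increasing with age), taken from the
sign of the corresponding between-stratum coefficient.

**Multiplicity.** Benjamini–Hochberg step-up FDR is applied per model term
across edges (one family per term, α = 0.05) — the most common convention
in edge-wise FC studies, where each term's connectome-wide map is read as
one analysis. The implementation is the sorted cumulative-minimum
form; the tests check it exactly against both `p.adjust(method = "BH")` and
a definition-by-enumeration oracle. Edges with no residual variation in a
stratum are flagged and excluded from the FDR family rather than
contributing p = NaN.

`aggregate_by_network()` maps significant edges to ordered network pairs
(7 canonical networks: VN, SMN, DAN, VAN, LN, FPN, DMN) and counts them by
direction — the network-level readout of where each group shows greater FC.

## ACSC fingerprint scoring and clip decoding

For edge e, stack the per-subject, per-clip values and form the
subject × subject matrix S of cross-session distances: S[i, j] is the mean
over ordered session pairs (a ≠ b) of |v(i, a) − v(j, b)|. Diagonal entries
average only distinct-session pairs — same-session self-distance is
trivially 0 and would bias the score. The score is

```
ACSC(e) = mean(off-diagonal of S) − mean(diagonal of S)
```

so large scores mark edges that are stable within a subject across clips
yet different between subjects: FC fingerprints. Two design decisions are
worth stating. First, the sign: defining the score as diagonal minus
off-diagonal of a *distance* matrix would make the best fingerprint edges
the most negative, contradicting the semantics "large score = high
same-subject cross-session similarity"; the off-diagonal-minus-diagonal
orientation preserves those semantics, and `literal_sign = TRUE` provides
the other reading. Second, scoring is per edge — top-k selection *of edges*
requires an edge-wise criterion — while `cross_session_matrix()` exposes
the whole-vector S over any edge subset for diagnostics.

The implementation avoids the quadruple loop: each of the restricted sums
reduces to column-wise sums of all pairwise absolute differences, computed
by one radix sort per matrix via the sorted-weights identity
Σ|xₚ − x_q| = 2·Σₖ(2k − m − 1)x₍ₖ₎. The test suite verifies exact
(1e−12) agreement with the brute-force definition on 100 random instances.
Scores are translation-invariant and invariant to subject/session
permutations; zero-variance edges are flagged and scored 0.

**Classification.** Clips (15 balanced classes, chance = 1/15 ≈ 6.7%) are
decoded with a linear one-vs-one SVM (C = 1, no standardisation —
the stock behaviour of a default error-correcting one-vs-one SVM; all
settings in `classifier_config()`). Cross-validation is always grouped by
subject: LOOCV holds out one subject's 15 samples per fold, 10-fold holds
out a seeded subject partition, and ACSC scores are computed inside each
training fold only — test subjects never influence feature selection, a
property audited by a corruption test. Macro-F1 accompanies accuracy: with
balanced classes micro-F1 degenerates to accuracy, which would make a
separate F1 column redundant. A class absent from both truth and
predictions is excluded from the macro mean (it cannot occur in balanced
CV); a class never predicted scores 0. One-vs-one voting ties resolve to
the lowest class label.

The published feature grid k ∈ {1,000, 4,000, …, 19,000} ∪ {full} is
defined for E = 19,900; `scale_k_grid()` rescales it proportionally
(k′ = max(1, round(k·E′/19,900))) so desk-scale sweeps keep the grid's
shape. `k_sweep()` emits one result per (sparsity, k) cell in the layout of
the published F1 table.

## The synthetic generator

`make_ground_truth()` + `make_dataset()` emulate the structure the
analyses assume: each subject × clip series is a zero-mean multivariate
normal draw whose covariance is

```
base (network-block) + clip component + subject fingerprint + sex/age effects
```

eigenvalue-floored at 1e−6 and re-symmetrised when the additive components
break positive definiteness. Defaults define the desk-scale study
conditions and were fixed once, on first principles:

* R = 50 regions in 7 contiguous-block networks, n = 30 subjects,
  durations = the published 15-clip catalogue × 0.5 plus 10 trailing TRs
  per segment (the hemodynamic-delay segmentation), noise SD 1 — small
  enough that the full pipeline runs in minutes, large enough that E = 1,225
  supports a meaningful k-grid;
* base correlations 0.3 within- / 0.1 between-network, typical of
  parcellated FC;
* 400 clip-informative edges with uniform ±0.25 clip-specific covariance
  offsets; 100 fingerprint edges with subject-specific N(0, 0.15) offsets
  (between-subject spread comfortably above the ≈1/√(T−3) ≈ 0.1 sampling
  noise of a Fisher-z edge at these durations); 50 sex and 50 age effect
  edges with signed offsets, drawn from the within-network pool so their
  baseline correlation keeps them above the sparsity threshold;
* motion is generated (log-normal) but has **no** planted FC effect by
  default — it is a null covariate, with configurable leakage and a
  sex–motion confound for covariate-adjustment tests.

Randomness is hierarchical: every per-(subject, clip) stream derives from a
stable string hash of (master seed, subject id, clip label), so a dataset
is bit-reproducible regardless of generation order, and a subject's
fingerprint component is identical in every clip by construction.

`simulate_edge_table()` generates observations directly at the edge level
(subject intercept + clip effect + planted effects + residual), bypassing
the time-series nonlinearity (Pearson → atanh → thresholding) so that a
planted effect of "δ = 1 SD" is exact in residual-SD units. Quantitative
calibration claims — sensitivity ≥ 0.9 and FDR ≤ 0.1 for a 1-SD effect at
n = 40, nominal type-I rates on null edges — are checked there, with
defaults σ_subject = 0.5, σ_clip = 0.3, σ_resid = 1 (within-subject
clip-to-clip variability exceeding between-subject variability, as in real
single-edge FC). The time-series route is additionally checked for planted
direction and contrast recovery, without the tight bands.

What the generator does **not** emulate: hemodynamic convolution and
autocorrelated BOLD noise (samples are temporally white), scanner/motion
artefacts, heavy-tailed FC distributions, distance-dependent edge
dependence, or any genuine neural geometry in the block partition. Passing
tests therefore demonstrate correctness of the estimators and honest
cross-validation under the assumed generative structure — not that real
movie-watching data satisfies that structure.

## Problem sizes and runtime choices

The test suite and acceptance script use: R = 10 (E = 45) for the
169-subject structural check of the 168 × 168 training-fold similarity
matrix; 350 edges × 5 seeds for planted-effect recovery; 2,000 null edges
for type-I calibration (Monte-Carlo SE ≈ 0.005 against the ±0.02
acceptance band); and n = 20, R = 50, k = 500 for the decoding checks,
where the strong-signal configuration (clip offsets ±0.35) is decoded at
ceiling and null-signal accuracy stays in a seeded band around 6.7%
chance. These sizes are the package's desk-scale study conditions; the
full-scale configuration (R = 200, n = 169) is supported by the same code
paths.

## Known limitations

* The between-within decomposition is exact only for balanced designs;
  unbalanced data (missing clips) are rejected rather than approximated —
  use `method = "lmer"` after completing the design.
* Proportional thresholding with signed ranking can retain negative edges
  at high sparsity, where the idempotence property no longer holds (see
  above).
* The SVM route inherits libsvm's deterministic but
  implementation-defined handling of exact vote ties.
* Real-data headline numbers (e.g. published F1 tables on the HCP 7T
  release) require the original restricted dataset and are out of scope;
  the package reproduces structural, closed-form and planted-recovery
  quantities instead.
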