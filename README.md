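# moviefc

Movie-watching fMRI evokes functional connectivity (FC) patterns that carry
two kinds of information at once: stable demographic signatures (sex, age)
and stimulus-specific signatures of the film clip being watched. `moviefc`
implements the full analysis chain for studying both on parcellated
movie-watching data — and, because the motivating dataset (the HCP 7T
movie-watching release, 169 subjects × 15 clips, 200 regions in 7 canonical
networks) cannot be redistributed, it ships a ground-truth-aware synthetic
generator so every stage is testable end to end.

The package is aimed at researchers analysing naturalistic-fMRI connectomes
and at anyone who needs a tested reference implementation of
fingerprint-based feature selection for connectome classification.

## What it computes

**Connectivity.** For each subject × clip time series (T × R), pairwise
Pearson correlations are Fisher z-transformed, z = atanh(r), and the matrix
is proportionally thresholded: the top ⌊s·E⌋ edges by signed z are kept
(E = R(R−1)/2; s = 0.25 primary, 0.2/0.3 robustness), so every subject's
network has identical edge count. At R = 200, s = 0.25 that is 4,975 of
19,900 edges.

**Demographic and stimulus effects.** Each edge's thresholded FC is
modelled as

```
fc ~ sex + age + clip + sex:age + sex:clip + age:clip + motion + (1 | subject)
```

with clip as the within-subject factor, sex and ordinal age (3 levels) as
between-subject factors and mean head motion as a covariate. For the
balanced designs produced here the model is fitted exactly by the
between–within (split-plot) decomposition, vectorised across all edges at
once; per-term Type III F-tests yield partial eta squared
η²p = F·df₁/(F·df₁ + df₂) and a direction for the sex and age main
effects. p-values are corrected per term with Benjamini–Hochberg FDR, and
significant edges are aggregated into 7 × 7 network-pair counts split by
direction.

**Clip decoding.** Each subject's 15 clip-wise FC vectors are classified
with a linear one-vs-one SVM (C = 1, no standardisation) under
subject-level leave-one-out (and 10-fold) cross-validation. Inside every
training fold, edges are ranked by the Average Cross-Session Correlation
(ACSC) score: for edge e, with S the subject × subject matrix of mean
cross-session distances,

```
ACSC(e) = mean(off-diagonal of S) − mean(diagonal of S)
```

so high-scoring edges are session-stable within subjects but
subject-discriminating. The top-k edges (k from 1,000 to 19,000 in steps of
3,000, rescaled proportionally for smaller connectomes, plus "full") are
the classifier features; chance level for 15 balanced classes is 6.7%.

## Worked example

```r
library(moviefc)

cohort <- make_cohort(20, sex_ratio = 0.5, seed = 1)
truth  <- make_ground_truth(50, seed = 1, clip_strength = 0.35)
ds     <- make_dataset(cohort, clip_catalogue(), truth)
stack  <- fc_stack(ds, sparsity = 0.25)

eff <- fit_edge_models(stack, cohort)
sx  <- subset(eff, term == "sex" & q <= 0.05)
nrow(sx)                                      # 50 discoveries
sum(sx$edge_id %in% truth$sex_effect_edges)   # 46 of the 50 planted edges

res <- loocv_classify(stack, k = 500)
res$accuracy                 # 1.0  (strong planted clip signal)
res$f1                       # 1.0
round(100 * chance_accuracy(15), 1)   # 6.7
```

At this small n (20 subjects) the sex term already recovers 46 of the 50
planted edges at q ≤ 0.05, and the strong planted clip signal is decoded at
ceiling against the 6.7% chance floor; all numbers shown are the printed
output of this exact script.

The numbered scripts under `analysis/` run the same stages at the
desk-scale study configuration (30 subjects, 50 regions, 15 clips) and
write their tables under `results/analysis/`:

```sh
Rscript analysis/01_simulate.R       # synthetic cohort -> TSVs
Rscript analysis/02_connectivity.R   # FC edge vectors at s = 0.2/0.25/0.3
Rscript analysis/03_effects.R        # per-edge mixed models + network counts
Rscript analysis/04_classification.R # ACSC + SVM sweep (several minutes)
```

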