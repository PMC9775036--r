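---
title: "Semi-supervised deep survival forests: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised deep survival forests: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Prognosis from genome-wide expression profiles is a right-censored
regression problem with far more genes than patients (p on the order of
20,000, n of a few hundred). `dfsc` implements a *deep survival forest
cascade*: a stacked, non-neural "deep" model in which each level holds an
ensemble of survival forests whose predictions augment the input features
of the next level, with an elastic-net Cox model linking each level's
augmented features to a risk score. Because outcome labels are expensive,
the package adds a teacher–student semi-supervised loop: a cascade fitted
on labeled samples pseudo-labels the unlabeled pool, and a student cascade
is refitted on the enlarged dataset.

## Model

The hazard for a sample with expression vector $x$ follows proportional
hazards,

$$h(t \mid x) = h_0(t)\, e^{\eta(x)},$$

where $\eta(x)$ is the cascade's risk score: the linear predictor of the
final level's elastic-net Cox model over the level's augmented features
(original genes plus that level's forest outputs). Parameters are
estimated from the Cox log partial likelihood with Breslow tie handling,

$$\ell = \sum_{j:\,\sigma_j = 1}\Big[\eta_j -
  \log\!\!\sum_{i:\,T_i \ge T_j}\!\! e^{\eta_i}\Big],$$

computed in the log domain with max-subtraction so forest-derived scores
cannot overflow. The cumulative baseline hazard is the Breslow estimator
$\hat H_0(t) = \sum_{t_k \le t} d_k / \sum_{i \in R(t_k)} e^{\eta_i}$, and
survival curves are $S(t \mid x) = \exp(-\hat H_0(t) e^{\eta(x)})$.
Adding a constant to all $\eta$ rescales $\hat H_0$ by its inverse and
leaves every survival prediction unchanged; the test suite asserts this
identifiability property.

## The cascade

Each level holds `n_forests_per_level` survival forests (default 4), half
standard log-rank forests, half *completely random* forests — trees whose
split feature and threshold are drawn uniformly at random (`ranger`'s
single-split extra-trees with `mtry = 1`), added for ensemble diversity.
Each forest contributes one prediction feature per sample, its ensemble
mortality $\sum_k \hat H(t_k \mid x)$ on a fixed 10-point quantile time
grid, on the `log1p` scale (survival forests have no class-probability
vector, the augmentation currency of classification deep forests;
ensemble mortality is the survival analogue). `features_per_forest > 1`
adds survival probabilities at quantile times.

Two design rules keep the cascade honest:

* **Out-of-fold augmentation.** The forest features fed to a level's Cox
  link (and to the next level) for *training* rows come from forests that
  never saw the row (3-fold cross-fitting by default); validation and
  test rows use the full forest. An in-fold variant exists only to
  demonstrate, in a property test, that in-fold features rank pure-noise
  training outcomes far above chance while out-of-fold features sit at
  0.5.
* **Validated growth.** An event-stratified fraction
  (`validation_fraction`, default 0.2) is held out before any forest is
  grown. Each level's penalty strength is chosen from a small log-spaced
  grid (5 values) by validation concordance, growth stops when validation
  concordance fails to improve for `patience` levels, and only levels up
  to the best score are kept — the retained depth maximizes the
  validation history by construction.

Default dimensions follow classification deep-forest practice at desk
scale: 4 forests per level, 100 trees per forest, at most 5 levels,
patience 1. All are exposed in `cascade_config()`.

### Numerical choices

Log-rank split evaluation cost grows with the number of distinct death
times, so forest *training* responses are coarsened onto a 30-bin
quantile time grid (`forest_time_bins`; Cox links, baseline hazards and
all metrics always use exact times). Forest mortality is read off a fixed
quantile grid so out-of-fold pieces share a scale. Terminal node size
defaults to 15, the customary survival-forest value. For `p > 5000` an
optional variance screen (`screen_top`) limits the pass-through feature
set. Every forest's seed is derived deterministically from
`random_seed`, level, forest and fold indices; fits are bit-reproducible.

## The teacher–student loop

`fit_dfsc()` fits a supervised cascade (round 0), then repeats: the
current teacher pseudo-labels the unlabeled pool; a student cascade is
fitted on the labeled rows plus accepted pseudo-labeled rows; the student
is promoted to teacher while its validation concordance improves, up to
`max_rounds` (default 3). The labeled validation split chosen in round 0
is reused in every round, so pseudo-labeled rows can never enter
validation, and the returned model — the round with the best labeled
validation concordance — is never worse than the supervised fit on that
criterion. With an empty pool, or a confidence gate that rejects every
pseudo-label, the result is bit-identical to `fit_cascade()`.

A pseudo-label carries the teacher's *median survival time* (the first
baseline event time where the predicted curve reaches 0.5; the last
observed event time if it never does) and is treated as an event
(`pseudo_as_censored` flips this; a pseudo-censoring adds no ranking
information to the partial likelihood, which is why the event reading is
the default).

### Soft risk classes and the confidence gate

Survival models have no native classes for a distillation loss, so the
teacher's training risk scores are z-scored and cut into `n_risk_bins`
(default 4) quantile bins. A sample's bin score is the log probability
mass of the bin under a Gaussian kernel centred at the sample's
standardized risk, with bandwidth half the mean bin-center spacing;
temperature-softening these scores (softmax of score$/\tau$, $\tau$
default 2) gives the soft distribution whose maximum is the pseudo-label
confidence (gate default 0.7). Two simpler constructions were rejected
during development, both for scale pathologies: raw-scale distances make
the gate an artifact of the Cox penalty (one probe accepted an entire
120-sample pool and regressed test concordance by 0.04), while absolute
distances on the z-scale cap the maximum soft probability near 0.41 —
below any useful gate — because their score gaps are bounded by the
bin-center spread. The kernel-mass construction is scale-invariant and
lets confidently-extreme samples approach one-hot membership.

The distillation loss is the soft cross-entropy
$-\frac{1}{|U|}\sum_{x_i \in U} \sum_y P_T(y \mid x_i; \tau) \log P_S(y
\mid x_i; \tau)$ over the accepted pool $U$ (without the minus sign the
sum is unbounded below and cannot be a minimization target, so
cross-entropy is the only coherent reading); by Gibbs' inequality it is
minimized over the student
exactly at $P_S = P_T$, where it equals the teacher's entropy. The loop
reports it per round as a convergence diagnostic. The stated convergence
condition ("the optimal solution" on the enlarged training set) is not
decidable as written; labeled-validation early stopping is the measurable
surrogate used here.

## Stability selection and evaluation

`stability_select()` fits L1-penalized Cox models on B = 100
event-stratified half-subsamples over a 10-point log-spaced penalty grid
anchored at the full-data $\lambda_{\max}$; a gene's *stable score* is
the fraction of subsamples in which it gets a nonzero coefficient at any
grid penalty — scores near 1 mark robustly selected genes. Reported
p-values are per-gene univariate Cox Wald tests on the full data (raw,
with a Benjamini–Hochberg column, since how to define gene-level
significance is otherwise open). Constant genes score 0 and are flagged.

Evaluation uses Harrell's concordance (pair `(i, j)` comparable iff
$T_i < T_j$ and $\sigma_i = 1$; risk ties count 1/2) and the
IPCW-weighted Brier score (weights $1/\hat G(T_i^-)$ for events before
$t$, $1/\hat G(t)$ for samples at risk past $t$, zero for earlier
censorings, with $\hat G$ the Kaplan–Meier estimate of the censoring
distribution), integrated by trapezoid over the 10%–80% event-time
quantile grid so one scalar per model remains. Cross-validation is
event-stratified (small event counts make unstratified folds
degenerate); single-sample folds (leave-one-out) have no comparable
pairs, so per-fold metrics are `NA` and a pooled out-of-fold row is
always reported. Internal baselines `lasso_cox` (penalty by internal CV)
and `rsf` (one log-rank forest) share folds with the cascade specs for
paired comparison.

## The synthetic cohort generator

`generate_survival_data()` is the test substrate standing in for the
TCGA cohorts: block-correlated Gaussian expression (blocks of 10 genes at
exchangeable correlation 0.4, emulating co-expression), standardized per
gene; a sparse causal set (default 10 genes at $|\beta| = 1$, alternating
signs); event times $T^* \sim$ Weibull(shape, rate
$\lambda_0 e^{x\beta}$) — exponential by default, the shape only rescales
the time axis and leaves rank-based metrics untouched; censoring times
from a same-shape Weibull whose rate is solved numerically so expected
censoring hits the target (closed form $\lambda_c / (\lambda_T +
\lambda_c)$ per sample), 30% by default. Samples are partitioned
uniformly into labeled / unlabeled / test sets; the default fractions
(50/25/25 of n = 300) mirror the roughly half-labeled training pools of
the TCGA benchmark design, whose exact per-cohort counts
`tcga_like_preset()` reproduces (e.g. PAAD 65/61/50). Unlabeled rows keep
their outcomes only in the returned ground truth, which also carries the
causal gene set and true risk scores for parameter-recovery tests.

The generator deliberately omits RNA-seq count noise, batch effects and
pathway-structured signal, so passing tests demonstrate correct mechanics
and honest generalization under proportional hazards — not performance on
real sequencing data.

## Benchmark scale and what the checks show

The simulation-based checks (test suite and `scripts/acceptance.R`) run
the generator at its defaults (n = 300, p = 500–1000) with a benchmark
model configuration of 4 forests × 50 trees, at most 2 levels, 3
out-of-fold folds — sizes chosen so the full study runs on a laptop in
minutes; package defaults are larger. Under these conditions the
semi-supervised cascade reaches a mean test concordance around 0.76–0.80
(true-risk oracle ≈ 0.89), stays inside [0.40, 0.60] on zero-signal
cohorts, and stability selection recovers 10/10 causal genes with scores
above 0.6.

One empirical claim deserves honesty: with half the training outcomes
masked (75 labeled samples), the paired benefit of pseudo-labeling over
the labeled-only cascade is statistically indistinguishable from zero at
this scale (mean paired difference within ±0.01, sign unstable across
seed sets). The round-selection validation split holds only ~15 samples
there, and the confidence gate admits only a handful of pseudo-labels per
round, so accepted students move test concordance by at most a few
thousandths either way. The package reports the paired difference rather
than asserting a benefit it cannot demonstrate at desk scale.

## Known limitations

Breslow tie handling only (no Efron/exact); no time-varying covariates,
competing risks or left truncation; Harrell's concordance rather than
Uno's IPCW variant; no survival-SVM or boosting baselines. The cascade's
prediction cost grows with depth since every level's forests are
evaluated. Confidence gating assumes the teacher's risk distribution is
roughly unimodal on the z-scale; heavily clustered risk scores would
make quantile bins unstable.
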