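---
title: "Multiview iterative random forests: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiview iterative random forests: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What this package computes

`mirf` discovers prognostic features and low-order signed feature
interactions from two z-scored omics views (microarray-style gene
expression and RPPA-style protein expression) observed on a shared sample
set, for a binary clinical contrast such as short-term (OS ≤ 6 months)
versus long-term (OS ≥ 2 years) survival, or low (≤ 60) versus high
(≥ 80) Karnofsky performance score. The engine is an iteratively
reweighted random forest combined with generalized Random Intersection
Trees (RIT), wrapped in three nested layers of bootstrap resampling:

1. **Inner layer** — each tree is grown on a bootstrap of its training
   set (the ordinary random-forest bootstrap).
2. **Outer stability layer** — after the final reweighting iteration, the
   training set is bootstrapped `B` times; each bootstrap refits the final
   weighted forest, projects its class-1 decision paths into signed
   itemsets, and runs RIT. An interaction's *stability* is the fraction of
   the `B` replicates that recover it.
3. **Replicate layer** — the whole procedure (train/test split, `K`
   reweighting iterations, stability bagging) is repeated on `R`
   bootstraps of the full dataset. A feature is *persistent* when its
   count-weighted Gini importance is at least `gini_min` in at least
   `persistence_min` of the replicates; an interaction is reported when
   its replicate-averaged stability strictly exceeds `stability_min` and
   all its members are persistent.

Three designs are trained per task — the gene view, the protein view, and
their feature-wise concatenation ("integrated") — and features retained by
both a single view and the integrated design are reported as cross-view
consensus.

## The reweighted forest

Trees are axis-aligned CART classification trees. At every split, `mtry`
(default `ceiling(sqrt(p))`) distinct candidate features are drawn without
replacement with probability proportional to the current feature weights;
the winning candidate maximizes the count-weighted Gini decrease

    n·G(parent) − n_L·G(left) − n_R·G(right),   G = 1 − Σ_k p_k²,

with ties broken by lowest feature index, then lowest threshold, so runs
are bit-reproducible under a fixed seed. Iteration 1 uses uniform weights;
iteration `k > 1` uses the previous iteration's importances, floored at
`1e-6` of their maximum so that no feature is permanently excluded by one
unlucky forest. The reported importance is the per-tree sum of
count-weighted decreases, averaged over trees.

**The importance scale is n-dependent.** Because decreases are weighted by
raw node counts (the convention under which a retention threshold of
"mean decrease in Gini ≥ 1" is meaningful), a tree's total decrease equals
`n·G(root)` minus the count-weighted leaf impurity — it grows linearly
with the training-set size. The default `gini_min = 1` is calibrated to
cohorts of a few hundred samples; see the null-behavior section below.

The tie-break rule trades permutation equivariance for reproducibility:
deep nodes holding a handful of samples routinely tie *exactly* in
count-weighted decrease (the decrease is a rational function of small
integer counts), and an index-based tie-break resolves those ties
differently under column permutation. Where the best split is unique —
in particular for stumps and shallow trees on continuous data —
importances are exactly equivariant, and the test suite pins that case.

## Signed itemsets and RIT

Every leaf holding at least one class-1 training sample contributes the
set of `(feature, sign)` pairs along its root-to-leaf path (`−` for the
`≤` branch, `+` for the `>` branch), weighted by the leaf's class-1
count; when a path splits twice on one feature in opposite directions the
deepest split's sign is kept, since the deepest constraint is the binding
one in the leaf's region. Only class-1 paths are mined (the positive
class carries the interactions of interest); this is configurable by
relabeling.

RIT grows `n_rit_trees` (default 500) intersection trees of depth `D = 5`
with `n_child = 2` children per node: the root is an itemset sampled with
probability proportional to its weight, and each child intersects its
parent's set with a freshly sampled itemset. Children of the root are
forced to sample an itemset index different from the root's, so every
depth ≥ 1 survivor is the intersection of at least two *distinct* input
itemsets (with a single input itemset the operation degenerates to the
identity, which is the correct closure behavior). Surviving leaf sets of
size ≥ `min_order` (default 2) are deduplicated and returned. A set with
prevalence θ among class-1 paths survives one root-to-leaf branch with
probability about θ^(D+1), so frequent sets pass and rare ones are
destroyed.

Stability is computed on signed sets; an unsigned view can be obtained by
collapsing signs downstream, but the signed form is what the
interaction figures of the underlying method display.

## Evaluation

Each replicate bootstraps the full dataset, then splits **by original
sample identity** into stratified 80/20 train/test parts, so bootstrap
copies of one sample never straddle the boundary. The literal
"split-the-bootstrap-rows" reading leaks training rows into the test set
and inflates null AUPR by about 0.3 over class prevalence — measurably
wrong, hence the identity-level split. Test AUPR is the area under the
precision–recall step curve of the forest's class-1 probabilities;
interaction AUROC treats each replicate's recovered interactions as
instances, scores them by stability, and labels as positive those whose
members all belong to the declared reference set (persistent features, or
planted features in simulations). Replicate metrics are summarized by a
mean, a t-based 95% confidence interval, and a one-sample t-test against
the appropriate baseline (class prevalence for AUPR, 0.5 for AUROC).

## The synthetic world

The generator (`simulate_multiomics()`) is a stand-in for the real
two-omics cohort the method was developed on; the joint distribution of
real omics views is not modeled, and generator choices are deliberately
simple:

* Both views are standard-normal z-scores; features are independent
  except the planted structure.
* Three planted features: genes `g1`, `g2` and protein `p1`, where `p1`
  is a correlated noisy copy of `g1` (ρ = 0.6), emulating the cross-view
  consensus signatures (a transcript and its protein product carrying the
  same signal) that motivate the integrated design.
* The binary outcome follows the Boolean rule
  `g1 > 0 AND (p1 > 0 OR g2 > 0)` with `P(outcome = 1)` equal to 0.9
  where the rule holds and 0.1 elsewhere. All three features are
  marginally informative, and the class-1 decision paths concentrate on
  the cross-view conjunction `(g1+, p1+)` — the planted interaction pair.
  An earlier draft used `(g1 AND p1) OR g2`; that world puts most class-1
  mass on the marginal `g2` branch, so the dominant recovered sets are
  `{−g2, …}` combinations rather than the planted pair, and it was
  revised once, before the acceptance checks were frozen.
* Survival is Weibull proportional hazards with shape 1.2 and scale 12
  months (a GBM-like median OS around one year), log-hazard linear in
  the planted features with coefficients 0.4, and independent
  exponential censoring whose rate is calibrated on the drawn event
  times to hit the requested censored fraction (default 20%).
* KPS is a latent score positively coupled (0.6) to longer survival,
  thresholded at (−1, 0, 1) onto {40, 60, 80, 100} — mirroring the
  observation that most long survivors have KPS ≥ 80.
* Missingness is MCAR only; no mechanism is claimed by the source
  method.

Because survival is linear in the planted features while the
classification outcome is the Boolean rule, simulated analyses of the
planted outcome pass it to `run_mirf(..., labels = cohort$truth$outcome)`
rather than thresholding the simulated OS months; the clinical
thresholds (≤ 6 / ≥ 24 months; KPS ≥ 80 / ≤ 60) remain the default path
for real cohorts.

A green planted-recovery test establishes that the pipeline finds this
kind of signal at this n and p; it does not establish performance under
correlated noise, batch effects, informative censoring, or real
expression marginals — none of which the generator emulates.

## Null behavior and the persistence threshold

On shuffled-label data the pipeline's test AUPR tracks class prevalence
(leak-free splits), but the persistent-feature set is *not* empty at the
default `gini_min = 1` with the reduced configuration (n = 400, 150
features per view, K = 3): a shuffled cohort retains finite-sample
feature–outcome correlations up to about `sqrt(2·log p / n)` ≈ 0.17, and
iterative reweighting concentrates split mass onto those chance features
in every replicate (they are properties of the cohort, stable across its
bootstraps). Their count-weighted importances land in 1–8 — far below
planted features (20–60) but above 1. The measured landscape: raising
`gini_min` to 2/3/4 drops the null median persistent count to 4/1/0
while planted recovery stays at 9–8 of 10 seeds; by 10 the weakest
planted feature (the OR-arm gene, importance ≈ 5–10) is lost. Treat
`gini_min` as an n-dependent dial with a genuine trade-off, and consider
a shuffled-label run as a calibration companion to any real analysis.

## Survival validation

Kaplan–Meier curves, the two-group log-rank test (`U²/V` against χ²₁),
mean-expression dichotomization (values at the mean go to "low"; the
boundary is arbitrary but fixed), and Harrell's concordance are
implemented directly; the Cox partial-likelihood machinery wraps
`survival::coxph` (Breslow ties by default — ties are sparse in monthly
data — with Efron behind a flag) and `glmnet` for the elastic-net path,
the same engines the original analysis used. The penalized fit runs a
10-fold, event-stratified cross-validation over the `glmnet` λ path and
selects the λ maximizing the held-out Harrell C computed by this
package's own concordance routine. The mixing parameter α defaults to
0.5 and is recorded in the output, since the source method names the
elastic net without stating α. Note that the C-optimal λ is a
*prediction*-optimal choice: it reliably keeps truly prognostic features
nonzero but routinely carries extra noise features (measured: both true
features retained in 10/10 simulations; exact support recovery only
3/10) — a known property of prediction-tuned elastic nets, not a defect
of the implementation. Backward stepwise elimination uses AIC, removing
the feature whose removal most improves it, with the empty (null) model
as the base case. Univariate hazard ratios use continuous z-scored
expression by default; Table-style dichotomized fits are available via
`dichotomize_by_mean()`.

## Stratification and embeddings

A signature score is the unweighted mean of z-scored expression over the
signature's features (absent features are reported and skipped, as when
a signature gene is missing from an external cohort; duplicated entries
collapse with a warning). Reference cutoffs are the long- and
short-survivor group means of the score, compared by a Bonferroni-
corrected unpaired Welch t-test. Zone assignment is the single largest
interpretive choice in the package: a sample is assigned to a survival
zone when its score lies *beyond that group's mean* on the correct side
(boundary inclusive), leaving a middle unassigned band — this reproduces
the qualitative "zones with an unassigned middle" behavior of the source
procedure. A `midpoint` rule (split at the midpoint of the two means,
everyone assigned) is provided as the alternative reading. Scores are
raw means, not sign-aligned: the source observation is that long
survivors sit at low signature expression, and a sign-alignment option
would change the score's meaning, so it is off by default.

PCA is a centered SVD with explained-variance ratios. t-SNE is an exact
(O(n²)) implementation — Gaussian affinities calibrated to the target
perplexity by bisection, Student-t output kernel, momentum gradient
descent with early exaggeration (12× for 100 iterations, learning rate
200, 1000 iterations) — adequate for cohort-scale inputs. The source
method states "perplexity = N", which is infeasible (perplexity must be
below (N − 1)/3); the default here is `floor(sqrt(N))`, a standard
heuristic, and the discrepancy is intentional and documented.

## Numerical and reproducibility choices

* All randomness flows from integer master seeds through
  `derive_seed()`, a multiplicative hash spawning independent substreams
  per (design, replicate, bootstrap) so that changing `R` or `B` does
  not reshuffle unrelated stages. Derived seeds stay below 2³¹.
* Moderated t-statistics fit the prior degrees of freedom and variance
  by moments on log sample variances (trigamma inversion by Newton's
  method); with no excess dispersion the prior collapses to infinite
  degrees of freedom and the common variance. A plain Welch mode is
  provided for comparison.
* KNN imputation is feature-wise with k = 10, distances are root mean
  squared differences over mutually observed samples (per-pair
  normalization keeps unequal overlaps comparable), and features with no
  usable neighbor fall back to their own mean. Imputation never touches
  observed entries and is idempotent on complete data.
* The missingness exclusion boundary ("at least 80%") is inclusive;
  persistence and importance retention are inclusive (`≥`), interaction
  stability is strict (`>`).
* Degenerate inputs fail loudly: single-class labels, all-zero feature
  weights, rank-deficient Cox designs, constant features at
  dichotomization, equal stratification cutoffs, and perplexities
  outside the feasible range are all errors, not warnings.

## Known limitations

* The generator's independence and Gaussianity assumptions are strong;
  planted-signal recovery rates do not transfer quantitatively to real
  cohorts.
* The count-weighted importance scale makes `gini_min` n-dependent
  (documented above); cross-study comparisons of importances require
  rescaling.
* Strict permutation equivariance of importances fails at exact
  count-ties by design (reproducibility wins).
* Exact t-SNE is quadratic in samples; thousands of samples would need a
  Barnes–Hut implementation, which is out of scope.
* Parallel execution is not built in; all loops are sequential and
  seed-stable.
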