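# mirf — multiview iterative random forests for multi-omics biomarker discovery

`mirf` is for computational biologists who have two expression views on
the same patients — typically z-scored microarray gene expression and
z-scored RPPA protein expression — and a binary clinical contrast such as
short-term (OS ≤ 6 months) versus long-term (OS ≥ 2 years) survival, or
low (≤ 60) versus high (≥ 80) Karnofsky performance score. It finds
features that predict the contrast **and** the low-order signed
interactions between them, then validates candidates with survival
models and stratifies patients by signature score.

## The method

The core is an **iteratively reweighted random forest** with
**generalized Random Intersection Trees (RIT)** under three nested
bootstrap layers:

1. *Inner*: every tree grows on a bootstrap of its training set. Splits
   maximize the count-weighted Gini decrease
   `n·G(parent) − n_L·G(left) − n_R·G(right)`, `G = 1 − Σ p_k²`; split
   candidates are drawn with probability proportional to feature weights,
   which iterate K times from uniform to importance-proportional.
2. *Stability*: the training set is bootstrapped B times; each refit
   forest's class-1 root-to-leaf paths become signed itemsets
   (`+` = "feature > threshold" branch, `−` = "≤"), and RIT intersects
   randomly sampled itemsets to recover sets frequent in the positive
   class. An interaction's **stability** is the fraction of the B
   replicates recovering it.
3. *Replicates*: the whole procedure repeats on R bootstraps of the full
   dataset. Features with mean decrease in Gini impurity ≥ 1 in ≥ 50% of
   replicates are **persistent**; interactions among persistent features
   with mean stability > 0.5 are reported. Defaults: K = 5, B = 50,
   R = 100, 80/20 stratified train/test splits.

Gene, protein, and integrated (concatenated) designs are trained
separately; features recovered by a view *and* the integrated design are
cross-view consensus candidates. Validation: Kaplan–Meier curves with
log-rank tests under mean-expression dichotomization, elastic-net Cox
regression with 10-fold cross-validation maximizing Harrell's C,
univariate/multivariate Cox with backward stepwise (AIC), and
signature-score stratification with Bonferroni-corrected expression-mean
cutoffs, plus PCA/t-SNE embeddings.

A synthetic two-omics cohort generator with a planted Boolean signal
(`g1 > 0 AND (p1 > 0 OR g2 > 0)`, where protein `p1` is a ρ = 0.6 noisy
copy of gene `g1`), Weibull proportional-hazards survival, a coupled
KPS-like score and MCAR missingness provides ground truth for every
stage. See `vignettes/mirf-methods.Rmd` for models, parameters and
design rationale.

## Worked example

```r
library(mirf)

cohort <- simulate_multiomics(simulation_config(seed = 42))
#> multiview cohort: 400 samples, 150 gene + 150 protein features
#> planted features: G0001, G0002, P0001

cfg <- mirf_config(K = 3, B = 10, R = 20,
                   forest = forest_params(n_trees = 100), seed = 7)
res <- run_mirf(cohort, task = "os", config = cfg,
                designs = "integrated", labels = cohort$truth$outcome)
res
#> multiview iRF result (task: os; K=3, B=10, R=20)
#>   integrated 4 persistent feature(s), 1 selected interaction(s), mean test AUPR 0.844

head(res$designs$integrated$features, 4)
#>         feature frequency mean_importance
#> 1    gene:G0001      1.00           75.60
#> 4 protein:P0001      1.00           15.42
#> 2    gene:G0002      0.95            9.97
#> 3    gene:G0075      0.50            2.22

head(res$designs$integrated$interactions[, c("key", "mean_stability", "selected")], 3)
#>                           key mean_stability selected
#> 79 +gene:G0001,+protein:P0001           0.93     TRUE
#> 52    +gene:G0001,+gene:G0002           0.27    FALSE
#> 40 -protein:P0073,+gene:G0001           0.12    FALSE
```

All three planted features are persistent (one spurious feature,
`G0075`, sits at the 0.50 persistence boundary), and the planted
cross-view pair `(G0001+, P0001+)` is the only interaction passing the
stability > 0.5 rule, at mean stability 0.93. The test AUPR of 0.844
(95% CI 0.798–0.889) is measured on held-out samples against a class
prevalence of 0.45. Downstream:

```r
sc  <- signature_score(cohort$gene_matrix, c("G0001", "G0002"))
cls <- binarize_outcomes(cohort$clinical)$os_class
ct  <- derive_cutoffs(sc, cls)
z   <- assign_zones(sc, ct)
#> cutoffs: long -0.665 / short 0.287 (p_adj 3.6e-12); fraction assigned 0.52
```

Long survivors sit at low signature expression, so the long-zone cutoff
is the lower group mean; 52% of patients fall beyond one of the two
group means and are assigned a predicted-survival zone.

## Command line

```sh
Rscript -e 'mirf::mirf_cli()' simulate --config cfg.json --seed 1 --out data/
Rscript -e 'mirf::mirf_cli()' train --expr data/gene_expression.tsv \
    --prot data/protein_expression.tsv --clin data/clinical.tsv \
    --task os --views gene,protein,integrated --config train.json --out run/
```

Subcommands: `simulate`, `preprocess`, `train`, `survival`, `stratify`.
Config files are JSON.

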