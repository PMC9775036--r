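# dfsc — semi-supervised deep survival forests for high-dimensional prognosis

`dfsc` predicts patient survival from high-dimensional gene-expression
profiles (p ≫ n) and ranks the genes driving the prediction. It is aimed
at computational biologists and biostatisticians working with cohorts
where expression is cheap but outcome labels are scarce — part of every
cohort is typically unlabeled.

At its core is a **deep survival forest cascade**: stacked levels of
survival-forest ensembles (half log-rank forests, half completely-random
forests for diversity) where each level's out-of-fold predictions augment
the next level's inputs, and an elastic-net Cox model links each level's
augmented features to a risk score. Under proportional hazards,

    h(t | x) = h0(t) · exp(η(x)),

with η(x) the final level's Cox linear predictor, fitted by the Breslow
partial likelihood; survival curves come from the Breslow baseline,
S(t | x) = exp(−H0(t)·e^η). Levels are grown while a held-out validation
concordance improves.

Unlabeled samples are used by a **teacher–student loop**: a cascade fitted
on labeled data imputes each unlabeled sample's median survival time,
soft risk-class distributions are formed by temperature-scaled softmax
over risk bins, and only confident pseudo-labels (max soft probability ≥
a gate) join the student's training data. The round with the best labeled
validation concordance is returned, so the result never falls below the
supervised fit on that criterion.

The package also provides **stable-LASSO gene ranking** (selection
frequency of each gene across 100 subsampled L1-penalized Cox fits, with
univariate Wald p-values), censoring-aware evaluation (Harrell C-index,
IPCW-weighted integrated Brier score, event-stratified k-fold
cross-validation with paired model comparison), and a **synthetic cohort
generator** with known ground truth — block-correlated expression, sparse
proportional-hazards signal, tunable censoring and labeled / unlabeled /
test partitions, including presets matching common TCGA cohort split
designs (e.g. PAAD 65/61/50).

## Worked example

```r
library(dfsc)

sim   <- generate_survival_data(generator_config(n_samples = 300,
                                                 n_genes = 1000,
                                                 random_seed = 42))
parts <- partition_subsets(sim)           # labeled / unlabeled / test

cfg   <- cascade_config(n_trees_per_forest = 50, max_levels = 2,
                        random_seed = 42)
model <- fit_dfsc(parts$labeled, parts$unlabeled, cfg,
                  distillation_config(random_seed = 42))
model
#> cascade_model: 1 level(s), 1000 genes, validation C-index 0.830

model$dfsc$history
#>   round n_pseudo val_cindex distill_loss
#> 1     0        0  0.8297872           NA
#> 2     1        9  0.8244681     0.431172

risk <- cascade_predict_risk(model, parts$test$X)
concordance_index(parts$test$time, parts$test$event, risk)
#> [1] 0.807
```

The loop fitted a supervised cascade (round 0, validation C-index 0.830),
accepted 9 confident pseudo-labels in round 1, and kept the round-0 model
because the student did not improve validation concordance. On held-out
test samples the model ranks survival with C-index 0.807 (0.5 = random;
the true-risk oracle on this cohort sits near 0.89).

Gene ranking on the same cohort:

```r
genes <- stability_select(labeled_subset(sim$dataset),
                          stability_config(n_subsamples = 100,
                                           random_seed = 42))
head(as.data.frame(genes), 5)
#>   gene_symbol stable_score      p_value   p_adjusted
#> 1       g0008            1 2.128607e-02 2.356257e-02
#> 2       g0177            1 4.317258e-10 8.634516e-09
#> 3       g0359            1 1.390880e-07 1.390880e-06
#> 4       g0555            1 7.891547e-06 3.156619e-05
#> 5       g0580            1 5.192104e-06 2.596052e-05
```

All five are truly causal genes of the simulation (10 of 10 land in the
top 20 with stable score 1.00); a stable score near 1 means the gene is
selected in essentially every subsample.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/dfsc.R simulate --preset PAAD --seed 1 --out-dir sim/
Rscript inst/cli/dfsc.R fit --expr sim/expr.tsv --clinical sim/clinical.tsv \
        --unlabeled-ok --out model.rds
Rscript inst/cli/dfsc.R select-genes --expr sim/expr.tsv --clinical sim/clinical.tsv \
        --top-k 20 --out report.tsv
Rscript inst/cli/dfsc.R evaluate --expr sim/expr.tsv --clinical sim/clinical.tsv \
        --models cascade,lasso_cox,rsf --folds 5 --seed 7 --out eval.tsv
```

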