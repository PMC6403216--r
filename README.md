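# codelcnn

Detection of **1p/19q co-deletion** — the defining molecular lesion of
oligodendroglioma — from targeted next-generation-sequencing copy-number
profiles, with a two-branch **ensemble 1D convolutional neural network**
and a deterministic rule-based arm caller.

## Who this is for

Molecular pathology and neuro-oncology bioinformatics groups that already
run a targeted cancer gene panel and want arm-level structural-variant
calls (specifically whole-arm 1p and 19q loss) out of the per-bin log2
copy-ratio tables their CNV pipeline (e.g. CNVkit) produces — plus the
ability to score SNP-array cohorts with the same model after
cross-platform harmonization.

## What it computes

Each sample's chromosomes 1 and 19 are summarized as fixed-length ordered
log2 vectors, `x1 ∈ R^1869` and `x2 ∈ R^649` (dense array profiles are
reduced to those lengths by contiguous group averaging). A two-branch
CNN — per-branch convolutional pretraining blocks, three residual block
families executed over 10 iterations, global-average-pool + dense bridge
to 1024 features per branch — concatenates 2048 features into a softmax
head producing

    P(X ∈ class1) = P(1p/19q co-deletion),   P(X ∈ class2) = 1 - P(X ∈ class1).

Class imbalance is handled by a from-scratch **SMOTE** (synthetic minority
samples `p + u(q - p)` toward k = 5 nearest minority neighbors on the
concatenated feature vector). Classifiers are evaluated with ROC/**AUC**
(verified against the Mann-Whitney pair statistic) and an operating
cutoff chosen by maximizing the **Youden index** J = sensitivity +
specificity - 1. Independently, a rule-based caller declares an arm
deleted iff ≥ 90% of smoothed in-region bins (chr1:1-125,000,000 /
chr19:26,500,001-59,128,983, hg19) sit at or below log2 = -0.2 with no
long copy-neutral run — so partial segmental loss is negative — and FISH
nucleus counts are interpreted with the combined criteria (target:control
ratio < 0.75, or > 50% of nuclei with ≤ 1 target signal).

The network engine (conv1d, max pooling, residual blocks, Adam, softmax
cross-entropy) is implemented natively in RcppArmadillo; no deep-learning
framework is required. A built-in simulator generates labeled synthetic
panel/array cohorts (arm shifts attenuated by tumor purity, partial
deletions, per-bin noise) for testing and demonstration.

## Worked example

```r
library(codelcnn)

# a labeled synthetic cohort: 19 co-deleted vs 42 controls
ds <- simulate_dataset(sim_config(n_codel = 19, n_control = 42,
                                  purity_range = c(0.8, 1), seed = 101))
feats <- featurize_profiles(ds$profiles, ds$truths$label)

# SMOTE-balance and train the default ensemble
bal <- balance_features(feats, seed = 202)
table(bal$label)
#>    codel no_codel
#>       42       42

model <- build_ensemble(ensemble_config(), seed = 303)
model
#> <codel_ensemble>
#>   inputs: chr1 1869, chr19 649
#>   branch1 pretrain out: 150 x 64; stack out: 150 x 512
#>   branch2 pretrain out: 25 x 64; stack out: 25 x 512
#>   features: 1024 per branch -> 2048 concatenated -> 2 classes
#>   parameters: 6,914,370; trained: no

fit <- train_ensemble(model, bal, train_config(seed = 404))

# held-out evaluation
te <- simulate_dataset(sim_config(n_codel = 30, n_control = 30,
                                  purity_range = c(0.8, 1), seed = 505))
ev <- evaluate_model(fit, featurize_profiles(te$profiles, te$truths$label))
sprintf("AUC = %.4f; cutoff %.4f; sens %.3f; spec %.3f",
        ev$auc, ev$cutoff, ev$sensitivity, ev$specificity)
#> "AUC = 1.0000; cutoff 1.0000; sens 1.000; spec 1.000"
```

An AUC of 1.0 on this held-out synthetic set means the classifier
perfectly ranks co-deleted above non-co-deleted samples in a world of
clean arm-level shifts (log2 -0.6 at purity 0.8-1.0, per-bin noise sd
0.15); see the methods vignette for what that does and does not
establish. The rule-based caller agrees with simulator truth on the same
world:

```r
calls <- do.call(rbind, lapply(ds$profiles, call_sample))
all(calls$codeletion == ds$truths$codeletion)
#> TRUE
```

## Command line

```sh
Rscript inst/scripts/codelcnn simulate  --out sim/ --seed 1
Rscript inst/scripts/codelcnn call      --profiles sim/ --out calls.tsv
Rscript inst/scripts/codelcnn featurize --profiles sim/ --labels sim/labels.tsv --out features.tsv
Rscript inst/scripts/codelcnn train     --features features.tsv --out model.rds
Rscript inst/scripts/codelcnn evaluate  --model model.rds --features features.tsv --out report.tsv
```

`reformat` is `featurize` defaulting to the array-probe dialect. All
defaults live in one JSON config (`--config`, see `pipeline_config()`);
every run writes a manifest with the config, seeds and package version.

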