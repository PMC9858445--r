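# siamfcn

Few-shot Siamese similarity learning for classifying subjects from
resting-state fMRI functional connectomes pooled across heterogeneous
imaging sites.

## The problem

Multi-site RS-fMRI cohorts (different scanners, acquisition protocols)
are systematically heterogeneous: a classifier trained by pooling all
sites tends to generalize poorly to a site it has never seen. `siamfcn`
addresses this for two-group diagnosis (ASD vs. typically developing
controls, NC) by learning a *similarity function* instead of a direct
decision boundary, and by anchoring every comparison to one designated
**baseline site**, so that a new site can be adopted with only a handful
of labelled subjects.

## The method

1. **Dynamic functional connectivity features.** Each subject's
   ROI-averaged BOLD matrix (T timepoints × R regions) is cut into
   overlapping sliding windows of length *M* and stride *s*. Window *k*
   yields a sub-network `D(k)` whose entry *(i, j)* is the Pearson
   correlation of regions *i* and *j* within the window. The mean of
   the `K = floor((T − M)/s) + 1` sub-networks is vectorized over its
   upper triangle into an `R(R−1)/2`-dimensional feature vector
   (6,670 features for the 116-region AAL parcellation).
2. **Siamese similarity network.** A single shared encoder *f* (an
   autoencoder-style MLP followed by fully connected layers) embeds both
   members of a pair; their similarity score is
   `sigma(||f(x1) − f(x2)||_1)`, trained with the mean-squared pair loss
   `L = 1/2 (out − y)^2`, where `y = 0` for a same-group pair and
   `y = 1` otherwise.
3. **Baseline-site prototypes, summed per-site loss.** The class
   prototypes are the mean embeddings of the baseline site's NC and ASD
   subjects. Each training site contributes an independent loss (its
   meta-training subjects paired against both prototypes) and the total
   objective is the plain sum `L_total = sum_k L_k` over the K training
   sites, which keeps any single site from dominating. Each site's held
   out meta-test split (30%) monitors generalization but never updates
   parameters.
4. **Target-site protocol.** An unseen site is balanced, a few support
   subjects per class fine-tune the model against the baseline
   prototypes, and the remaining query subjects are labelled by
   prototype matching (smaller similarity output = more similar;
   exact ties go to ASD). Accuracy, precision and F1 are reported with
   ASD as the positive class.

Because public imaging data cannot ship with the package, a synthetic
multi-site generator (`sim_config()`, `simulate_cohort()`) produces
labelled BOLD cohorts with a controllable group effect (a correlation
shift on a fixed edge set) and site heterogeneity (per-site edge
perturbations shared by both groups), so every stage is testable end to
end.

## Worked example

```r
library(siamfcn)

cfg <- benchmark_config(seed = 1)   # 7 synthetic sites, R = 20, T = 150
res <- run_pipeline(cfg$sim, cfg$run)

res$fit
#> <siamese_fit> baseline SITE04, 4 training sites, 300 steps; final total loss 0.2731

round(res$meta_test, 1)             # meta-test accuracy (%) per training site
#> SITE00 SITE01 SITE02 SITE03
#>    100    100    100    100

res$metrics$SITE05[c("accuracy", "precision", "f1", "n")]
#> $accuracy [1] 100   $precision [1] 100   $f1 [1] 100   $n [1] 30
```

The benchmark's group effect (0.4 on 20 of 190 edges) is strong enough
that the trained model separates the groups essentially perfectly on
held-out subjects of the training sites *and* on the two sites it never
saw; with the group effect set to zero (`benchmark_config(seed,
delta = 0)`) the same pipeline sits at chance (~50%), confirming the
signal is real rather than leaked.

Individual stages are exposed both as functions
(`simulate_cohort()`, `features_for_manifest()`, `train_siamese()`,
`evaluate_target_sites()`) and as CLI subcommands
(`inst/cli/siamfcn simulate|features|train|evaluate`).

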