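---
title: "Similarity-based few-shot classification of multi-site functional connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity-based few-shot classification of multi-site functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Motivation and model

Resting-state fMRI cohorts assembled from several imaging sites are the
practical route to adequate sample sizes for psychiatric classification,
but scanners and protocols shift each site's feature distribution. A
classifier that pools sites learns those shifts as if they were
biology; a classifier trained on one site does not transfer. `siamfcn`
implements a metric-learning answer: learn how *similar* two subjects'
connectomes are, always comparing against one fixed **baseline site**,
and let every other site (during training) or a few labelled subjects
(on a new site) calibrate that comparison.

The pipeline has three stages.

**Features.** For a subject with BOLD matrix $X \in \mathbb{R}^{T
\times R}$ (T timepoints, R regions), sliding windows of length $M$ and
stride $s$ give $K = \lfloor (T-M)/s \rfloor + 1$ segments; trailing
timepoints that cannot fill a window are dropped, never padded, because
the windowed correlation is defined over exactly $M$ samples. Window
$k$ produces the sub-network $D^{(k)}_{ij} = \mathrm{corr}(x_i^{(k)},
x_j^{(k)})$ (Pearson). The elementwise mean $\bar D$ over windows is
the subject's connectivity matrix, and its strict upper triangle in
row-major $(i<j)$ order is the feature vector of length $R(R-1)/2$ —
6,670 entries for the 116-region AAL parcellation.

**Similarity network.** One shared encoder $f_\theta$ (there is a
single parameter set; the "twin branches" are the same function) embeds
a feature vector through an autoencoder-half MLP and fully connected
layers into $\mathbb{R}^d$. A pair $(x_1, x_2)$ is scored by
$\mathrm{out} = \sigma(\lVert f(x_1) - f(x_2) \rVert_1)$ and trained
with $L = \tfrac12(\mathrm{out} - y)^2$, $y = 0$ for same-group pairs
and $1$ otherwise. Training pairs every meta-training subject of every
training site with both baseline prototypes — the class-wise mean
embeddings of the baseline site's NC and ASD subjects — giving one
$y=0$ and one $y=1$ pair per subject and hence balanced pair labels by
construction. Site $k$'s loss is the mean over its $2n_k$ pairs, and
the objective is the unweighted sum $L_{\mathrm{total}} = \sum_k L_k$:
a sum over equally weighted sites rather than a pooled mean over pairs,
so small sites are not drowned out and the optimizer must keep all
sites' losses low simultaneously. Prototypes are recomputed from the
current parameters at every gradient step (gradients flow through them
into the baseline embeddings); the package enforces this with a model
version stamp, and stale prototypes are a hard error.

**Evaluation.** Each training site is split 70/30 (stratified by label,
seeded) into meta-training and meta-test; meta-test subjects are only
ever forwarded through the network, never differentiated through. An
unseen target site is balanced by seeded down-sampling of the larger
class, a small support set (default 5 subjects per class) fine-tunes a
fresh copy of the model for a few steps against the baseline
prototypes, and the remaining query subjects are classified by
prototype matching: predict NC when the similarity output against the
NC prototype is strictly smaller (smaller = more similar), ASD on exact
ties. Metrics are accuracy, precision and F1 with ASD as the positive
class — the usual diagnostic convention; the package reports this
choice in every metrics file.

## The sigmoid range and the loss target

Over non-negative L1 distances the plain sigmoid spans $[0.5, 1)$, so
the $y=0$ target of the pair loss is not literally reachable: a
perfectly matched pair scores $0.5$, not $0$. We keep this literal
mapping as the default because the training signal still points the
right way (same-group distances are driven toward 0, different-group
distances upward) and classification is an argmin over the two outputs,
which is unaffected by the common offset. For users who want the full
$(0,1)$ range, `head_mode = "affine"` scores pairs with
$\sigma(a \cdot \mathrm{dist} + b)$ and learns $a, b$ jointly with the
network. Relatedly, the pair loss is applied to the sigmoid *output*,
not the raw distance: that is the reading consistent with binary
targets $y \in \{0,1\}$ and a score bounded in $(0,1)$; the raw
distance would make the $y$ values arbitrary scale anchors.

Whether the "autoencoder" part of the encoder should carry an explicit
reconstruction objective is equally open; the package implements a
mirrored decoder and a weighted reconstruction penalty
(`recon_weight`), but the default is 0 — an encoder-shaped MLP with no
reconstruction term — because nothing in the training objective
requires it. Both code paths are exercised by the gradient tests.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `window_length` (M) | 30 timepoints | sliding-window length; common dynamic-FC practice, not canonical |
| `window_stride` (s) | 1 timepoint | window advance; maximal overlap |
| `encoder_widths` | 512, 128 | autoencoder-half widths (for 6,670-dim input) |
| `embedding_dim` | 64 | dimension of the L1-compared embedding |
| `activation` | relu | hidden nonlinearity (`tanh` available) |
| `learning_rate` | 1e-3 | full-batch SGD step size |
| `n_iterations` | 500 | training steps |
| `meta_train_fraction` | 0.7 | within-site meta-train share |
| `fine_tune_shots_per_class` | 5 | labelled target-site support subjects per class |
| `fine_tune_steps` | 50 | fine-tuning gradient steps |
| `fisher_z` | off | optional atanh transform of correlations |

Sites are small (tens of subjects), so training is plain full-batch
gradient descent; all randomness (splits, balancing, support sampling,
initialization) flows from one run seed through named substreams, which
makes every run bit-reproducible and lets stages be re-run
independently without perturbing each other.

The bundled reference benchmark (`benchmark_config()`) scales the
architecture to its 190-dimensional feature vector (widths 64–32,
embedding 16) and uses a larger step size (0.05) for 300 iterations —
with the mean-squared sigmoid loss, gradients are bounded by
$\tfrac14\lvert\mathrm{out}-y\rvert$ per pair, and at 1e-3 the
desk-scale problem would still be descending long after its loss shape
has stabilized at 0.05. These are optimizer settings for the reference
problem, not method constants; both are plain `run_config()` fields.

## The synthetic cohort generator

No public imaging data ships with the package, so the generator
produces the study conditions directly at the level the pipeline
measures: latent correlation matrices. Every (site, group) cell gets a
target correlation matrix assembled from

* a **shared base** — a random low-rank factor-model correlation
  matrix, fixed by the seed, playing the role of the functional
  architecture common to all humans;
* a **group effect** — `delta` added to a fixed, seed-chosen set of
  `n_affected_edges` edges, ASD cells only (disease-specific
  dysconnectivity on a sparse edge set);
* a **site effect** — i.i.d. Gaussian offsets (SD `site_effect_sd`) on
  *every* edge, drawn once per site and shared by both groups, the
  signature of a scanner/protocol shift that moves a whole site
  coherently.

The sum is clamped to $[-0.99, 0.99]$ off-diagonal and repaired to a
valid correlation matrix by clipping eigenvalues at $10^{-6}$,
reconstructing, and re-normalizing to unit diagonal — deterministic and
standard, at the cost of slightly attenuating large effects. Subjects
are i.i.d. draws of $T$ timepoints from a zero-mean Gaussian with that
correlation, plus independent observation noise (SD `noise_sd`), which
attenuates observed correlations by $1/(1 + \mathrm{noise\_sd}^2)$ — a
property the tests verify rather than assume.

Defaults (7 sites × 20 subjects per group, R = 20, T = 150,
delta = 0.4 on 20 of 190 edges, site SD 0.1, noise SD 0.3) are chosen
as a desk-scale cohort with a strong, sparse group effect and moderate
heterogeneity: per-edge sampling error at T = 150 is about 0.08, so
affected edges carry roughly a 4–5 SD signal while site offsets
(SD 0.1) are of the same order as the noise on every edge. R = 20
rather than 116 keeps test runtimes in seconds; the 116-region feature
dimension itself (6,670) is exercised separately.

What the generator deliberately does **not** emulate: hemodynamic
autocorrelation, motion and physiological artifacts, age/sex structure,
unequal site sizes, missing scans, and non-Gaussian marginals. Passing
the synthetic benchmark therefore demonstrates that the machinery —
features, objective, protocol, bookkeeping — behaves as specified, not
that any particular accuracy will be attained on real cohorts; on the
benchmark the signal is strong enough that trained accuracy saturates
near 100%, whereas real-data regimes are far noisier.

## Numerical conventions and degenerate inputs

* **Zero-variance windows.** Pearson is undefined for a constant
  signal; the correlation is reported as 0 with a warning instead of
  propagating NaN into the mean matrix — a constant segment carries no
  correlation evidence either way.
* **Standardization.** Features are z-scored per dimension before the
  encoder, using statistics from the *training sites' meta-training
  subjects only* (stored in the checkpoint). L1 distances are scale
  sensitive; without this, high-variance edges dominate the metric.
  Target sites are standardized with the stored statistics — no
  target-site leakage.
* **Split/rounding rule.** Per class, `round(fraction * n)` subjects
  (half-up) go to meta-train, the remainder to meta-test; a class with
  fewer than 2 subjects cannot be stratified and errors out.
* **Tie-breaks.** Equal similarity outputs classify as ASD,
  deterministically.
* **Zero-denominator metrics.** Precision is 0 when there are no
  positive predictions, F1 is 0 when precision + recall is 0; both are
  warned about, since small balanced target sites can reach these
  states.
* **Fine-tuning** updates all parameters (no freezing) and recomputes
  baseline prototypes after every step, including after target-site
  fine-tuning; the input model object is never mutated. Support
  subjects are excluded from every reported metric, enforced by an id
  audit.
* **Divergence** (non-finite loss) aborts training with a diagnostic
  rather than returning a broken model.

## Test problem sizes

Unit tests run on cohorts of 4–7 sites, 6–20 subjects per site per
group, R = 10–20, T = 60–150; Monte-Carlo checks of the simulator use
T = 5000 at R ≤ 5. Gradient correctness is verified against central
finite differences (including the affine head and the reconstruction
path), and the windowed-correlation pipeline against a loop-based
textbook oracle at tolerance 1e-12. Multi-seed behavioural checks (null
calibration at chance, signal recovery, fine-tuning benefit,
heterogeneity monotonicity, advantage over site-blind pooling) use 10
seeds each.

## Known limitations

* Full-batch SGD with a fixed step size is adequate for tens of
  subjects per site but would need mini-batching and an adaptive
  optimizer for cohorts orders of magnitude larger.
* The literal sigmoid head compresses all well-separated pairs toward
  output 1; the affine head is preferable when the absolute similarity
  score (rather than the argmin decision) matters.
* Window length and stride are genuinely free parameters of dynamic-FC
  feature extraction; results on real data can be sensitive to them,
  and the package makes no attempt to select them automatically.
* The baseline site is an input, not an estimate. The
  `baseline_sweep()` helper reruns training over candidate baselines
  and reports meta-test accuracy so the choice can be made empirically.
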