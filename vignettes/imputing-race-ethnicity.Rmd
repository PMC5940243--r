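---
title: "Imputing race and ethnicity from EMR disease histories: model, interpretation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputing race and ethnicity from EMR disease histories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emrimpute)
```

## The imputation problem

Anonymized EMR extracts describe each patient as a variable-length list of
ICD9 codes plus basic demographics, and frequently omit race and ethnicity.
`emrimpute` treats the missing label as a four-class supervised target
(Other, White, Hispanic, Black) and estimates a posterior over the classes
from everything the anonymized record retains. The posterior can be used
directly (pick the maximum-probability class) or as the plausible-value
distribution in a multiple-imputation workflow.

Two properties of the data shape every design choice below: the feature
matrix is **binary and sparse** (a typical patient exhibits a handful of
the ~10³–10⁴ distinct codes), and the class distribution is **strongly
unbalanced** (the majority class alone covers roughly half of a large
urban cohort).

## Data model and encoding

A patient record is `(id, class, age, gender, {codes})`. Onset ages
attached to codes are discarded; continuous ages are floored to integer
years and each observed integer age becomes its own binary feature
(`age_47`), as does each of the five gender levels (`gender_female`, ...)
and each ICD9 code. No minimum-frequency filter is applied to codes: the
vocabulary is exactly what the training corpus exhibits. Column order is
deterministic — gender, then ages ascending, then codes in byte order — so
encodings are reproducible regardless of record order, and encoding is
batch-invariant (any row partition, encoded separately and stacked, equals
the one-shot encoding; this is tested as a property).

Codes met only at prediction time have no column; they are dropped and
counted (`n_unseen`), the only choice that preserves the trained model's
input shape.

## The classifier

The network is a fully-connected MLP: input F → hidden layers (default two)
→ softmax over 4 classes. Tunable parameters, defaults, and why:

| parameter | default | notes |
|---|---|---|
| `hidden_dims` | 512, 512 (full scale); 64, 64 in the pipeline | width buys capacity; the desk-scale default saturates the synthetic generator's Bayes ceiling |
| `activation` | PReLU, α₀ = 0.25 | one learned slope per hidden layer; ReLU is the α = 0 special case. 0.25 is the initialization proposed with the PReLU unit |
| `dropout_rate` | 0.5 (spec default); 0.2 in the pipeline | inverted dropout on hidden activations, train-time only; small networks need less regularization |
| `learning_rate` | 10⁻³ | Adam step; moment decays 0.9/0.999 and ε = 10⁻⁸ are the standard published defaults |
| `batch_size` | 128 | unremarkable; configurable |
| `patience` | 5 | epochs of non-improving validation loss permitted before stopping; the next one halts training |

Weights are initialized with seeded fan-in variance scaling
(N(0, √(2/fan_in))), the standard choice for rectifier networks; biases
start at zero. Training minimizes categorical cross-entropy; the weights
from the epoch with minimal validation loss are cached and returned, so the
returned model always attains the recorded minimum (asserted from the
history in the tests). A non-finite loss aborts with a diagnostic rather
than silently continuing. `random_grid_search()` draws activation, dropout,
log-uniform learning rate and batch size, trains each candidate briefly on
a tuning subsample (at most 10,000 validation samples, 80/20 split) and
returns the minimal-validation-loss draw, ties to the earliest.

Cross-validation uses k shuffled folds whose sizes differ by at most one;
the k test folds tile the cohort, so every patient is predicted (and later
explained) exactly once. About 10% of each training split is held out for
early stopping and tuning. In the pipeline, hyperparameter search runs once
on the first fold and the winning configuration is reused: the architecture
is fixed across folds before training.

## Missing-data simulation

`mask_observations()` deletes each observed feature value (each 1-entry)
independently with probability 0.1–0.3, leaving the feature columns
themselves intact — missing *observations*, not missing *features* — which
is the MCAR regime. Demographics are eligible for masking by default, since
an anonymized extract can lose any observation; `protect_demographics`
restricts masking to ICD9 columns. Masking applies to train, validation and
test alike, emulating a uniformly deficient extract.

## DeepLIFT interpretation

For a trained network, DeepLIFT decomposes each output's
difference-from-reference Δt into per-input contributions obeying
summation-to-delta: Σᵢ C[i,t] = Δt. The input reference is the all-zeros
vector — the natural baseline for sparse binary encodings, "no observed
disease, reference demographics" — and hidden/output references are its
forward pass. (A population-incidence reference is a defensible
alternative; `compute_references()` accepts a custom vector but zeros are
the default.) Affine layers use the linear rule; rectifiers use the rescale
rule, multiplier Δout/Δin, with a degenerate-case fallback when
|Δin| ≤ ε = 10⁻⁷: the activation's derivative at the reference (1 on the
active side, α otherwise), which is the rule's continuous limit and keeps
summation-to-delta intact. Dropout is identity at interpretation time.

Scores target the **pre-softmax logits** by default: softmax saturation
makes probability-scale multipliers collapse toward zero for confident
samples, which would let a handful of uncertain samples dominate aggregate
scores. With `target_layer = "probabilities"` each class column is rescaled
by Δp_t/Δlogit_t (fallback p_ref(1−p_ref)), preserving summation-to-delta
on the probability scale for users who want probability-denominated scores.

Per-sample matrices are summed over all test samples of a fold and then
across the k folds, mirroring the cross-validation structure, and each
feature's four aggregate scores are sorted (descending) into a class
ordering; ties break by the canonical class order (Other, White, Hispanic,
Black) for determinism. Features are ranked by score *range* — max minus
min — which measures discriminative ability. Frequency-based orderings
(mean-centered per-class presence counts) are provided for contrast; they
agree with DeepLIFT orderings on deterministic markers but can legitimately
differ elsewhere, which is exactly the point of a model-based attribution.

Three exactness properties pin the implementation down: summation-to-delta
to 10⁻⁵ relative tolerance on every sample (in practice ~10⁻¹²); equality
with the closed-form weight-product decomposition on identity-activation
networks (α = 1); and, when a single feature differs from reference, the
feature's score equals the network's actual output change when that feature
is toggled.

## The synthetic cohort generator

Real EMR extracts of this kind are private, so the generator emulates their
structure with a known ground truth: classes drawn from unbalanced priors
(0.532 / 0.187 / 0.155 / 0.126 — a realistic two-city urban composition);
**marker** features, Bernoulli with elevated prevalence in one target class
(default: 8 markers, two per class, 0.60 in-target vs 0.05 elsewhere);
~10² ICD9-style **background** features at a uniform 5% prevalence; ages
from a discretized bell (18–90, mean 45, sd 16) and a gender mix dominated
by male/female — both class-independent. Features are conditionally
independent given class, so the Bayes-optimal accuracy is computable
exactly by enumerating marker patterns (≤ 20 informative bits), giving
every classifier test an analytic ceiling.

**Interaction mode** plants feature *pairs* whose agreement (both present
or both absent) is class-informative while each member's marginal
prevalence is 0.5 in every class: a main-effects logistic regression sees
nothing, an MLP can learn the pairing. This operationalizes the claim that
the network exploits non-linear, non-frequentist structure, at desk scale.

What the generator does **not** emulate: disease co-occurrence structure,
longitudinal onset ages, coding noise, site effects, and the real feature
count (~15,000). Passing tests therefore demonstrate correctness of the
machinery and recoverability of planted structure — not clinical-scale
performance numbers, which require the private data.

## Problem sizes and numerical choices

Desk-scale experiments use a 20,000-patient default cohort with k = 3
folds and hidden layers of 64 (marker recovery, ceiling comparison), a
6,000-patient cohort for the masking-rate sweep, and 3,000-patient cohorts
for the interaction comparisons — sizes at which the MLP reaches the Bayes
ceiling within ~1–2 accuracy points in seconds per fold on one CPU, and
results are stable across seeds. Other numerical conventions:

- probabilities are clipped to [10⁻¹⁵, 1] inside the cross-entropy;
- argmax prediction ties resolve to the lowest class index;
- per-class precision/recall/F1 define 0/0 as 0; single-class AUCs are `NA`
  and excluded from averages;
- "macro-average AUC" is reported in two flavors: `macro_weighted_auc`
  (per-class AUCs weighted by class support — the convention used in the
  evaluation tables this suite mirrors) and the conventional unweighted
  `macro_unweighted_auc`, under distinct names to avoid ambiguity;
- the micro-average AUC pools all (sample, class) pairs into one binary
  problem rather than averaging one-vs-rest AUCs, following the "all cases
  considered as binary" definition;
- paired t-tests compare methods fold-by-fold with Bonferroni adjustment;
  identical score vectors give p = 1, and a nonzero zero-variance
  difference is flagged degenerate (p reported as its limit, 0);
- all randomness flows from explicit integer seeds; one master seed derives
  per-stage seeds by hashing stage labels, so stages are independently
  reproducible.

## Limitations

- Training is plain R matrix code: ample for 10⁴–10⁵ patients with a few
  hundred features, not for 10⁶ patients with 15,000 features on a laptop.
- The Bayes ceiling requires conditional independence given class and at
  most 20 informative bits; it is a property of the generator, not of real
  data.
- Imputation quality on real cohorts depends on label quality of the
  training subset and on the MCAR assumption of the masking simulation;
  missing-at-random and missing-not-at-random regimes are out of scope.
- Baselines are thin adapters over nnet/ranger/xgboost with light default
  hyperparameters; they are comparison points, not tuned competitors.
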