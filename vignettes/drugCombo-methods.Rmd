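---
title: "Predicting effective drug combinations: model, features and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting effective drug combinations: model, features and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugCombo)
```

## The problem

Many diseases respond better to a pair of drugs than to either drug alone,
but the space of candidate pairs is quadratic in the pharmacopoeia and wet-lab
screening cannot cover it. drugCombo frames pair screening as binary
classification: encode an unordered drug pair \((d_1, d_2)\) as a numeric
vector built from three kinds of evidence, rank the features, and train a
small random-forest classifier on known effective pairs (positives) against
randomly sampled pairs (negatives).

The benchmark shape the package reproduces by default is 169 drugs, 121
approved positive combinations, and 605 (five per positive) random negative
pairs drawn from the remaining \(\binom{169}{2} - 121 = 14{,}075\)
candidates.

## The feature encoding

Each pair becomes a vector of \(7 + 2P\) non-negative features (465 when
\(P = 229\) pathways), every one a symmetric function of the two drugs:

1. **Chemical interaction (1 feature).** The pair's interaction confidence
   score \(Q_c(d_1, d_2)\) from a STITCH-style chemical-chemical table, on
   its raw 0–999 database scale. Absent pairs score exactly 0; this
   zero-default convention applies to every score lookup in the package.
2. **Cross-target protein interactions (2 features).** With target sets
   \(T(d_1)\), \(T(d_2)\), the max and mean of \(Q_p(t_1, t_2)\) over all
   cross pairs. When the drugs share a target, the identical-protein pair is
   excluded (a protein's interaction with itself is undefined in the source
   databases) and the mean divides by the number of evaluated pairs.
3. **Within-target-group interactions (4 features).** For each drug,
   \(v^1\) = max and \(v^2\) = mean of scores over unordered pairs within
   its own target set; the pair contributes the order-free combinations
   \(v^1_1 + v^1_2\), \(v^2_1 + v^2_2\), \(|v^1_1 - v^1_2|\),
   \(|v^2_1 - v^2_2|\). A singleton target set has no within pairs and
   scores \((0, 0)\), consistent with the zero-default convention.
4. **Pathway enrichment (\(2P\) features).** Per drug and pathway, the
   enrichment score is \(-\log_{10}\) of the upper-tail hypergeometric
   probability of the overlap between the drug's *network-expanded* target
   set (targets plus their direct interaction neighbours) and the pathway's
   gene set. The pair contributes \(e^j_1 + e^j_2\) and \(|e^j_1 - e^j_2|\)
   for every pathway \(j\), in a fixed lexicographic pathway order.

### The enrichment model

For a universe of \(N\) genes, a pathway of \(M\) genes, an expanded gene
set of size \(n\) and an overlap of \(m\), the score is

\[
\mathrm{score} = -\log_{10} \; P[X \ge m], \qquad
X \sim \mathrm{Hypergeometric}(N, M, n),
\]

implemented as the survival function at \(m - 1\) (`stats::phyper`) rather
than naive summation, for numerical stability; the naive summation is kept
in the test suite as the independent oracle. Conventions fixed here:

* \(m = 0\) scores exactly 0 (the tail probability is 1); the tail is
  clamped to \([0, 1]\) so accumulation error can never produce a negative
  score.
* Scores are capped at **300**: tail probabilities below \(10^{-300}\)
  saturate at the double-precision underflow floor.
* The universe is used only through the count \(N\) (default 20,000 for a
  human-sized genome); when a universe membership list is supplied, gene
  sets and pathways are intersected with it first.
* "Direct neighbour" means any stored interaction score strictly greater
  than the `neighbor_threshold` (default 0, i.e. any positive stored score);
  a stricter cutoff (e.g. 400 on the STRING scale) is a configuration knob.

## Feature ranking: mRMR

Features are discretized into three states at mean \(\pm\) one sample
standard deviation (\(-1\), 0, \(+1\); constant columns become all 0), and
mutual information (plug-in estimate, bits) measures both relevance to the
label and redundancy between features. Two orderings are produced:

* **MaxRel**: non-increasing MI with the label.
* **mRMR**: greedy; each step picks the feature maximizing
  \(\mathrm{rel}(f) - \frac{1}{|S|}\sum_{s \in S} \mathrm{MI}(f, s)\)
  (the MID objective, the classic mRMR program's default). The quotient
  variant (MIQ) is available via `variant = "miq"`.

Ties break toward the lower original column index everywhere, so both lists
are fully deterministic. Relevance is computed once on the full dataset (the
feature lists are global, not per-fold); the resulting selection bias is a
documented property of this workflow, not an accident — see the README.

Note that the mean-±-sd discretizer maps any *balanced* two-point column to
a constant: a perfectly balanced binary feature carries no relevance under
this rule. The benchmark's features are continuous scores, and its labels
are imbalanced (1:5), so this edge case does not arise in practice; it is
stated here because it matters when composing toy examples.

## Classifier and evaluation

The classifier is the classic small random forest: 10 trees, each grown
without pruning on a bootstrap sample of the training rows, with
\(\lfloor \log_2 M \rfloor + 1\) random candidate features per node (Gini
splits), majority vote across trees. The per-row score for ROC purposes is
the fraction of trees voting positive (11 discrete levels at 10 trees). The
vote tie (5–5) predicts negative, the majority class under the benchmark's
1:5 imbalance. Out-of-bag error is computed and reported but never used for
selection. No R random-forest package is available in the target
environment, so the forest is implemented in C++ (Rcpp) behind `rf_fit()` /
`rf_votes()`, with determinism for a fixed seed part of the contract.

Performance is summarized by the confusion-matrix suite — accuracy,
specificity \(TN/(TN+FP)\), sensitivity \(TP/(TP+FN)\), and the Matthews
correlation coefficient with \(0/0 \to 0\) — plus the ROC AUC computed by
the midrank (trapezoid) convention, which gives 0.5 for constant scores and
`NA` when only one class is present.

**Cross-validation** partitions rows uniformly at random into five
near-equal portions (sizes differ by at most 1); each portion is tested
once and metrics are pooled over all rows. The partition is unstratified by
default — the protocol this package follows separates the data "equally at
random" — with a stratified option for the 1:5 imbalance. **Incremental
feature selection** evaluates the k-prefix of the mRMR list for
\(k = 1 \dots k_{\max}\), reusing one fold partition across all \(k\), and
selects the \(k\) maximizing MCC (smallest \(k\) on ties). The forest seed
for each \((k, \text{fold})\) pair derives from a master seed by a fixed
counter scheme (`master + 100003 k + fold`, mod \(2^{31}-1\)), so extending
\(k_{\max}\) never perturbs earlier rows.

## The synthetic benchmark

Real inputs (STITCH/STRING dumps, curated target sets, pathway databases)
are large, licensed, and unnecessary for verifying the machinery, so the
`synth_*` functions generate inputs of the same shape:

* sparse symmetric integer score tables (uniform 150–999) with Bernoulli
  edge probabilities — defaults `chem_density = 0.05` over drugs and
  `ppi_density = 0.002` over 2,000 proteins, chosen once as plausible
  sparsity for curated interaction databases at these dimensions;
* per-drug target sets of 1–8 proteins; 229 pathway gene sets of 10–60
  proteins over a 20,000-gene universe;
* 121 positive pairs and 5× sampled negatives over 169 drugs, so the
  default feature matrix is exactly 726 × 465.

The defaults carry **zero planted signal** (the null world): a full run on
them should, and in the acceptance tests does, produce cross-validated MCC
indistinguishable from 0.

Signal is always injected at the *data* layer, never into feature values,
so every code path is exercised end to end:

* `chem_shift` raises positive pairs' chemical scores (clamped at 999);
* `cross_ppi_boost` adds cross-target interaction edges within positive
  pairs with the given probability;
* `n_signal_pathways` plants correlated pathway enrichment: each connected
  component of the positive-pair graph receives one shared "affinity" per
  designated pathway (the number of that pathway's genes wired into each
  member drug's network neighbourhood, levels 0/4/8/12), so the two drugs
  of a positive pair agree in enrichment while random pairs usually do not.

Two honest limitations of that last channel follow from the biology of the
encoding, not from implementation choices. First, enrichment is a per-drug
quantity, so negative pairs whose two drugs happen to share a component
inherit the same agreement — with 121 positive edges over 169 drugs the
positive-pair graph has a giant component, and a sizeable minority of
negatives fall inside it. Each individual planted `absdiff:` feature is
therefore informative but not dominant, and a green signal-recovery test
establishes that the planted set crowds the top of the MaxRel list, not
that every planted feature beats every background feature. Second, the
affinity levels are spaced four genes apart because the hypergeometric
score also moves with each drug's expanded-set size \(n\); closer spacing
would drown the planted correlation in that nuisance variation. The strict
"all planted features in the top ranks" property is verified on the purely
pair-level channels (chemical shift + cross-target boost), which the
generator can guarantee.

What the generator does **not** emulate: realistic degree distributions of
interaction databases, realistic pathway-size distributions, shared-target
structure between related drugs, or identifier namespaces (ids are opaque
strings throughout). A green pipeline test on synthetic data establishes
correctness of the machinery, not transferability of any particular
performance number to real databases.

## Numerical and design choices not stated elsewhere

* Scores stay on their raw input scale (no division by 1000): every
  downstream feature is scale-covariant and trees are scale-invariant.
* Duplicate rows for one unordered pair collapse to the **maximum** score
  (databases list both orientations; max is order-independent).
* Self pairs are never stored; looking one up returns 0 by convention.
* Drugs with empty target sets are rejected at load time (the benchmark
  excludes combinations lacking target information).
* Pathway order is lexicographic by id, fixing feature-column order.
* Enrichment profiles persist via `%.17g` (shortest-exact) formatting so a
  stage re-run from disk is byte-identical to the in-memory run.
* MCC uses double arithmetic for the four-factor product (no integer
  overflow at any realistic n) and substitutes 0 when the denominator is 0.
* Configs are JSON (a YAML reader is used when the yaml package is
  present); every random draw traces to a named seed in the run manifest,
  because the benchmark's headline numbers depend on its random negative
  sample and fold partition — auditability is the only defence.

## A worked example

```{r example, eval = FALSE}
library(drugCombo)

cfg <- pipeline_config(
  outdir = "run",
  synth  = synth_config(chem_shift = 500, cross_ppi_boost = 0.3,
                        n_signal_pathways = 9, seed = 1),
  k_max  = 60, cv_seed = 1, forest_seed = 1)
manifest <- run_pipeline(cfg)
manifest$stages$featurize   # 726 rows x 465 features
manifest$stages$ifs         # optimal k, MCC/ACC/AUC at the optimum
```

Artifacts land under `run/`: the six generated inputs, `enrichment.tsv`,
`features.tsv`, the two ranked lists, the IFS table (`k`, ACC, SP, SN, MCC,
AUC per prefix), `ifs_curve.svg`, `roc_curve.svg`, the optimal-feature
report and `manifest.json`.

## Known limitations

* The forest is the fixed 10-tree configuration under test, not a tuned
  learner; no hyperparameter search is provided by design.
* Relevance is estimated on the full dataset before cross-validation, as in
  the workflow this package reproduces; reported CV metrics for selected
  subsets are therefore optimistic relative to nested selection.
* The discretized plug-in MI estimator is the method under test; no
  continuous (kernel / k-NN) estimators are included.
* No multiple-testing correction is applied to enrichment scores — they are
  used as scores, not as hypothesis tests.
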