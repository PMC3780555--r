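# drugCombo

Screening drug *combinations* — unordered pairs of co-administered drugs —
is a classification problem: approved effective pairs are rare, the
candidate space is quadratic in the number of drugs, and the interesting
question is which measurable properties of a pair separate effective
combinations from arbitrary ones. drugCombo is an R package for
bioinformaticians and cheminformaticians who want that pipeline as tested,
reusable, fully seeded code:

1. **Encode** each pair (d₁, d₂) as a symmetric vector of 7 + 2P
   non-negative features (465 at P = 229 pathways):
   * the chemical-chemical interaction confidence score Q_c(d₁, d₂)
     (STITCH-style 0–999 scale, 0 when absent);
   * max and mean protein-interaction score Q_p over cross pairs of the two
     target sets, and the order-free sums/absolute differences of each
     drug's within-target-set max and mean (6 features);
   * per pathway j, the sum e₁ʲ + e₂ʲ and absolute difference |e₁ʲ − e₂ʲ| of
     the drugs' enrichment scores, where eʲ = −log₁₀ P[X ≥ m] with
     X ~ Hypergeometric(N, M, n) over the drug's network-expanded target
     set (2P features).
2. **Rank** all features by mutual information with the label (MaxRel) and
   by the greedy minimum-redundancy maximum-relevance objective
   rel(f) − mean MI(f, selected) (mRMR, MID variant), after three-state
   discretization at mean ± sd.
3. **Select** a feature-count k by incremental feature selection: evaluate
   each k-prefix of the mRMR list with a 10-tree random forest
   (mtry = ⌊log₂ M⌋ + 1, unpruned, majority vote) under 5-fold
   cross-validation, and keep the k maximizing the Matthews correlation
   coefficient.

No interaction-database downloads are required: a synthetic-data module
generates STITCH/STRING/GMT-shaped inputs at the benchmark's exact shape
(169 drugs, 121 positive / 605 negative pairs, 229 pathways → a 726 × 465
matrix) with a configurable planted signal, so the entire pipeline is
verifiable offline. See the methods vignette
(`vignettes/drugCombo-methods.Rmd`) for the model, conventions and design
decisions.

## A worked example

```r
library(drugCombo)

cfg <- pipeline_config(
  outdir = "run",
  synth  = synth_config(chem_shift = 500, cross_ppi_boost = 0.3,
                        n_signal_pathways = 9, seed = 1),
  k_max  = 60, cv_seed = 1, forest_seed = 1)
manifest <- run_pipeline(cfg)
manifest$stages$ifs
#> $k_max
#> [1] 60
#> $optimal_k
#> [1] 3
#> $mcc
#> [1] 0.9900826
#> $acc
#> [1] 0.9972452
#> $auc
#> [1] 0.998955
```

This generates a 726 × 465 labelled matrix whose positives carry a planted
chemical-score shift, extra cross-target interaction edges, and correlated
pathway enrichment; ranks the features; and sweeps IFS over k = 1…60. The
planted signal dominates the MaxRel head, as it should:

```r
head(data.table::fread("run/ranked_maxrel.tsv"), 5)
#>     rank        feature  relevance
#> 1:     1           chem 0.51371670
#> 2:     2 ppi_cross_mean 0.31046087
#> 3:     3  ppi_cross_max 0.18242309
#> 4:     4 absdiff:PW0003 0.04040029
#> 5:     5 absdiff:PW0005 0.03226378
```

`optimal_k = 3` with MCC 0.99 means three features (here: the planted
chemical and cross-target ones) already separate this synthetic world
almost perfectly — real data are far harder; on zero-signal synthetic data
the same pipeline yields MCC ≈ 0, as the acceptance tests verify.

Artifacts under `run/`: the six generated input files (`input/`),
`enrichment.tsv` (drugs × pathways), `features.tsv` (pairs × features with
labels), `ranked_maxrel.tsv` / `ranked_mrmr.tsv`, `ifs.tsv` (k, ACC, SP,
SN, MCC, AUC per prefix), `ifs_curve.svg`, `roc_curve.svg`,
`optimal_features.tsv`, and `manifest.json` recording the config hash and
every seed.

A command-line interface wraps the same stages:

```sh
Rscript inst/cli/drugcombo all --outdir run --k-max 60
Rscript inst/cli/drugcombo ifs --config run.json   # re-run one stage
```

## Reading externally supplied data

The loaders accept STITCH-style and STRING-style TSVs (ids in the first two
columns, `combined_score` selectable by name), a two-column `drug_id` /
`protein_id` target table, GMT pathway files, and two-column pair lists;
`sample_negatives()` draws the random negative set. Absent pairs score 0,
duplicate rows collapse to their maximum, self pairs are never stored, and
drugs without targets are rejected — see `?load_score_table`.

## A caveat worth repeating

Feature relevance is computed once on the full dataset before
cross-validation (the ranked lists are global). Reported CV metrics for
selected subsets are therefore optimistic relative to a fully nested
selection protocol. This mirrors the workflow the package reproduces and is
flagged here deliberately.

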