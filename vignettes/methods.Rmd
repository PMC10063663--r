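---
title: "Methods: sparse non-negative embeddings from similarity judgments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sparse non-negative embeddings from similarity judgments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model, the estimation and selection machinery,
the synthetic-data generators, and the numerical choices behind `simdims`.
Code chunks are shown but not evaluated here; the package's test suite and
`scripts/acceptance.R` execute all of them at fixed seeds.

## The model

Behavioral similarity judgments between pairs of stimuli (e.g. short action
videos) are summarized as a symmetric item-by-item similarity matrix
$S \in [0,1]^{n \times n}$. The model assumes a small number of
non-negative, sparse latent dimensions explains these judgments:

$$ S \approx W H, \qquad W \ge 0,\; H \ge 0, $$

with $W$ an $n \times k$ matrix and $H$ a $k \times n$ matrix. Because the
input is symmetric, the two factors of the fit are highly correlated
(`factor_symmetry()` quantifies this), and the rows of $H$ are used as the
dimension weights everywhere downstream (`dimension_weights()`).

Sparseness is controlled by Hoyer's measure for a vector $v$ of length $m$:

$$ s(v) = \frac{\sqrt{m} - \lVert v\rVert_1 / \lVert v\rVert_2}{\sqrt{m} - 1} \in [0, 1], $$

where 0 means a fully dense vector and 1 a single non-zero entry. The fit
can constrain the columns of $W$ to sparseness `s_w` and the rows of $H$ to
`s_h`.

## From ratings to a similarity matrix

`similarity_dataset()` stores long-format dissimilarity ratings in one of
two designs:

* `rating_sampled` — many raters each judge the pairs within a random item
  subset, so pairs have variable numbers of ratings (the large-stimulus-set
  regime);
* `participant_complete` — every rater judges every pair (the smaller
  complete-design regime).

`aggregate_ratings()` averages all ratings per pair (pooled across raters,
not a mean of per-rater means, so raters contributing more ratings to a
pair weigh proportionally). `to_similarity()` converts mean dissimilarities
$D$ to similarities $S = 1 - D / \max D$, with the unobserved diagonal set
to 1: an item is maximally similar to itself, consistent with a
dissimilarity of 0. `impute_missing()` fills unobserved pairs with
$\max(\min_j S_{aj}, \min_j S_{bj})$, computed from observed entries only
and applied simultaneously, so imputation is idempotent and cannot leak
imputed values into other imputations.

```{r}
library(simdims)
ds <- read_ratings("ratings.csv", mode = "participant_complete")
V <- impute_missing(to_similarity(aggregate_ratings(ds)))
```

## Fitting

`nmf_fit()` minimizes the Frobenius loss with:

* **NNDSVD initialization** (`nndsvd_init()`): deterministic, built from
  the leading $k$ singular triplets, choosing per component the positive or
  negative section with the larger mass. This makes every fit
  bit-reproducible without a random-restart protocol.
* **Multiplicative updates** when a factor is unconstrained. Zeros in the
  initialization are filled with $\mathrm{mean}(V)/100$: multiplicative
  updates cannot move an exactly-zero entry, and NNDSVD produces many
  structural zeros that would otherwise lock the fit into a poor stationary
  point.
* **Projected gradient steps** when a sparseness constraint is active: after
  each gradient step the affected columns/rows are projected onto the set
  of non-negative vectors with the target $L_1/L_2$ ratio (Hoyer's
  projection, `project_sparseness()`), preserving the $L_2$ norm. The step
  size adapts: halved when the loss increases, grown by 1.2 on success.
* **Stopping**: relative loss change below `tol` (default `1e-5`) or
  `max_iter` (default 500). Ten consecutive genuine loss increases raise a
  classed `nmf_divergence` error rather than returning a bad fit.

## Model selection

`select_dimensions()` runs the full nested scheme:

1. **Outer hold-out** (`split_holdout()`): about 10% of the data never
   touches fitting — one rating per pair in `rating_sampled` mode, five
   whole raters in `participant_complete` mode.
2. **Inner folds** (`make_cv_plan()`): per repetition (default 5) the
   training units are split into two equal folds (together roughly two
   thirds) and a k-selection third.
3. **Sparsity search** (`sparsity_search()`): for each candidate $k$, a
   9-by-9 grid over `s_w, s_h` $\in \{0, 0.1, \ldots, 0.8\}$ is scored by
   fitting on one fold and evaluating on the other (both directions,
   averaged). The evaluation metric everywhere is Kendall's $\tau_A$
   between the lower-triangle entries of the reconstruction and the target
   matrix; $\tau_A$ counts tied pairs as neither concordant nor
   discordant. Non-convergent fits score $-1$.
4. **k curve and elbow** (`k_curve()`, `find_elbow()`): the best grid point
   per $k$ is refit and scored on the k-selection third; the selected $k$
   maximizes the distance to the chord of the min-max-normalized curve.
   Ties go to the smaller $k$; an exactly linear curve selects the smallest
   interior $k$ with a warning.
5. **Final fit** (`finalize_nmf()`): refit on all training data at the
   selected $(k, s_w, s_h)$, initialized from the first repetition's
   first-fold fit, and scored once against the untouched hold-out.

`cross_validated_pca()` provides the baseline: identical outer split and
inner folds (pass `split` and `plan` from the NMF run), but per $k$ a
column-mean-centered rank-$k$ SVD reconstruction and no sparsity search.

## Robustness, validation and labels

* `run_robustness()` removes all stimuli of a category (or scene setting),
  reruns the entire selection, matches each new dimension to its best
  original correlate among surviving items (`match_dimensions()`), and
  compares the observed correlations with a null built by independently
  permuting the item assignment of each row 1000 times (`shuffle_null()`);
  $p = (1 + \#\{\text{null} \ge \text{obs}\}) / (n_{\text{iter}} + 1)$.
* `build_trials()` / `score_responses()` implement the odd-one-out check:
  eight videos per trial (seven from the dimension's top eight, one from
  its bottom eight), chance 12.5%; raters whose catch-trial accuracy is not
  strictly above chance are excluded. `sign_permutation_test()` provides
  omnibus (max-statistic) corrected p-values with one sign flip per
  participant shared across dimensions.
* `label_agreement()` embeds free-text dimension labels with pretrained
  word vectors (`read_word_vectors()`, multi-word labels average their
  in-vocabulary tokens), pools within-dimension pairwise Euclidean
  distances across dimensions and experiments, and calls two labels
  related below the pooled 10th percentile. Chance is the proportion of
  across-dimension pairs below the same threshold. Note this agreement
  statistic is scale-invariant for homogeneous label clusters: it rewards
  dimensions labeled more consistently than the pooled pool, not tight
  clusters per se.

## Synthetic data and its limits

`make_planted_model()` draws $W$ from folded-normal entries, projects each
column to a target Hoyer sparseness, and rescales so $WW'$ lies in
$[0, 1]$. `simulate_dataset()` turns the planted similarities into
per-rater dissimilarities $1 - \mathrm{clip}(b \cdot S + \varepsilon, 0, 1)$
with optional rating noise and per-rater scaling bias.

The generator is deliberately simple and differs from real raters in known
ways: ratings are conditionally independent given $S$ (no drift, no
item-specific rater effects); noise is Gaussian and homoscedastic; planted
categories are the argmax dimension per item rather than a curated stimulus
taxonomy; and at sparseness 0.5 many planted similarities are exactly zero,
creating tied values that real behavior would not produce (ties cap
$\tau_A$ below 1 even for perfect recovery). Two further structural points
matter when interpreting recovery numbers: the similarity conversion's
affine shift adds a rank-one component, so the selected $k$ is often one
above the planted $k$; and the unit diagonal fill is inconsistent with the
planted $WW'$ diagonal, which bounds the fitted hold-out $\tau_A$ on
synthetic data even without noise.

## Problem sizes and numerical choices

The hot loops (the fit and $\tau_A$) are implemented in C++; a full nested
selection at the complete-design scale (65 items, 53 raters, `k_range`
1:12, reduced sparsity grid `c(0, 0.3, 0.6)`, 5 repetitions) runs in tens
of seconds on one CPU. The package's tests and the acceptance script use
these sizes as their standard working scale; the full 9-by-9 sparsity grid
and larger `k_range` are available through the same interfaces
(`default_sparsity_grid()`, `k_cap`) when more compute is warranted.
Random-number use is centralized: every stochastic function takes a `seed`
and restores the caller's RNG state, so pipelines are reproducible
end-to-end from a single master seed.

## Limitations

* $\tau_A$ (not $\tau_B$) is used throughout; with heavily tied data its
  ceiling is below 1, which should be kept in mind when comparing against
  other implementations.
* The elbow criterion is a heuristic; on curves without curvature it falls
  back to the smallest interior candidate with a warning rather than
  guessing.
* Imputation of unobserved pairs is a crude row-minimum rule; with very
  sparse designs the imputed mass can dominate and the cross-validated
  $\tau_A$ should be read accordingly.
* The label-agreement statistic depends on the composition of the pooled
  distance distribution; adding or removing dimensions changes the
  threshold and therefore every dimension's agreement.
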