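---
title: "Multi-block joint dimensionality reduction with mbmcia: model, conventions, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-block joint dimensionality reduction with mbmcia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbmcia)
```

## The model

A multi-block dataset holds N matrices $X_k$ ($n \times p_k$, samples in
rows) over the same $n$ samples; the global matrix
$X = [X_1 \cdots X_N]$ concatenates them column-wise. For each order
$j = 1, \dots, R$ the package maximizes

$$\sum_{k=1}^{N} \mathrm{cov}^2(X_k \vec a_k,\ \vec f), \qquad
\vec f = \sum_k w_k X_k \vec a_k, \qquad
\lVert \vec a_k \rVert_2 = 1,\ \lVert \vec w \rVert_2 = 1,$$

over the block loadings $\vec a_k$ and block weights $\vec w$. The global
score $\vec f$ is a weighted consensus of the block scores
$\vec f_k = X_k \vec a_k$; the squared weights $w_k^2$ are the *block
contributions* and sum to one per order. Stacking orders gives global scores
$F$ ($n \times R$), global loadings $A$ ($p \times R$, column $j$ the
block-wise concatenation of $w_{kj}\,\vec a_{kj}$), block scores $F_k$ and
block loadings $A_k$, related by $F = XA$ and $F_k = X_k A_k$ on the
preprocessed data.

The solver is a multi-block power iteration (NIPALS family): per iteration,
$\vec a_k \propto X_k^\top \vec f$, $\vec f_k = X_k \vec a_k$,
$w_k \propto \vec f_k^\top \vec f$ (then normalized), and
$\vec f \leftarrow \sum_k w_k \vec f_k$. The objective is recorded every
iteration and is monotonically non-decreasing; the test suite asserts this
over 100+ randomized instances, and checks on tiny instances that the
converged order-1 objective equals a brute-force multi-start maximization of
the same objective to $10^{-4}$ relative. No eigendecomposition is used
anywhere: variance explained comes from the converged objective values
("pseudo-eigenvalues" $\lambda_j$) as $\lambda_j / \sum_i \lambda_i$.

### Deflation: MCIA vs CPCA

Before order $j+1$ the captured structure is removed:

* **block** (MCIA): $X_k \leftarrow X_k (I - \vec a_k \vec a_k^\top)$.
  Successive loadings are orthonormal *within each block*
  ($A_k^\top A_k = I$), and $F = XA$ holds exactly — with $N = 1$ the whole
  procedure reduces to PCA of the single preprocessed block (verified against
  the SVD to $10^{-6}$).
* **global** (CPCA): $X_k \leftarrow X_k - \vec f (\vec f^\top X_k)/(\vec
  f^\top \vec f)$. Successive global scores are mutually orthogonal
  ($F^\top F$ diagonal); block loadings are generally *not* orthonormal.

Neither mode formally guarantees non-increasing $\lambda_j$;
`variance_explained()` warns (rather than fails) if the ordering is violated.

## Preprocessing

Two levels, applied in a fixed order: column transform first, then one scalar
divisor per block computed **on the column-transformed block**. Whole-block
scaling is the recommended guard against block-size disparity: without it a
20,000-feature block out-votes a 50-feature block simply by total variance.

| level  | option                   | definition |
|--------|--------------------------|------------|
| column | `none`                   | identity |
| column | `center`                 | subtract column mean |
| column | `center_scale`           | center, divide by column sd (denominator $n-1$) |
| column | `colprofile`             | see below |
| block  | `none`                   | divisor 1 |
| block  | `unit_variance`          | $\lVert Y\rVert_F / \sqrt{n-1}$ (total variance 1) |
| block  | `largest_singular_value` | $\sigma_1(Y)$ |
| block  | `num_columns`            | $\sqrt{p_k}$ |

Conventions worth knowing:

* **$n-1$ everywhere.** One standard-deviation/covariance denominator, used
  identically in preprocessing and in the solver's objective. The choice only
  rescales $\lambda_j$, never score or loading directions.
* **Zero-variance columns** get scale divisor 1 (the centered column is
  all-zero) plus a warning — never dropped, so loading rows always align with
  the input feature ids.
* **`colprofile`** is one fixed convention for non-negative (count-like)
  data, mirroring the correspondence-analysis heritage of co-inertia methods:
  with training grand total $G$, column masses $c_j$, and row sums $s_i$, an
  entry becomes $(x_{ij} - s_i c_j)/\sqrt{s_i G}$ — algebraically the
  centered row profile $(P_{ij}/r_i - c_j)$ weighted by $\sqrt{r_i}$. Only
  $G$ and $c$ are reused on new data (plus each new row's own sum), so the
  transform is well-defined out of sample. Negative entries and zero row
  sums are rejected, not patched.
* The fitted parameters (centers, scales, block scalars, $G$, $c$) travel
  inside the result object and its on-disk serialization; `apply_preprocessor`
  never re-estimates anything.

## Numerical choices

* **Initialization**: deterministic by default — the column of the
  concatenated (possibly deflated) global matrix with the largest variance.
  `init = "random"` draws a seeded standard normal vector instead, the escape
  hatch for adversarially symmetric inputs; the seed lives in the config so
  runs stay bitwise reproducible.
* **Convergence**: relative change of the global score,
  $\lVert f_{t+1} - f_t \rVert / \lVert f_t \rVert <$ `tol` ($10^{-9}$
  default), capped at `max_iter` = 5000 (a warning recorded in the
  diagnostics, not an error).
* **Scale of $f$**: the global score is *not* re-normalized inside the
  iteration; its scale carries the pseudo-eigenvalue. Other MCIA
  implementations may scale eigenvalues differently (e.g. by $n-1$ factors);
  proportions of variance explained are invariant to that.
* **Signs**: each order is flipped so the largest-magnitude entry of the
  global loading is positive; $\vec a_k$, $\vec f_k$, $\vec f$ flip jointly
  and $\vec w$ is untouched, preserving every identity. This pins down signs
  across platforms and BLAS builds.
* **Degenerate blocks**: if $\lVert X_k^\top \vec f\rVert < 10^{-12}$
  mid-iteration (e.g. an all-zero block, or a block whose rank is exhausted
  by deflation), that block's loading is zeroed, its weight pinned to 0, and
  a per-block flag set — the other blocks' solution proceeds. All blocks
  degenerate ends the fit: if it happens at order $j \le R$, the result is
  truncated at $j-1$ with a warning. Note the within-block orthonormality
  invariant $A_k^\top A_k = I$ is only attainable while $j \le p_k$; beyond a
  block's width the degeneracy path takes over by design.
* **Ties** in `top_features` break by (block order, feature order), making
  rankings deterministic.

## Out-of-sample prediction

Loadings are fixed linear combinations of input features, so a new sample of
the same features embeds as $F_{new} = X_{new,preproc} A$. Under block
deflation this is exact (on training data it reproduces $F$ bitwise to
$10^{-10}$), and per-block embeddings $F_{k,new} = X_{k,new} A_k$ are
returned too. Under global deflation the training identity $F = XA$ does not
hold exactly, so the prediction is still computed but carries an
`"approximate"` attribute and no block scores — the semantics are only
provable for the MCIA mode. New data may not add, drop or reorder features;
mismatches are rejected with the symmetric difference listed, because a
silently re-aligned feature space is the worst failure mode of multi-omics
tooling (the same reason sample alignment across blocks is by id, never by
row position).

## The synthetic generator: what a green test establishes

`generate_multiblock()` plants $X_k = \sum_r s_{kr}\, \vec z_r \vec
v_{kr}^\top + \epsilon$: factor scores $\vec z_r$ drawn standard normal,
orthogonalized, and rescaled to norm $\sqrt n$ (unit empirical variance —
orthogonality makes "the planted factor" unambiguous for correlation checks
while keeping the natural $N(0,1)$ scale); per-block unit-norm loadings;
i.i.d. Gaussian noise ($\sigma = 0.1$ default, a strong-signal regime);
optional cluster structure injected as evenly spaced shifts (default spacing
4 within-cluster standard deviations) on factor 1 *in factor space*, so it
survives any column preprocessing. `nci60_like_fixture()` instantiates a
scaled-down bulk tumor panel: 21 samples, blocks of 200/50/120 features,
3 subtypes, per-factor signals (10, 3, 2), noise 0.5, fixed seed.

What this emulates: shared low-rank structure across heterogeneous blocks
with controllable signal-to-noise. What it does not: count distributions,
overdispersion, sparsity, batch effects, or feature correlation structure of
real omics data. A green recovery test therefore establishes that the linear
algebra recovers planted linear structure — not that any particular
normalization pipeline is appropriate for a given assay; count-data
normalization (CPM, log, TF-IDF) and feature selection are deliberately
upstream of this package.

## Known limitations

* Blocks are densified on load; the solver is dense-BLAS based. Fine into the
  $10^4$-feature range, not tuned for full single-cell matrices.
* Missing values are rejected, not imputed; partially observed blocks are out
  of scope.
* CPCA-mode predictions are approximate (flagged as such).
* One `colprofile` convention is committed to; other correspondence-analysis
  weightings exist.
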