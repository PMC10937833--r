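---
title: "Prior-knowledge-guided latent variables for bulk transcriptomes: models and methods"
author: "sigplier authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prior-knowledge-guided latent variables: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigplier)
```

## The model

Bulk RNA-seq mixes the transcriptomes of many cell types and states. When a
collection of cell-state gene signatures is available from single-cell
studies, a bulk cohort can be decomposed into latent variables (LVs) that
are anchored to those signatures, so that LV scores behave as
interpretable, cell-state-level summaries of each sample.

Given an expression matrix $Y$ (genes $\times$ samples, on the
$\log_2(\mathrm{TPM}+0.5)$ scale, genes z-scored by default) and a binary
membership matrix $C$ (genes $\times$ signatures), the package minimizes

$$\|Y - ZB\|_F^2 \;+\; \lambda_1\,\|Z - CU\|_F^2 \;+\;
  \lambda_2\,\|B\|_F^2 \;+\; \lambda_3 \sum_{s,k} |U_{sk}|,
  \qquad Z \ge 0,\; U \ge 0,$$

where $Z$ ($N \times K$) holds the gene loadings, $B$ ($K \times M$) the
per-sample LV scores, and $U$ ($S \times K$) the sparse weights aligning
each LV with a few signatures. The L1 penalty keeps each LV anchored to a
small number of signatures; the alignment term is what breaks the rotation
invariance of an unconstrained factorization and makes individual LVs
meaningful. Nonnegativity of $Z$ and $U$ makes "a signature's genes load
higher on this LV" a one-sided, testable statement; both constraints can be
switched off in `plierConfig()`.

A fitted model transfers to any new cohort preprocessed the same way:
$B' = (Z^\top Z + \lambda_2 I)^{-1} Z^\top Y'$ with the training loadings
$Z$ and the training per-gene standardization statistics. Genes absent from
the new data are zero-filled after standardization; the projection warns
below 80% gene overlap and refuses to run below 50%.

## Optimization

The loss is minimized by block coordinate descent:

* **B**: closed-form ridge solve $(Z^\top Z + \lambda_2 I)^{-1} Z^\top Y$.
* **Z**: exact column-wise coordinate descent on the quadratic
  $\|Y - ZB\|^2 + \lambda_1\|Z - CU\|^2$, each column clipped at zero.
* **U**: coordinate-wise nonnegative-lasso updates (soft-threshold at
  $\lambda_3 / 2\lambda_1$, clipped at zero), columns independent.

Every block step is an exact minimization over its coordinates, so the
outer-iteration loss trace is non-increasing by construction; this is
asserted (to a relative tolerance of $10^{-8}$ per step, allowing for
floating-point noise) rather than hoped for. Iteration stops when the
relative loss change falls below `tol` ($10^{-6}$ by default) or after
`maxIter` (200) outer iterations. After the loop, one extra B update is
applied so that the stored scores equal exactly what
`plierTransform()` computes on the training data.

**Initialization** is deterministic: the truncated SVD of the standardized
matrix, each loading column sign-flipped if majority-negative, scaled by
$\sqrt{d_j}$ on both sides, then clipped at zero. A column that clipping
would empty falls back to the absolute values of the singular vector.
Degenerate ridge systems (e.g. $\lambda_2 = 0$ with a collapsed column)
receive a $10^{-10}$-scale jitter; genes with vanishing variance are
guarded with an $10^{-12}$ floor on the standard deviation, though the
filtering step removes them up front.

## Hyperparameters and their defaults

* `k` — number of LVs. Chosen by `estimateNumLVs()`: parallel analysis in
  which the entries of each gene row are permuted (`nPerm = 20` times) and
  the observed singular values are compared component-by-component with the
  95% quantile of the permuted ones; `k` is the length of the leading run
  of exceedances. The leading-run reading keeps isolated late exceedances
  (expected at a 5% rate under the null) from inflating the count. The
  decomposition is not sensitive to moderate over-specification of `k`;
  surplus LVs simply attract no signature weight.
* `lambda1`, `lambda2` — default to the *noise level of the permutation
  scree*: the top singular value of a within-row-permuted copy of the
  standardized matrix. Penalty weights compete with squared singular values
  in the loss, so the natural default scale is the singular-value scale; a
  per-entry variance (a number near 1 for standardized data) would leave
  the alignment term inert and the factorization effectively
  unconstrained.
* `lambda3`, `frac` — the L1 weight defaults to
  $2\lambda_1 \cdot q_{1-\mathrm{frac}}$, where $q_{1-\mathrm{frac}}$ is
  the $(1-\texttt{frac})$ quantile of the nonzero candidate weights (the
  unpenalized nonnegative regression of the initial $Z$ on $C$). `frac`
  (default 0.5) is therefore a sparsity dial: the fraction of candidate
  signature weights the soft-threshold would retain at initialization.
  Smaller `frac` gives a sparser $U$; the number of nonzero entries of the
  converged $U$ is non-increasing in `lambda3`, which the tests assert on
  a grid.
* `standardize` (default `TRUE`) — gene z-scoring before fitting; the
  training means/sds are stored in the model and reused at projection
  time, so out-of-sample projection is well-defined.

## Preprocessing contract

Filtering operates on the TPM scale, where "zero" is well defined: genes
with null variance, genes with *strictly more than* 95% zeros (exactly 95%
is kept), and genes in no atlas signature are removed, in that single pass;
the filter is idempotent. The log transform $\log_2(\mathrm{TPM}+0.5)$ is
applied afterwards and bounds values below by $-1$. Gene identifiers are
opaque, case-sensitive strings — no alias resolution is attempted, because
symbol mapping is dataset-specific. Signature metadata travels in a
separate TSV keyed by signature name rather than in the GMT description
field, keeping the GMT files standard-conformant.

## Association scoring

Whether an LV is genuinely anchored to a signature is decided by gene
hold-out: `associationScan()` removes a random fifth
($\lceil 0.2\,n \rceil$ genes) of each signature from $C$, refits with the
training hyperparameters and seed, and, for every (LV, signature) pair
with positive refit weight, compares the loadings of the held-out genes
against the loadings of all genes *outside* the signature (held-in genes
belong to neither group). The AUC of that comparison estimates
$P(\text{held-out gene outranks non-member})$ with ties counted
$\tfrac12$; the p-value is the one-sided Mann–Whitney test of the same
contrast — one-sided because the question is specifically whether the AUC
exceeds one half. Benjamini–Hochberg correction is applied across all
scored pairs as one family. An LV is *interpretable* when some record
passes AUC $> 0.7$ and FDR $< 0.05$, both strict. Signatures with fewer
than five genes in the universe are skipped with a warning. A single
seeded hold-out draw is the default; `replicates` averages AUCs over
several draws when a smoother estimate is wanted.

Cell-type labels propagate from the atlas metadata: each interpretable LV
takes the cell type of its best passing record (highest AUC, ties broken
by lower FDR, then higher weight), with "Non associated" mapping to the
"Rest" category. Cell-type models use the up-to-four top-ranked LVs of a
cell type, mirroring how such LV subsets are used downstream.

## Downstream statistics

Differential LV analysis between two sample groups uses the unpaired
two-sided Mann–Whitney test per LV with BH correction restricted to the
tested subset (by convention, the interpretable LVs). The test switches
from exact enumeration to the normal approximation (with tie and
continuity corrections) when the combined sample size exceeds 20 or ties
are present; a fully tied input returns $U = n_1 n_2/2$, $p = 1$.
Direction is called from group medians — a reporting convention, not part
of the test.

Classification uses stratified 10-fold cross-validation repeated 10 times:
each repetition draws a fresh stratified fold assignment, pools the
out-of-fold scores across folds, and yields one AUROC; the mean ± SD over
the ten repetitions is reported (SD across repetitions, not folds). The
default learner is a random forest with library defaults and no
hyperparameter tuning — at the cohort sizes these models target, nested
tuning would cost more than it returns. A logistic model and arbitrary
`fit`/`predict` pairs are pluggable. Beware single-feature random-forest
models: deep trees memorize noise on one weak continuous feature and can
cross-validate below chance where logistic regression tracks the feature's
true AUC.

Shapley attributions are computed by exact coalition enumeration (up to 12
features; the cell-type models use at most 4). The value of a coalition is
the mean model score over background rows with the explained sample's
features substituted on the coalition. Exactness buys testable contracts:
efficiency holds to $10^{-8}$, ignored features get exactly zero, and
duplicated features in symmetric models get equal attributions.

## What the synthetic generator emulates — and what it does not

`simulateDataset()` plants the structure the decomposition assumes: random
gene-set signatures (the first `nActive` active, the rest decoys), loading
columns equal to 1 on the active signature's genes plus $|N(0, 0.05)|$ on
a random 2% of other genes, standard-normal sample scores with the first
two active LVs shifted by `groupEffect` in group 1, and additive Gaussian
noise (`noiseSd`, default 0.5) on the log scale, shifted so the minimum is
the $-1$ floor. Defaults are 2000 genes, 80 samples (balanced groups), 30
signatures of 50 genes, 5 active.

The generator works on the *post-transform* scale by design: the
framework consumes $\log_2(\mathrm{TPM}+0.5)$ values, so the fixture
emulates the statistical structure at that point of the pipeline. It does
**not** emulate count-level RNA-seq noise (negative binomial dispersion),
library-size or batch effects, gene–gene correlation beyond the planted
factors, or realistically overlapping cell-state signatures. Passing tests
therefore demonstrate that the estimator recovers the structure it is
built for and that its statistics are calibrated — not that any particular
biological cohort will decompose cleanly.

## Verification at a glance

The test suite checks, among others: loss monotonicity on random
instances (200 genes × 50 samples, K = 10); equivalence with the
truncated SVD when the alignment and L1 terms are off; recovery of all
planted (LV, signature) pairs at AUC ≥ 0.9 and FDR < 0.05 on the default
generator conditions across 20 seeds, with decoy signatures at chance;
AUC and Mann–Whitney agreement with brute-force enumeration oracles for
all group sizes up to 6; BH agreement with an independently coded step-up
on 1000 random vectors; projection self-consistency to $10^{-6}$;
calibration of the repeated-CV AUROC on separable (6σ) and permuted-label
data — the null level averaged over five independent permutations, since
one permutation's mean AUROC carries sampling noise of the same order as
the chance band; Shapley axioms for up to four features; differential-test
null calibration (false positive rate ≤ 0.07 at FDR < 0.05 over 100
replicates) and power ≥ 0.9 at the default effect size with 40 samples
per group; and byte-level reproducibility of every seeded stage. These
problem sizes keep the whole suite in the low minutes on one CPU while
exercising every contract at the scale it is stated for.

## Known limitations

* The optimizer is a local method; different seeds can reach different
  local minima. Determinism is guaranteed per seed, global optimality is
  not.
* The hold-out scan refits the full model once per replicate, which is the
  dominant cost at scale.
* The automatic penalty calibration is a convention chosen for robust
  recovery on planted structure, not a reproduction of any particular
  implementation's internals.
* Probe-to-gene mapping, batch correction, and count-level normalization
  are out of scope; inputs are expected as TPM tables with stable gene
  identifiers.
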