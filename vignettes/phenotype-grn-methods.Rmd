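---
title: "Methods: phenotype-relevant GRN inference from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotype-relevant GRN inference from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Classical gene regulatory network (GRN) inference asks which transcription
factors (TFs) regulate which genes. phenoGRN asks a narrower question: which
TF→gene interactions are *phenotype-relevant* — the TF regulates the gene
**and** the gene's expression tracks a binary phenotype (the motivating
setting is human embryonic stem cells versus definitive endoderm cells). The
package integrates three channels of summary statistics per candidate
TF *i* / gene *j* pair:

* `P_j` — the gene–phenotype association p-value from a differential
  expression analysis (raw, not FDR-adjusted: the model needs the null
  distribution of honest p-values);
* `p_ij` — an expression-based TF–gene *pseudo* p-value (Elastic Net
  feature selection followed by OLS);
* `q_ij` — a ChIP-seq-based TF–gene pseudo p-value (peak-to-gene distance
  p-values consolidated by a minimum over peaks and conditions).

"Pseudo" matters: both TF–gene channels are biased toward small values even
under the null (selection in one case, min-consolidation in the other), so
their null distributions are modeled as Beta mixtures rather than Uniform.

## The model

For each candidate pair, a latent Bernoulli indicator `T_ij = 1` means
"TF *i* regulates gene *j* in a phenotype-relevant way". The generative
model is:

* `gamma ~ TruncatedNormal(mu, sigma; 0, 2*mu)` with `mu = 2/22`; the
  bounds are symmetric about `mu`, so the prior edge probability is
  exactly `mu`. This encodes sparsity: a gene is expected to be regulated
  by about two of the 22 TFs of the motivating study. The untruncated
  standard deviation is **not** part of the published design; the default
  `sigma = 1/22` puts the bounds at two standard deviations and is exposed
  as a hyperparameter.
* `T_ij ~ Bernoulli(gamma)`.
* `P_j | T_.j` is Uniform(0,1) if every indicator of gene *j* is zero, and
  `Beta(alpha', 1)` otherwise; `alpha'` in (0,1) is estimated up front by
  an EM fit of the two-component mixture
  `lambda * Beta(a, 1) + (1 - lambda) * Uniform` to the pooled `P_j`
  (closed-form M-step `a = -sum(z) / sum(z log x)`, convergence at 1e-8
  log-likelihood gain).
* `p_ij | T_ij = 1 ~ Beta(a_H1, 1)`; under `T_ij = 0` it follows
  `r * Beta(a_H1, 1) + (1 - r) * Beta(a_H0, 1)` with per-gene latents
  `r ~ U(0,1)`, `a_H1 ~ U(0, 0.5)`, `a_H0 ~ U(0.5, 1)`. The same form,
  with its own latents, applies to `q_ij`.

Per gene, three negative controls are appended — artificial edges with
(p = 1, q = q*), (p = p*, q = 1) and (p = 1, q = 1), where p*, q* are the
smallest observed values over the gene's real candidates. Their posterior
scores act as gene-specific exclusion thresholds: an interaction supported
by only one modality should not outrank an artificial edge carrying that
same single-modality support.

### Inference

Posteriors are estimated by MCMC (default 4 chains × 2000 tuning + 4000
retained iterations, the first 400 retained draws per chain additionally
discarded). The sampler is written in C++: exact Gibbs updates for the
indicators — the only coupling between indicators of a gene is the
any-edge disjunction in the `P_j` likelihood — and shrinkage slice
sampling for `gamma` and the per-gene mixture latents on their bounded
supports (rejection-free and tuning-free). Observed p-values are clipped
to `[1e-300, 1]` before log-density evaluation. Split-R-hat is reported
per indicator and values above 1.05 trigger a warning. The reported score
is the mean indicator over all retained draws of all chains, pooled with
equal weight.

Two ablated variants mirror the full model (`RnCnP`): `RnP` drops every
ChIP term and `CnP` every expression term. Ablated code paths never read
the inactive channel's values — including in control construction — so
their output is bit-identical under arbitrary perturbation of that
channel.

### Design choices the published design leaves open

* **Scope of `gamma` sharing.** `gamma` is shared within a gene batch
  (default 50 genes) and independent across batches, matching the
  batch-wise processing of the original pipeline; the alternative readings
  (global or per-gene sharing) are not distinguishable from the published
  description.
* **Controls as replicas.** Each control is an independent single-edge
  replica that re-observes the gene's `P_j` under its own indicator and
  does **not** enter the real gene's any-edge disjunction — otherwise a
  control could mask real evidence by "explaining" the phenotype p-value.
  Controls share `gamma` and the gene's per-modality mixture latents
  (they describe the same gene's evidence scale).
* **Elastic Net stage.** The loss
  `1/(2n)||y - Xw||^2 + a*rho*||w||_1 + a*(1-rho)/2*||w||^2` (`rho = 0.5`)
  is minimized by the package's own warm-started coordinate descent: the
  obvious off-the-shelf solver (glmnet) internally standardizes the
  response, which rescales the L2 term away from this exact loss; glmnet
  is retained as an independent oracle in the tests via a penalty mapping.
  The penalty is chosen by traversing a geometric path of 50 points from
  `alpha_max` (smallest all-zero penalty) down three decades, taking the
  last point whose support size stays within `min(15, n - 3)`. The
  published description says only that the penalty was tuned along a
  regularization path; the support cap guarantees OLS degrees of freedom.
  Inputs are centered (inverse-quantile-normalized response, standardized
  features), so the penalized fit carries no intercept; the OLS refit
  keeps one.
* **Inverse quantile normalization** uses plotting position
  `(rank - 0.5)/n` with average ranks for ties — symmetric and free of
  infinite values at the extremes.
* **Strictness.** All published thresholds print strict inequalities
  ("FDR < 0.01", "|logFC| > 2", "scored lower than", "smaller than mu"),
  so boundary values survive every filter and fail every selection.
* **Elbow reading.** "First local maximum of the consecutive score drops"
  is read on the *drop* sequence: with drops `d_k = s_k - s_{k+1}` and
  `-Inf` sentinels, the keep count is the smallest `k` with
  `d_k >= d_{k-1}` and `d_k >= d_{k+1}`; drops equal up to 1e-9 count as
  ties, so exactly constant sequences keep one score. The alternative
  reading (local maximum of the scores themselves) is degenerate for
  monotone sorted sequences.
* **Filter3 on normalized scores.** The published pipeline order places
  the `mu` threshold after min-max normalization; whether raw or
  normalized scores were thresholded is unstated.
* **ChIP-only candidates.** The published fallback sets `q = 1` when a
  pair has expression evidence but no ChIP link. The symmetric completion
  (`p = 1` for ChIP-only pairs) is applied and flagged in `p_imputed` /
  `q_imputed` columns, since the candidate set is described as coming from
  either channel.

## The synthetic world

The generator plants a ground-truth network and draws the three summary
statistics *exactly* under the model's assumptions: `P_j ~ Beta(0.2, 1)`
for phenotype genes, Uniform otherwise; true-edge pseudo p-values from
`Beta(0.1, 1)` in both channels; null pseudo p-values from the
`r`-weighted mixtures with `r = 0.2` and null shapes 0.8 (expression) and
0.9 (ChIP). Defaults describe 22 TFs, 200 genes, 30% phenotype genes with
on average two regulators each, and 5 decoy candidate TFs per gene (the
real pipeline derives the candidate count from the data; a simulation
must fix it). The optional expression generator builds a linear world —
standard-normal TF rows, gene rows as weighted sums of their regulators
plus a class shift for phenotype genes and Gaussian noise (28 samples,
weight 1, shift 1, noise 0.5 by default, mirroring the motivating study's
scale) — which exercises the regression stage end to end.

What a green test does establish: the pipeline recovers planted structure
when the model's distributional assumptions hold, the sampler agrees with
an exact quadrature oracle, and every filter implements its stated rule.
What it does not: robustness to misspecified evidence (real p-values are
not clean Beta mixtures), to correlated TFs, to batch effects, or to the
quality of upstream peak calling — all of which live outside the summary
statistics this package consumes.

## Numerical choices

* p-values of exactly 0 are clipped to 1e-300 everywhere (log-densities).
* The quadrature oracle uses 200-point Gauss–Legendre per dimension
  (Golub–Welsch nodes); doubling the resolution moves single-edge
  posteriors by less than 1e-6.
* Coordinate descent iterates to a 1e-12 coefficient-change tolerance;
  OLS uses a QR decomposition and drops rank-deficient columns with a
  warning.
* Sorting ties in rankings and summaries break by TF identifier for
  determinism; the C++ sampler uses its own 64-bit RNG seeded from the
  user seed, so results are reproducible across platforms independent of
  R's RNG state.

## Known limitations

The linear expression world cannot express nonlinear regulation; the
AUPRC-ratio evaluation treats unscored universe pairs as jointly ranked
last, which is one of several defensible conventions; and the published
study's headline benchmark numbers depend on external datasets and a
curated CRISPRi ground truth, so they are out of reach of the synthetic
world — the acceptance suite checks calibration, oracle agreement,
planted-structure recovery with the published ablation ordering, and the
published worked-example arithmetic instead.
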