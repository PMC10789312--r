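---
title: "Multi-kernel classification of case-control status from microbiome profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-kernel classification of case-control status from microbiome profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mkbmc)
```

## The problem

Case–control microbiome studies measure, for each sample $i$, the relative
abundances $P_i = (p_{i1}, \dots, p_{iq})$ of $q$ OTUs together with a rooted
phylogenetic tree over those OTUs, and ask whether the community composition
predicts a binary outcome $y_i$. Different diseases leave different
footprints: sometimes the *abundance* of a clade shifts, sometimes the
*presence or absence* of rare taxa changes, and the implicated taxa may be
phylogenetically clustered or scattered. A single distance metric captures
one of these signal forms and is blind to the others.

`mkbmc` combines several signal forms in one classifier. Each of four
classical community distances is sharpened ("boosted") with per-feature
association weights learned from the training labels, converted to a
Gaussian similarity kernel, and the kernels are combined with weights
learned in closed form under an entropy-regularized alignment objective.
The learned kernel weights double as an interpretable readout of *which*
signal form drives the prediction.

## Boosted distances

Let $b_r$ be the branch lengths of the rooted tree ($r = 1, \dots, R$
branches, one per non-root node) and $p_{ir}$ the **branch profile** of
sample $i$: the summed relative abundance of the leaves descending from
branch $r$, computed by a single post-order accumulation. With
non-negative per-feature boosting weights $a_r$ the four distances are

$$
d_w(i,j) = \frac{\sum_r b_r a_r\,|p_{ir} - p_{jr}|}
                {\sum_r b_r a_r\,(p_{ir} + p_{jr})}, \qquad
d_{un}(i,j) = \frac{\sum_r b_r a_r\,|I(p_{ir}>0) - I(p_{jr}>0)|}
                   {\sum_r b_r a_r\,I(p_{ir} + p_{jr} > 0)},
$$

$$
d_{BC}(i,j) = \tfrac12 \sum_{r=1}^{q} a_r\,|p_{ir} - p_{jr}|, \qquad
d_{H}(i,j) = \sum_{r=1}^{q} a_r\,|I(p_{ir}>0) - I(p_{jr}>0)|,
$$

where the tree metrics ($d_w$, $d_{un}$) run over branches and the
OTU metrics (Bray–Curtis $d_{BC}$, Hamming $d_H$) over leaf abundances
(rows sum to 1, so the classical Bray–Curtis denominator is the constant
2). Setting $a_r \equiv 1$ recovers the textbook metrics exactly, which
the test suite asserts against independent oracles (`vegan`, `picante`,
and per-branch brute-force enumeration).

The boosting weights are $a_r = -\log_{10} p_r$ from a per-feature
association test against the training labels, normalized to mean 1:

* abundance-type metrics ($d_w$, $d_{BC}$): two-sided Welch two-sample
  *t*-test on the feature values;
* presence-type metrics ($d_{un}$, $d_H$): test of the 2×2
  presence-by-label table — Fisher's exact test when any expected cell
  count is at most 5, Pearson's $\chi^2$ without continuity correction
  otherwise. (The "at most" boundary is deliberate: the canonical
  perfectly-separated 10/10 table has expected counts exactly 5 and should
  be handled exactly.)

For the tree metrics the tests are run on the *branch profiles*
(`boost_level = "branch"`, the default), so internal branches summarizing
a signal clade are boosted directly; a leaf-only variant
(`boost_level = "otu"`) is available. P-values are floored at $10^{-300}$
before the log. The mean-1 normalization is a pure convention: the $a_r$
scale cancels in the UniFrac ratios and, for the linear metrics, rescales
the distance and the mean-distance bandwidth together — the kernels are
provably unchanged, and a dedicated test certifies this at $10^{-12}$.
When every p-value equals 1 the weights fall back to uniform with a
warning.

## From distances to kernels

Each distance matrix becomes a similarity kernel
$K(i,j) = \exp(-d(i,j)^2 / 2\sigma^2)$ with bandwidth $\sigma$ set to the
mean of the pairwise *training* distances (strict upper triangle: the zero
self-distances would bias $\sigma$ downward). Numeric covariates get one
kernel each: the covariate is z-scored with training statistics (making
the kernel invariant to affine rescaling and Euclidean distances
comparable across covariates), the distance is $|x_i - x_j|$, and the same
bandwidth rule applies. Test samples always reuse the frozen training
boosting weights, bandwidths, centers and scales — nothing on the test
side feeds back into the model. Kernels are used as similarities; positive
semi-definiteness is neither assumed nor needed (nothing is inverted).

## Learning kernel weights

With $L$ kernels (four microbiome + one per covariate), training labels
define the agreement matrix $CC(i,j) \in \{-1, 0, 1\}$ (+1 same class,
−1 different, 0 diagonal). The weights minimize

$$
-\sum_{i,j}\sum_l w_l K_l(i,j)\,CC(i,j) + \rho \sum_l w_l \log w_l,
\qquad \sum_l w_l = 1,\; w_l \ge 0 .
$$

The first term rewards kernels whose similarities are large within classes
and small between them; the entropy term pulls the weights towards
uniformity as $\rho$ grows. Stationarity gives a softmax in the alignment
scores $S_l = \sum_{i,j} K_l(i,j)\,CC(i,j)$:

$$ w_l = \frac{\exp(S_l/\rho)}{\sum_m \exp(S_m/\rho)} , $$

computed with max-subtraction (the $S_l$ are $O(N^2)$). At $\rho = 0$ the
problem is linear and all mass goes to the top-scoring kernel, split
equally over exact ties. The test suite checks this closed form against a
brute-force simplex-grid minimizer and verifies that weight order always
follows score order and that the weight entropy is non-decreasing in
$\rho$ — which is also why *which kernel is largest* can be studied at any
fixed $\rho > 0$.

### Choosing $\rho$

True maximum entropy is reached only as $\rho \to \infty$, so the grid
endpoint $\rho_{\max}$ is the smallest value in a doubling search (start
1, factor 2, capped at $2^{60}$) whose weights reach
$(1 - 10^{-3})\log L$ entropy. $\rho$ is then tuned over the 11-point grid
$\{0, \rho_{\max}/10, \dots, \rho_{\max}\}$ by stratified 5-fold
cross-validation on the training AUC, with ties broken towards the largest
$\rho$ (flatter weights are more stable out of sample). Inside each fold
the boosting weights *and* bandwidths are re-learned from the fold's
training part only; boosting on the full training set before
cross-validation would leak label information into the held-out folds and
flatter the tuning AUCs.

## The classifier

Given weights, the combined similarity is
$\sum_l w_l K_l(i,j)$. Every training sample receives a **similarity
t-score** $t_i$: the Welch two-sample *t*-statistic comparing its
similarities with the remaining training cases against those with the
remaining controls (leave-self-out). A logistic model
$\operatorname{logit} P(y=1) = \beta_0 + \beta_1 t$ is fit by maximum
likelihood (IRLS via `glm`, 100 iterations, tolerance $10^{-8}$). Under
complete separation the slope diverges; it is clamped at $|\beta_1| = 30$
with a warning and the intercept refit by offset. A test sample gets its
t-score from its similarities to all training cases and controls (nothing
to leave out) and its case probability from the fitted logistic curve;
each prediction depends only on that sample and the training set.

## The simulation engine

The generator reproduces the data-generating process used to study the
method, so every stage is testable without external downloads:

* **Totals** $N_i \sim$ negative binomial with mean 1000 and size 25
  (variance $\mu + \mu^2/k$).
* **Counts** are Dirichlet-multinomial: $p \sim
  \mathrm{Dirichlet}(\alpha)$ with $\alpha_r = \pi_r(1-\theta)/\theta$
  (the standard over-dispersion parameterization; $\theta \to 0$ recovers
  the multinomial), then counts $\sim \mathrm{Multinomial}(N_i, p)$.
* **Signal OTUs**: the tree's leaves are partitioned into 20 clusters by
  PAM on the cophenetic distance. Scenario I picks every OTU of the
  cluster at a given total-abundance rank (default rank 2 for the
  abundance model A, rank 8 for the presence model B); scenario II picks
  the top OTU of each of 9 distinct clusters in descending abundance;
  scenario III combines one related and one unrelated set (disjoint by
  construction). Clusters are ranked by the *baseline* proportions
  $\pi$, so the signal set is a fixed property of the parameter set and
  identical across all replicates of a configuration.
* **Outcome**: model A uses
  $\operatorname{logit} E(y_i) = \beta \cdot
  \mathrm{scale}(\sum_{\ell \in G} p_{i\ell})$, model B the same with
  presence indicators $I(p_{i\ell} > 0)$; scenario III uses two-term
  combinations with $(\beta_1, \beta_2)$. `scale()` standardizes over the
  generated pool (prospective standardization), labels are Bernoulli
  draws, and exact case/control balance is achieved retrospectively by
  oversampling a pool (initial factor 3, doubling up to 100× the target)
  and subsampling $n/2$ per class without replacement.

The default parameter set is a synthetic stand-in for parameters estimated
from a real upper-respiratory-tract dataset (which ships with external
software and is loadable via `load_dm_parameters()` for exact
replication): a random coalescent tree with $q = 856$ leaves, baseline
proportions from a log-normal with $\sigma_{\log} = 2$ normalized to sum 1
(a realistic rank-abundance skew), and $\theta = 0.02$.

**What passing tests show — and what they do not.** The synthetic defaults
reproduce the broad structure of real 16S data (over-dispersed counts,
heavy-tailed abundances, tree-clustered signal) but not its estimated
parameters: quantitative AUC tables obtained under the synthetic defaults
are indicative, not replications. Features of real data that the
generator does not emulate include taxon-specific dispersion, correlated
noise beyond the single Dirichlet $\theta$, batch effects, and
compositional artifacts of variable sequencing depth beyond the negative
binomial totals. One consequence observed in development: under the
presence-signal model B the margin between the presence kernels
(unweighted UniFrac, Hamming) and the abundance kernels is narrower under
the synthetic defaults than the clear separation reported with estimated
parameters, because presence and abundance of log-normally distributed
clades are strongly coupled.

## Numerical choices and conventions

| Quantity | Convention | Why |
|---|---|---|
| $\sigma$ | mean of strict upper-triangle training distances | self-distances would bias it down |
| $a_r$ normalization | mean 1 | provably inert; reproducible convention |
| p-value floor | $10^{-300}$ | keeps $-\log_{10}$ finite |
| zero-denominator UniFrac pair | distance 0 | two empty samples are identically empty |
| $\rho = 0$ ties | uniform over argmax kernels | deterministic, symmetric |
| CV ties | largest $\rho$ | flatter weights, more stable |
| separation | $\|\beta_1\|$ clamped at 30 | bounded probabilities, warning |
| both-groups zero variance | $t = 0$, $p = 1$ (warning) | degenerate tests carry no usable signal |
| all-zero samples | kept as zero rows, warning | visible rather than silently dropped |

Degenerate inputs fail loudly: single-class labels, zero-variance
covariates, an all-zero distance matrix (bandwidth would be 0), misaligned
feature ids between boosting weights and data, and empty OTU overlap
between a test table and the training space are all errors.

## Problem sizes used by the checks

The long-running checks in the test suite use sizes chosen to make their
statistical claims at desk scale: the null-behavior check runs 50
replicates at $n = 200$, $q = 120$ (the null AUC band is dimension-free);
the signal-attribution check runs 50 replicates per outcome model at the
full $n = 500$, $q = 856$ with fixed $\rho = 1$, which is exact for the
argmax-weight statistic because weight order is invariant to $\rho$. The
oracle-AUC check uses the standard-normal surrogate for the standardized
signal predictor with 1000 balanced testing sets of 500.

## Known limitations

* Binary outcomes only; continuous outcomes would require a kernel
  regression head.
* The Gaussian kernel is the only covariate kernel form implemented.
* Kernel weights from the entropy objective are dense ($w_l > 0$ for
  $\rho > 0$); the method ranks signal forms rather than selecting them.
* With small training sets the boosting weights are noisy; the
  cross-validated $\rho$ then tends towards uniform weights, which is the
  intended safeguard.
* PAM clustering of very large trees costs $O(q^2)$ memory for the
  cophenetic matrix.
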