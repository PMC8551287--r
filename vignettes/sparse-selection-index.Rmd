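---
title: "Sparse selection indices for multi-generation genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse selection indices for multi-generation genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Breeding programs accumulate genotype/phenotype data over cycles
(years).  Training a genomic prediction model on all of it is not always
best: allele frequencies and linkage-disequilibrium patterns drift
between generations, so marker effects estimated on old material may not
transfer to current selection candidates.  A *sparse selection index*
(SSI) addresses this per individual: instead of one training set for
everybody, each candidate gets its own set of "support" individuals —
training lines with a non-zero weight in its prediction equation —
selected automatically by an L1 penalty.

`ssindex` implements the full workflow: dominant-marker QC, adjusted
phenotypes (BLUEs) from incomplete-block trials, additive and Gaussian
kernels, variance components, BLUP and SSI prediction with
cross-validated penalty selection, scenario-based evaluation, and a
doubled-haploid (DH) population simulator that makes every part testable
without external data.

## Models

**GBLUP.** With centered phenotypes $y = u + \varepsilon$,
$u \sim N(0, \sigma_u^2 G)$, $\varepsilon \sim N(0, \sigma_\varepsilon^2 I)$,
where $G = ZZ'/p$ and $Z$ is the column-centered and scaled marker
matrix.  Predictions for a prediction set (PS) from a training set (TS)
are $\hat u_{PS} = B\, y_{TS}$ with the Hat matrix

$$B = G_{PS,TS}\,(G_{TS} + \lambda_0 I)^{-1}, \qquad
  \lambda_0 = \sigma_\varepsilon^2 / \sigma_u^2 .$$

**RKHS / KBLUP.** The same with $G$ replaced by a Gaussian kernel
$K_{ij}(\theta) = \exp(-\theta\, \tilde d^2_{ij})$, where
$\tilde d^2_{ij}$ is the squared Euclidean distance between the raw 0/1
marker rows divided by its average over all $n^2$ ordered pairs
(diagonal included), so $\tilde d^2$ has mean exactly 1.  Bandwidths
$\theta \in \{0.2, 1, 5\}$ give progressively more "local" kernels.  A
*kernel average* $K_A = \sum_k (\sigma^2_{a_k}/\sigma^2_a) K_k$ weights
the three kernels by their estimated genetic variances.

**SSI.** Row $i$ of the sparse Hat matrix solves

$$\tilde b_i(\lambda) = \arg\min_b\; \tfrac12 b'(K_{TS} + \lambda_0 I)b
  - g_i'b + \lambda \lVert b\rVert_1 ,$$

with $g_i$ the similarities of prediction individual $i$ to the TS.
$\lambda = 0$ recovers the BLUP row; $\lambda \ge \max_j |g_{ij}|$ gives
the zero row.  Rows are independent problems and may be solved in any
order or in parallel with identical results.

## The solver

The problem is a lasso in "covariance" (Gram) form and is solved by
cyclic coordinate descent with soft-thresholding
($b_j \leftarrow S(g_j - \sum_{k\neq j} C_{jk} b_k, \lambda)/C_{jj}$),
warm starts along a descending $\lambda$ grid, and active-set iteration
(one full sweep, then sweeps over the non-zero set, then a full
verification sweep).  Implementation notes:

* A running product $Cb$ makes each coordinate update $O(n)$.
  Coordinate changes below 1% of the tolerance defer the $O(n)$ update;
  the accumulated deferred mass is bounded and $Cb$ is refreshed exactly
  before it can affect convergence decisions.  This matters on
  family-structured kernels, where the dense end of the path otherwise
  dominates runtime.
* Convergence is declared when the maximum absolute coefficient change
  in a deferral-free full sweep falls below `tol`.  Defaults are
  `tol = 1e-5`, `maxit = 5000` sweeps per $\lambda$; the evaluation
  layer uses `1e-4`, the scale used by standard lasso software.  Every
  returned solution can be certified independently by `kkt_check()`
  (stationarity of the subgradient at `1e-6` on small instances).
* $\lambda = 0$ is solved exactly by Cholesky — the objective is smooth
  there and the minimizer is the BLUP row — rather than by iterating
  coordinate descent to machine precision.
* The default grid is geometric from $\lambda_{\max}$ down to
  $10^{-3}\lambda_{\max}$ with $\lambda = 0$ appended.

## Penalty selection

`cross_validate_lambda()` does 10-fold cross-validation within the
training set: each fold in turn becomes a pseudo-prediction set, its SSI
paths are solved on a *relative* grid (fractions of the fold problem's
$\lambda_{\max}$, so grid indices are comparable across folds), and the
fraction maximizing the mean held-out correlation is selected; exact
ties break to the sparsest penalty.  The study this package follows
reports a single tuned penalty per training-set composition, so
`run_experiment()` offers `cv_reuse = "scenario"` (tune once on the
first partition's training set, reuse for the other partitions) next to
the exhaustive `"training-set"` mode; the former costs a small fraction
of the latter and is used in the acceptance experiments.

## Variance components

For centered phenotypes there are no fixed effects, so REML and maximum
likelihood coincide: `reml_single_kernel()` eigendecomposes $K$ once and
does a 1-D search over $h^2$, profiling out the scale.  Reported
quantities are $\sigma_u^2$, $\sigma_\varepsilon^2$,
$\lambda_0 = \sigma_\varepsilon^2/\sigma_u^2$ and
$h^2 = \sigma_u^2/(\sigma_u^2+\sigma_\varepsilon^2)$.  The estimates are
invariant (as a covariance model) to scalar rescaling of $K$.

`gibbs_multi_kernel()` fits $y = u_1 + u_2 + u_3 + \varepsilon$ for
kernel averaging with scaled-inverse-$\chi^2$ priors, df = 5, scales set
so each genetic term's prior mode explains an equal share of half the
sample variance (the residual mode explains the other half), mirroring
common Bayesian genomic-prediction defaults; defaults are 12000
iterations with 2000 burn-in.  A caveat established by the tests: the
two wide-bandwidth kernels ($\theta = 0.2, 1$) are more than 99%
collinear on realistic marker panels, so only their *sum* — and the
contrast with the local kernel ($\theta = 5$) — is identifiable.
Kernel-average weights should be read accordingly.

## Phenotype adjustment

Plot-level records from alpha-lattice trials are adjusted with

* multi-location: $Y = \mu + G + L + R(L) + B(RL) + (G{\times}L) + e$
* single-location: $Y = \mu + G + R + B(R) + e$

with genotype, location, replicate and $G{\times}L$ fixed and the
incomplete block random.  Because every record belongs to exactly one
block, $V = \sigma_e^2 I + \sigma_b^2 ZZ'$ is block diagonal and REML
reduces to a 1-D profiled likelihood in $\gamma = \sigma_b^2/\sigma_e^2$
(searched on the log scale, tolerance 1e-8); whitening by $V^{-1/2}$ is
a closed-form shrinkage of each block mean.  Fixed effects use
sum-to-zero contrasts, so the adjusted phenotype $\hat\mu + \hat G_i$ is
invariant to relabeling of locations, replicates and blocks; adjusted
values may still differ from another software's output by an additive
constant, which is irrelevant to correlation-based accuracy.
Inestimable $G{\times}L$ cells in incomplete designs are dropped
(coefficient 0) with a warning.  A genotype seen in a single plot still
receives a value, with a larger reported standard error.

## Marker QC

Dominant markers (0 = band absence, 1 = presence) are screened against
an expected 3:1 presence:absence segregation ratio with a 1-df
chi-square goodness-of-fit test (an exact binomial option is provided),
Benjamini–Hochberg adjusted at FDR 5%, then filtered at MAF < 0.05 with
MAF defined on presence frequency (only presence/absence is observable
for dominant calls).  Both criteria are recorded for every marker; a
low-MAF marker is labeled `maf` even when also distorted, since the MAF
rule removes it regardless.

## The simulator

`simulate_population()` emulates a multi-cycle DH program: founder
inbreds are Bernoulli 0/1 vectors; each biparental family contributes DH
lines that are single F1 gametes doubled, with recombination along a
genetic map under the Haldane model (no interference, Markov chain per
chromosome).  The default map stand-in is 10 chromosomes × 1 Morgan with
equally spaced markers — the real marker platform's map is unknown, so
no claim is made that this matches it.  Cross-cycle structure comes from
founders shared between cycle pools; trait heterogeneity from per-cycle
QTL effect vectors drawn jointly normal with pairwise correlation
$\rho_g$ (1 = homogeneous, 0 = independent effects per cycle).  Residual
noise is calibrated per cycle from the empirical variance of the true
breeding values so the realized within-cycle $h^2$ matches the target in
expectation; per-cycle intercepts default to 0 (accuracy is
correlation-based and intercept-invariant).  `simulate_trial()` lays the
population out in a location × replicate × incomplete-block design with
independent normal location, replicate, block, G×L and residual effects.

What a green test on simulated data does *not* establish: real
rAmpSeq-style panels have unknown LD structure, selection (the real
germplasm was phenotypically pre-selected), dominance/epistasis, and
genotype-by-year variation — none of which are modeled.

### The benchmark world

The stochastic acceptance experiments freeze one "stated world": 4
cycles × 8 biparental families × 50 DH from 16 founders per cycle, 3
founders carried between consecutive cycles (mirroring a program of many
mostly-unrelated biparental families connected by a few shared elite
parents); 600 loci of which the 100 QTL are *excluded* from the observed
marker panel, so anonymous dominant markers tag QTL only through family
LD; $\rho_g = 0.3$, $h^2 = 0.5$; training on cycles 1–3 plus 15% of
cycle 4 (n_TS = 1260), predicting the remaining 340 cycle-4 lines over
30 paired partitions.  Under these conditions the additive-kernel SSI
beats GBLUP by a few accuracy points with a support of roughly a fifth
of the training set, and the cross-validated penalty is positive —
computed afresh by `tests/testthat/test-acceptance.R` on every run.

### A limitation surfaced by the homogeneous control

With $\rho_g = 1$ and a single founder pool, sparsity has no
population-level signal to exploit: in the frozen benchmark the
control's cross-validation selects $\lambda_{CV} = 0$, so the SSI
reduces exactly to GBLUP and the paired difference is identically zero.
In other population draws, however, random k-fold CV *within* a
family-structured training set can prefer a small positive penalty even
under homogeneous effects: fold members are predicted mostly from their
full sibs, so discarding distant lines costs little in-fold, while the
actual prediction set (new families of the next cycle) has few sibs in
the training set and can lose a couple of accuracy points from the same
sparsity.  The one-sided statement — sparsity does not *help* under
homogeneity — held in every draw examined; the selected penalty being
exactly zero did not.  Practically: tune $\lambda$ with family- or
generation-aware folds if in-fold relatives are not representative of
the prediction task.

## Evaluation conventions

* The prediction cycle is split 85–15 by withholding
  $\lceil 0.15\,n\rceil$ lines; augmentation adds
  $\lceil f\,n\rceil$ of the withheld lines ($f \in \{0.05, 0.10,
  0.15\}$) to the training set.  Ceiling rounding reproduces the
  published counts (a 486-line cycle gives 413 predicted and 25/49/73
  augmentation lines; all twenty published n_TS values follow).
* Augmentation subsets are nested within a partition (5% ⊂ 10% ⊂ 15%),
  so augmentation curves are comparable.
* All models within a partition see identical training/prediction sets
  (paired comparisons); variance components are re-estimated on each
  realized training set.
* Accuracy is $\rho = \mathrm{cor}(y_{PS}, \hat u_{PS})$; gains are
  percentage changes, kernel-vs-additive (Gain 1) and sparse-vs-dense
  (Gain 2); the sparsity summary is $n_{sup}$ (mean support size) and
  $\%\text{sparsity} = 100\, n_{sup}/n_{TS}$.
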