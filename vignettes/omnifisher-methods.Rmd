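---
title: "Gene-level multi-omics association testing: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-level multi-omics association testing: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`omnifisher` tests, gene by gene, whether a trait is associated with *any*
of up to three omics layers measured on the same study — SNP genotypes
(G), DNA-methylation M-values (M) and RNA expression (E) — and combines
the three layer-level p-values into one gene-level p-value that accounts
for the correlation between layers.  This vignette is the package's own
account of the statistical model, the numerical algorithms, and every
design decision a maintainer might want to revisit.

## 1. The kernel-machine score test per layer

For one gene and one layer with feature matrix $D$ ($n$ subjects by $m$
features) the trait model is

$$y = X\beta + D\gamma + \varepsilon \qquad \text{or} \qquad
\operatorname{logit} P(y = 1) = X\beta + D\gamma,$$

with covariates $X$ (an intercept is always enforced) and random feature
effects $\gamma_j \sim N(0, \tau w_j)$.  The null $\gamma = 0$ is
equivalent to $\tau = 0$ and is tested by the variance-component score
statistic

$$Q = \frac{(y - X\hat\beta)' D W D' (y - X\hat\beta)}{\hat\sigma_E^2}
\quad \text{(continuous)}, \qquad
Q = (y - \hat\mu)' D W D' (y - \hat\mu) \quad \text{(binary)},$$

computed entirely under the null model (`fit_null()`).  Under $H_0$,
$Q \sim \sum_i \lambda_i \chi^2_{1,i}$ where $\lambda_i$ are the positive
eigenvalues of $P_0^{1/2} D W D' P_0^{1/2}$, with
$P_0 = I - X(X'X)^{-1}X'$ for continuous traits and
$P_0 = \hat\Sigma - \hat\Sigma X (X'\hat\Sigma X)^{-1} X'\hat\Sigma$,
$\hat\Sigma = \operatorname{diag}(\hat\mu(1-\hat\mu))$, for binary traits.

**Eigenvalue/statistic pairing.** A point that is easy to get wrong: for
continuous traits the $1/\hat\sigma_E^2$ factor inside $Q$ already cancels
the residual variance carried by $y - X\hat\beta$ (whose null covariance is
$\sigma^2 P_0$), so the correct null weights are the eigenvalues of
$P_0 D W D' P_0$ **unscaled**.  Dividing the eigenvalues by
$\hat\sigma_E^2$ as well is only correct when $\operatorname{Var}(y) = 1$
and produces anti-conservative p-values otherwise; during development this
surfaced as a 20% inflated continuous Type I error with simulated traits of
variance 1.2, diagnosed against exact permutation moments and a dense
oracle.  The package therefore uses the unscaled pairing.

**Computation.** The eigenvalues are obtained from the $m \times m$ dual
matrix $W^{1/2} D' P_0 D W^{1/2}$ (same nonzero spectrum), so no
$n \times n$ factorization is ever needed for the test itself; $P_0$
products are matrix-free.  Eigenvalues below $10^{-10} \lambda_{\max}$ are
dropped as numerical rank control.  Explicit eigenvectors (needed only for
perturbation across layers with *different* null models) are materialized
on demand: for continuous traits $P_0^{1/2} = P_0$ (idempotent); for
binary traits via a cached symmetric eigendecomposition of $P_0$ with
negative eigenvalues clamped to zero.

**Degenerate inputs.** A residual vector that is exactly zero (perfect
null fit) gives $Q = 0$ and $p = 1$; a zero feature matrix likewise.
Dosage (non-integer) genotypes in $[0, 2]$ are accepted.  Weights $w_j$
default to 1 (`W = I`).

## 2. Tail probabilities of the chi-square mixture

`mixture_chisq_pvalue()` evaluates
$p = P(\sum_i \lambda_i \chi^2_{1,i} > Q)$:

* **Single or equal eigenvalues** are a scaled chi-square, evaluated
  exactly (`method = "exact"`).
* Otherwise the characteristic function is inverted numerically (the
  Davies approach): the oscillatory integrand
  $\sin(\theta(u)) / (u \rho(u))$ is integrated by composite Simpson with
  an embedded half-grid error estimate, grid-doubling until the estimate
  is stable at the target accuracy (default $10^{-9}$), and an analytic
  truncation point.  Two truncation bounds are used: the absolute envelope
  bound (effective for many or large eigenvalues) and an
  integration-by-parts bound for the oscillatory tail (effective for few
  eigenvalues, where the envelope decays slowly).  A total
  integration-term limit of $10^6$ caps the work.
* The **Kuonen saddlepoint** approximation (Lugannani–Rice form) takes
  over when the required number of terms exceeds the limit, when the
  inversion result falls outside $[0, 1]$, when the statistic is far below
  the null mean ($Q < 0.05 \sum \lambda$, where the truncation bounds are
  unattainable and $p$ is near 1), and for $p < 10^{-6}$, where an
  absolute-accuracy inversion loses relative precision but the saddlepoint
  remains tail-accurate.
* Results are clipped to $(10^{-300}, 1]$.

Perturbation batches (Section 4) reuse one eigenvalue set for hundreds to
tens of thousands of statistics; these are evaluated on a shared grid at a
relaxed absolute accuracy ($3 \times 10^{-7}$), and batches of 150+
statistics interpolate the smooth monotone map $Q \mapsto \log p$ through
a monotone (Hyman) spline on 129–257 inversion nodes.  Observed p-values
always use the full-accuracy path.

## 3. Covariance-adjusted Fisher combination

With layer p-values $p_1, \dots, p_w$ ($w \le 3$), Fisher's statistic
$T = -2 \sum_i \ln p_i$ has $E(T) = 2w$ and, allowing correlation,
$\operatorname{Var}(T) = 4w + 2\sum_{i<j}
\operatorname{cov}(-2\ln p_i, -2\ln p_j)$.  A Satterthwaite approximation
matches $cT$ to $\chi^2_v$ with $v = 2[E(T)]^2/\operatorname{Var}(T)$ and
$c = v/E(T)$; the generally fractional degrees of freedom are evaluated
through the gamma$(v/2,\ \text{scale } 2)$ survival function.  Design
points:

* Diagonal covariance entries are fixed at 4 (the variance of $-2\ln U$
  for uniform $U$) regardless of the estimate.
* Estimated negative covariances are retained (clamping them would bias
  the estimator), but $\operatorname{Var}(T)$ is floored at $0.1 \cdot 4w$
  with a warning so $v$ stays valid.
* p-values are floored at $10^{-300}$ before the logarithm.
* With zero off-diagonal covariance the combination reduces exactly to
  classical Fisher ($c = 1$, $v = 2w$); with $w = 1$ it is the identity.

The *usual* (uncorrected) Fisher combination, $T \sim \chi^2_{2w}$, is
provided for comparison; on correlated layers its Type I error is
inflated, which the simulation harness reproduces.

## 4. Perturbation: shared draws, covariance, and the optimal test

The covariance of $-2\ln p$ across layers is estimated by perturbing the
score statistics: conceptually, one standard-normal draw per subject
(shared across layers, so subjects carrying several layers induce the
cross-layer correlation) is rotated by each layer's eigenvectors $V_l$,
giving $Q_l^{(b)} = r_l^{(b)\prime} \Lambda_l r_l^{(b)}$ and p-values
$p_l^{(b)}$ from the same mixture law as the observed statistic.

**Implementation.** The stacked rotated vector
$s = (V_G'r, V_M'r, V_E'r)$ is exactly $N(0, \Gamma)$ with $\Gamma$ the
cross-layer eigenvector Gram matrix, so the package samples $s$ directly
through the symmetric square root of $\Gamma$ — distribution-identical to
drawing $r$ per subject, and far cheaper.  When all layers share one null
model, $\Gamma = C' P_0 C$ for precomputed $n \times m$ blocks $C$, so
the whole perturbation needs no $n \times n$ factorization; with
different null models or subject sets the explicit eigenvectors are
embedded in the union subject space (entries zero for subjects missing a
layer) and the two routes agree (this is tested).  The symmetric square
root preserves the shared-draw contracts exactly: duplicated layers
receive identical perturbed p-values, and results are invariant to layer
processing order (layers are canonicalized to G, M, E internally).

**Covariance estimation** uses $B_{\text{cov}} = 200$ draws by default,
with the observed p-values included as iteration $b = 0$ (a config switch
`include_observed` controls this).  Degenerate (constant) columns get
zero covariance with a warning.  Pairwise combinations use sub-blocks of
the 3×3 estimate rather than re-estimated pairwise covariances.

**The optimal test** computes, for the observed iteration and every
perturbed iteration, the combined p-values of all nonempty layer subsets
(G, M, E, GM, GE, ME, GME — fewer when layers are missing), takes
$p^{(b)} = \min_{l^*} p_{l^*}^{(b)}$, and estimates the final p-value by

$$\hat p = \frac{1 + \sum_{b=1}^{B} I(p^{(b)} \le p^{(0)})}{1 + B},$$

the standard resampling correction that keeps $\hat p$ strictly positive
(resolution $1/(B+1)$).  The covariance used inside each stage is
estimated from that stage's own draws.  `run_gene()` escalates $B$
stepwise (default 1,000 → 10,000 → 100,000) while $\hat p < 10/B$, so
computation concentrates on genes with small p-values; the simulation
harnesses use a single 1,000-draw stage, which suffices for rejection
decisions at $\alpha \ge 0.01$.

Per-gene random substreams are derived from `(seed, gene_id)` so results
are reproducible regardless of gene execution order.  The binary-trait
perturbation uses the identical standard-normal scheme as the continuous
case; this is justified because the binary $Q$ is the same quadratic form
with $\hat\Sigma$ absorbed into $P_0$.

## 5. The synthetic-data generator

The simulation study draws per-gene datasets (50 SNPs, 5 CpGs, 1
expression value) from three pools that emulate the structure — not the
content — of real panels: a coalescent-style haplotype panel, an array
methylation study, and an expression panel.  The pools are parametric
emulators; what they are built to reproduce is the *null structure* that
drives Type I error (marginal scales, within-gene correlation, and the
genotype–expression coupling) and an interior-power operating regime at
the generating models' fixed effect sizes.

* **Haplotypes** (10,000 over a 200-kb-like region): thresholded
  stationary AR(1) latent Gaussians with adjacent-site liability
  correlation 0.95, so allelic $r^2$ decays geometrically with distance
  (realistic LD blocks); site frequencies are log-uniform on
  $[0.002, 0.5]$ (rare-skewed, coalescent-like) and coded to minor
  alleles.  An earlier founder-copying design was abandoned because
  independently drawn founder alleles yield near-zero inter-site LD.
* **Methylation**: per-CpG methylation levels from a hypo/hyper
  two-component mixture (beta fractions 0.05–0.3 and 0.7–0.95), with
  within-CpG beta variation at concentration 1,500 — per-CpG M-value sd
  near 0.1, typical of array methylation in blood — coupled through a
  Gaussian copula with correlation 0.6 inside 5-CpG blocks.
* **Expression**: normal on the log scale; gene means around the global
  mean 7.45 (sd 0.4), within-gene sd 0.2; the pool is recentered so its
  grand mean is exactly 7.45.

**Phenotype models.** Binary traits use
$\operatorname{logit} P(y=1) = -2.94 + 0.001 X_1 + 0.001 X_2 +
\text{(causal terms)}$ with $X_1 \sim N(20, 1)$,
$X_2 \sim \text{Bernoulli}(0.5)$; $-2.94 = \log(0.05/0.95)$ encodes a 5%
prevalence.  Subjects are drawn until 500 cases and 500 controls accrue,
keeping the first of each in draw order.  Continuous traits use the same
linear predictor without intercept plus standard-normal error, with
$n = 1000$ (matching the binary sample size; the original design states
only the binary one).  Causal effects are 0.3 per allele when G alone is
causal, otherwise 0.2; 0.9 per causal CpG; 1 per expression unit centered
at the pool mean.  Causal SNPs are redrawn per dataset: the first
(anchor) causal SNP is a common variant (MAF at least 0.2) — in the
coupled setting it doubles as the gene's eQTL, and eQTLs are typically
common — while the remaining four come from the low-frequency band
(MAF 2–10%); under LD, five common causal SNPs would drive gene-level
power to 1 at these effect sizes, while this mix keeps power interior so
the method comparisons are informative.  Causal methylation
contributions are centered at their pool means — the analogue of the
expression term's centering at 7.45 — because CpG-level M-value offsets
are bimodal around $\pm 3$ and uncentered contributions would push the
binary prevalence outside any samplable range.

**G–E coupling.** In the correlated setting the expression value is the
pool value plus the first causal SNP's genotype, $E^* = E + G_1$, making
the G and E layers dependent even under a permuted (null) trait — the
device that exposes the usual Fisher combination's inflation.

**Null datasets** are produced by permuting the traits of causal datasets
(10 permutations per dataset), which preserves every omics marginal and
the coupling exactly while breaking the trait association.

**What passing tests do and do not show.** The emulator reproduces the
qualitative regime: calibrated corrected tests, inflated usual Fisher
under coupling, and the power orderings (optimal wins when G alone is
causal, the regular combination wins when all layers are).  Absolute
power values and the exact magnitude of the inflation depend on pool
dispersions and LD that real data fix externally, so those numbers should
be read as regime-level, not quantitative, statements about any real
cohort.  Real-data features the generator does not emulate include
population structure and ancestry confounding, batch and cell-type
composition effects, missing-at-random patterns within layers, and
count-based RNA-seq noise.

## 6. Simulation harnesses and problem sizes

`type1_harness()` and `power_harness()` run the three methods (optimal
Omnibus-Fisher, regular Omnibus-Fisher, usual Fisher) over replicate
datasets and report rejection rates with binomial standard errors;
resolution warnings fire when `alpha < 10 / n_datasets`.  The package's
own acceptance checks use desk-scale replicate counts — 2,000 null
datasets at $\alpha = 0.05$ (5,000 at $\alpha = 0.01$), 500 power
datasets, covariance draws $B_{\text{cov}} = 200$, optimal-test
$B = 1000$ — scaled down from the original 10,000-replicate design; the
binomial acceptance bands are computed at these sizes.

## 7. Known limitations

* Unrelated subjects only; no mixed models, survival outcomes, or
  covariate imputation.
* The analytic mixture null assumes the score's quadratic-form normal
  approximation; heavily non-normal continuous traits (strong skew or
  kurtosis) make all kernel score tests of this family anti-conservative.
* The optimal test's resolution is bounded by $1/(B+1)$; genome-wide
  significance claims need the escalated stages, at corresponding cost.
* The Satterthwaite-adjusted combination is a two-moment approximation
  with a noisily estimated covariance (B = 200 draws); deep in the tail
  and under strong inter-layer correlation it runs slightly above nominal
  — visible in the package's own 0.01-level calibration check under G–E
  coupling, and in the nature of the approximation itself.
* Negative estimated covariances are handled by a variance floor rather
  than a formal positive-definite projection.
* The gene–feature annotation is taken as given; positional assignment of
  features to genes is out of scope.
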