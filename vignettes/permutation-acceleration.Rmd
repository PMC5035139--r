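---
title: "Accelerated permutation inference for the GLM: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accelerated permutation inference for the GLM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permaccel)
```

## The model and the reference procedure

At each of V tests (voxels of an image, or columns of a data matrix) we
consider the general linear model

$$ Y = M\psi + \epsilon, $$

with $N$ observations, an $N \times R$ full-rank design $M$, and the
null hypothesis $H_0 : C'\psi = 0$ for a full-rank $R \times S$
contrast $C$. The model is transformed into the equivalent partitioned
form $Y = X\beta + Z\gamma + \epsilon$, with $X$ spanning the contrast
space, $Z$ the nuisance space, and $X'Z = 0$; inference on $\beta$ is
then inference on $C'\psi$. The partitioning is not unique: we use the
contrast-conformant projection $X = M (M'M)^{+} C$ with $Z$ an
orthonormal basis of the residual column space of $M$. Only invariants
are guaranteed (identical statistics from the original and partitioned
forms, verified in the test suite), never particular basis vectors. A
useful consequence of this construction: whenever the model contains an
intercept that the contrast does not touch, the partitioned $X$ has
exactly zero column means — which is what the no-permutation method
below requires.

A pivotal statistic $T$ (t, F, Pillai's trace, Wilks' $\lambda$, or an
NPC combination) is computed for the observed data and for $J - 1$
random rearrangements — permutations of observations (exchangeable
errors, EE), sign flips (independent symmetric errors, ISE), or both —
and the p-value is the inclusive counting estimate
$p = J^{-1} \sum_j I(T^*_j \ge T)$, the unpermuted case always counted
as rearrangement 1. Rearrangements are drawn independently (duplicates
allowed; exhaustive enumeration replaces sampling automatically
whenever all unique rearrangements fit in the request). Nuisance
handling follows the Freedman–Lane scheme by default; Manly and
Draper–Stoneman are available. For the t statistic all three are
evaluated through the factorisation
$T = \kappa B \odot \Sigma^{[-1/2]}$, where $B$ is a product of a
$J \times N$ rearrangement-operator matrix and an $N \times V$ data
matrix, $\Sigma$ holds residual sums of squares obtained by projection
onto the model's orthonormal basis, and
$\kappa = (X'X(N - \mathrm{rank}\,M))^{1/2}$. This is algebraically
identical to refitting the model per rearrangement (tested against a
naive refit) and is what makes both large-J runs and the low-rank
accelerator below practical.

## The six acceleration strategies

**Few permutations.** Plain counting with small $J$. Exact at
attainable levels; the price is a wide Wilson interval around each
p-value and hence a higher resampling risk (the probability that a
repetition reaches a different accept/reject decision).

**Negative binomial.** Each test runs until $n$ exceedances
$T^*_j \ge T$ have occurred; then $\hat p = n/j$. The unpermuted case
counts both as the first rearrangement and as one exceedance of itself,
so the estimate reduces to the counting one when the cap $J_{cap}$
(default 50000) is reached first. This convention makes $\hat p$ carry
a small $O(p(1-p)/n)$ upward bias relative to the classical unbiased
$(n-1)/(j-1)$; validity ($P(\hat p \le \alpha) = \alpha$) is what
matters and is verified by simulation. Weak effects stop after a few
rearrangements; only still-active tests are recomputed, which is the
source of the acceleration. Spatial statistics cannot be combined with
per-test stopping; for familywise error a separate workaround stops
when the image-wise extremum has beaten the unpermuted extremum $n$
times (ties count as exceedances) and adjusts all tests by the maxima
collected so far — with the caveat that every test then depends on the
single most extreme unpermuted voxel.

**Generalised Pareto tail.** Tests whose counting p-value falls below
`refine_below` (default 0.10, i.e. twice the usual $\alpha$) have the
tail of their permutation distribution refined. Exceedances
$y = T^*_j - u$ over the threshold $u$ at the upper quartile are fitted
by the method of moments,
$\hat\xi = (\bar y^2/s^2 - 1)/2$,
$\hat\sigma = \bar y(\bar y^2/s^2 + 1)/2$ (the $(n-1)$-denominator
variance; the estimators are denominator-sensitive), and the fit is
accepted when the Anderson–Darling p-value is at least `alpha_ad`
(default 0.05). On rejection the smallest 10% of the current
exceedances are discarded — raising $u$ — down to a floor of 10
exceedances, after which the counting p-value is returned unchanged.
An accepted fit gives
$p = (n_{exceed}/J_{eff}) \,(1 - F(T - u))$, continuous with the
counting tail mass at $T = u$. The iteration schedule and the AD level
are our choices (both configurable); the AD null distribution for
moment-estimated parameters has no closed form, so the critical-value
table frozen in the package was calibrated by Monte Carlo (20000
replicates per shape value, 100 exceedances per sample; the generating
script ships under `tools/`).

**Gamma (Pearson III) approximation.** The first three moments of each
test's permutation distribution are matched by a shifted (and for
negative skew, mirrored) gamma: shape $4/\gamma^2$, scale
$\sqrt{v}\,\gamma/2$, location $m - 2\sqrt{v}/\gamma$. The skewness
estimator is the adjusted Fisher–Pearson one, because $J$ is small.
Statistics outside the fitted support are clipped to 1 or $1/J$
according to the skew direction. A known structural limitation,
quantified in the tests: a three-moment fit carries no kurtosis, so for
a near-symmetric t-like null its tail decays like a normal and p-values
below roughly 0.01 are underestimated relative to a counting reference
(median agreement within a factor of two; rank agreement above 0.9).
The tail approximation does not share this limitation and is the
recommended default when correctness deep in the tail matters.

**No permutation (analytic moments).** Pillai's trace can be written as
$T = \mathrm{trace}(AW)$ with $A = H_X$ and $W = UU'$, both symmetric
with mean-centered columns provided the intercept lives entirely in $Z$
and $X$ is centered. The first three moments of $T$ over all $N!$
permutations are then available in closed form under symmetric errors,
a Pearson III distribution is fitted to them, and the one-sided p-value
follows by halving the upper-tail value (and subtracting from one when
$\hat\beta < 0$; a zero coefficient counts as positive). Rather than
transcribing closed-form moment expressions from the literature, the
package computes them exactly by Möbius inversion over the
index-coincidence patterns (set partitions) of the defining sums — a
polynomial-cost computation whose correctness is gated entirely on an
exhaustive-enumeration oracle for $N \le 7$, where it agrees to
machine precision, including for general (non-projector) symmetric
matrices. For the rank-one $W$ of a univariate test, the pattern sums
reduce to power sums of the residualized response, making the per-test
cost a few thousand floating-point operations. The method produces
uncorrected p-values only (the extremum statistic is not of the form
$\mathrm{trace}(AW)$), approximates permutations proper (not sign
flips), and must not be trusted under skewed errors.

**Low-rank matrix completion.** $B$ has rank at most $N$ and $\Sigma$
at most $N(N+1)/2$, so after an initial $J_0 = N(N+1)/2$ fully sampled
permutations provide SVD row-space bases, every further rearrangement
needs only $v \ge v_0 = N(N+1)/2$ randomly sampled tests; the rest of
the row is recovered *exactly* by projection
($\beta_j = \tilde\beta_j \tilde U^{+} U$). The column mean of
$\Sigma_0$ is removed before the SVD and added back after recovery, to
limit sign-ambiguity effects in a strictly positive matrix. The initial
$J_0$ rows are revisited through completion so all rearrangements are
treated equally, and the full $J \times V$ matrix is never stored —
rows update counters and maxima and are discarded. Sampled index sets
are redrawn for every rearrangement. Completion requires
$\min(J, V) > v_0$ and is available for the t statistic only;
sampling below $v_0$ is allowed only behind an explicit
`allow_approximate` flag, as error rates are then not controlled.
Exactness (relative error below $10^{-8}$ against brute force, in
practice $10^{-13}$) is asserted for all three shuffling strategies.

## Spatial statistics and multiplicity

Cluster extent and cluster mass are computed over connected components
of suprathreshold voxels (26-connectivity by default; 6 and 18
available), and TFCE as the per-voxel integral
$\int e(h)^E h^H\,dh$ with the standard volumetric defaults $H = 2$,
$E = 0.5$, $dh = \max(T)/100$. Cluster mass is pinned as the sum of the
suprathreshold statistic values themselves (not the excess over the
threshold). Negative contrasts are handled by transforming the negated
map separately. All spatial statistics are recomputed on every
rearrangement's map, and cluster-level inference is corrected: each
observed cluster is compared with the permutation distribution of the
image-wise maximum cluster statistic. Only corrected cluster p-values
are exposed, as uncorrected per-cluster values have no clean
interpretation in this framework.

Familywise error is controlled through the distribution of the
image-wise extremum, optionally refined by a single GPD or Pearson III
fit on the extremum distribution (one fit regardless of V, so the cost
is negligible; failures fall back to counting with a warning). FDR is
Benjamini–Hochberg step-up via `p.adjust`, conservative with discrete
p-values when $J$ is small. Wilson score intervals quantify the Monte
Carlo uncertainty of any counting p-value.

## The synthetic evaluation harness

The generator emulates the evaluation conditions: $N = 20$ images of
$12^3$ voxels; Gaussian or standardized Weibull(scale 1, shape 1/3)
noise — mean $\Gamma(4) = 6$ and variance $\Gamma(7) - 36 = 684$ give
the standardization constants; smoothing by a FWHM-4-voxel Gaussian as
multiplication in the frequency domain without zero padding (the grid
is periodic, so no edge artefacts); the design is a standard-Gaussian
regressor of interest plus intercept with contrast $[1\;0]'$; signal,
when present, is added to **all** voxels (avoiding smoothing bleed into
pure-noise regions) with amplitude
$\psi_1 = t^{-1}(1 - \alpha; N - \mathrm{rank}\,M)\,
(C'(M'M)^{+}C)^{1/2}$. Because $(C'(M'M)^{+}C)^{1/2}$ is the standard
error of the contrast under unit error variance, this sets the t
statistic's noncentrality equal to the one-sided critical value, giving
~50% power at $\alpha$ for Gaussian errors irrespective of sample size
(verified at 49–53% by both the package's permutation test and an
independent parametric computation). Smoothing shrinks the marginal
variance of a unit-variance field, so the generator rescales by the
analytic $\ell_2$ norm of the kernel; per-voxel variance stays 1 and
the calibration keeps its meaning. Tests are one-sided with a positive
contrast throughout, matching the one-sided quantile in the
calibration.

Two caveats the harness quantifies rather than hides. First, under
Weibull errors the stated 5/8 attenuation of $\psi_1$ does **not**
reproduce ~50% power in our replication: the one-sided permutation test
rejects ~72% of the time on raw standardized-Weibull errors and ~26–29%
after FWHM-4 smoothing (which Gaussianizes the field to a residual
skewness of ~2.4); 50% would correspond to an effective smoothing of
about 1.8 voxels FWHM. The harness reports the honestly computed
number. Second, the generator produces stationary, homoscedastic
fields with spatially constant signal; real imaging data are
non-stationary and skewed in structured ways, so passing tests here
demonstrate correctness of the machinery, not performance guarantees on
real data.

The benchmark (`run_benchmark`) repeats realisations, analyses each
with a large-J counting reference and with the accelerators, and
reports empirical type-I error, power, and the resampling risk of
FWER-corrected decisions against the reference. Desk-scale defaults
(reference $J$ = 5000, 10–25 realisations) stand in for the original
large grids ($J$ = 50000, 100 realisations); the statistics compared
are the same.

## Numerical choices and degenerate inputs

* Pseudoinverse and rank decisions drop singular values below
  $\max(\mathrm{dim}) \cdot \epsilon \cdot \sigma_{max}$.
* Ties in counting p-values are inclusive ($\ge$), never randomized.
* Zero residual variance yields a signed infinite t with a warning
  (zero data give 0); degenerate permutation distributions fall back to
  counting in the gamma path and to rejection in the tail fit.
* GPD shapes within $10^{-12}$ of zero use the exponential limit;
  Pearson III skewness below $10^{-7}$ falls back to the normal limit
  with a warning.
* The directional rule's $\hat\beta = 0$ tie is treated as positive.
* One root seed drives every stochastic component; shuffle sets,
  sub-sampling, and the benchmark are bit-reproducible given the seed.

## Worked example

```{r example}
set.seed(1)
N <- 20; V <- 500
g <- rnorm(N)
M <- cbind(g, 1)
psi1 <- calibrated_effect(M, c(1, 0))
Y <- matrix(rnorm(N * V), N)
Y[, 1:100] <- Y[, 1:100] + psi1 * g   # effect in the first 100 tests

fit <- perm_glm(Y, M, c(1, 0), J = 500, accel = "tail", fwer = TRUE,
                fdr = 0.05, seed = 2)
summary(fit)
```

The problem sizes used in the package's tests (grids up to $12^3$,
reference runs up to $J$ = 10000, 25 benchmark repetitions) were chosen
as the smallest at which the Monte Carlo tolerances stated alongside
each check are meaningful.
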