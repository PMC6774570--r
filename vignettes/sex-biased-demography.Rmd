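---
title: "Inferring sex-biased demography from X-chromosomal and autosomal spectra"
author: "sexbias package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring sex-biased demography from X-chromosomal and autosomal spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexbias)
set.seed(1)
```

## The problem

In a two-sex Wright–Fisher population with $N_f$ breeding females and $N_m$
breeding males ($N = N_f + N_m$, $p = N_f/N$), the autosomes and the X
chromosome have different inbreeding effective sizes:

$$N_{eA} = 4p(1-p)\,N, \qquad N_{eX} = \frac{9p(1-p)}{2(2-p)}\,N .$$

Their ratio $Q = N_{eX}/N_{eA} = 9/(8(2-p))$ is $3/4$ when the sexes
contribute equally and crosses $1$ at $p = 0.875$. Because $Q$ is monotone
in $p$, the relative amount of X-chromosomal to autosomal variation carries
information about the *effective sex ratio*. The catch is that population
size changes also perturb the X-to-autosome diversity ratio — the X, having
the smaller effective size, re-equilibrates faster after a bottleneck or an
expansion — so ratio-based estimators that ignore demography confound
sex-bias with size change. This package implements a likelihood framework
that models the two jointly.

## Model

The observed data are site frequency spectra (SFS) for an autosomal and an
X-chromosomal locus class. Under the Poisson random field model the class-$i$
entry of the SFS is Poisson with mean $\theta L F(i)$, where
$\theta = 4N_{ref}\mu$ per site, $L$ is the callable length, and $F(i)$ is
the expected per-$\theta$ density determined by the demography ($F(i) = 1/i$
for constant size). The joint log-likelihood of the two classes is the sum
of the per-class Poisson log-likelihoods; $\log s_i!$ terms are kept (via
`lgamma`, which also extends the likelihood to averaged, non-integer
spectra), so reported log-likelihoods are absolute.

Demographies are ordered epochs, oldest first, each with a relative size,
a duration, and an instantaneous or exponential change type. The autosomal
model is fitted first (`fitAutosomal`); the X model is then *derived* from
it by the epoch-size invariant $N_{tX} = Q(p_t)\,N_{tA}$ with all size
changes at the same times in generations (`deriveXDemography`). In the X
chromosome's own coalescent units this gives
$\nu_{tX} = Q(p_t)/Q(p_1)\,\nu_{tA}$, $\tau_{tX} = \tau_{tA}/Q(p_1)$, and a
fixed per-site $\theta_X = Q(p_1)\,r\,\theta_A$, where $r = \mu_X/\mu_A$.
With a male-to-female germline mutation ratio $\alpha$,
$r = 2(2+\alpha)/(3(1+\alpha))$ (`muXFromAlpha`); $\alpha = 3$ gives
$r = 5/6$. Two published forms of these constraints are internally
inconsistent with the no-bias special case ($\theta_X = \tfrac34 r \theta_A$,
$\tau_X = \tau_A/c_1$); we derive everything from the size invariant, which
reproduces the consistent special cases exactly and round-trips $p$ to
machine precision (see the test suite).

The nested X-model ladder is:

* **M0** — no sex-bias: every $p_t = 0.5$ (zero free parameters);
* **M1** — constant sex-bias: one shared $p$;
* **MT** — changing sex-bias: per-epoch $p_t$ under a tie structure (for a
  three-epoch bottleneck the default ties the epochs outside the
  bottleneck, $p_1 = p_3$; `freeAll = TRUE` frees every epoch).

Tests are likelihood-ratio statistics on the joint likelihoods:
$\Lambda_0 = -2(LL_{M0} - LL_{M1})$ for constant bias and
$\Lambda_1 = -2(LL_{M1} - LL_{MT})$ for changing bias. For a constant-size
population the alternative is profiled in closed form
(`lrtConstantSize`): $\tilde p$ from the segregating-site ratio and
$\tilde\theta$ from the joint MLE. $\Lambda_0$ is approximately
$\chi^2_1$ under the null; multi-epoch models use a parametric-bootstrap
critical value by default (`parametricBootstrap`), and an empirical-null
mode is available. The nominal level is an explicit argument
($\alpha = 0.05$ by default) with the critical-value provenance recorded in
the result object.

## The expected-SFS engine

`expectedSFS` computes the exact neutral expected spectrum under any
multi-epoch model. The ancestral lineage count of a sample of $n$
chromosomes is a pure-death Markov chain with rate
$\binom{k}{2}/\nu(t)$; the expected time spent with $k$ lineages is
integrated by *uniformization* within each constant-size piece (chunked so
the dominant rate tracks the shrinking lineage count; the two-lineage tail
is closed-form, and the ancestral equilibrium epoch is handled
analytically). The density follows from the subtended-leaf combinatorics

$$F(b) = \tfrac12 \sum_{k=2}^{n} k\,E[t_k]\,
  \frac{\binom{n-b-1}{k-2}}{\binom{n-1}{k-1}} .$$

This route was chosen over a diffusion/grid solver because it is exact for
the one-population neutral SFS (the only regime the package models — no
selection terms), has no grid or extrapolation error to tune, and is fast
enough to sit inside an optimizer ($n = 500$ in well under a second).
Exponential epochs are discretized internally (32 log-spaced steps; the
staircase converges at the $10^{-3}$ relative level used in the tests).
Numerical guards: per-chunk Poisson truncation at
$\lambda s + 12\sqrt{\lambda s} + 25$ terms, a support cutoff at
$10^{-14}$ probability mass, and a hard chunk budget that raises an error
carrying the offending size and residual duration rather than returning a
wrong spectrum.

Two independent code paths cross-check each other throughout the tests:
this engine, and a coalescent tree sampler (`simulateCoalescentSFS`) that
simulates genealogies by time-rescaling and drops Poisson mutations on
branches. Their means agree per entry within Monte-Carlo error on
constant, growth and bottleneck histories.

## Estimators

* $\tilde p$ (`pTildeConstant`, and `fitXConstrained`'s M1/MT estimates in
  the model-based pipeline): inverts $Q$ while accounting for demography.
* $p_\pi$ (`pPiEstimator`): $Q_\pi = (\pi_X/\pi_A)/r$, $p_\pi = 2 -
  9/(8Q_\pi)$, with $\pi$ computed from the SFS (`piFromSFS`) so linked and
  unlinked inputs share one code path. It ignores size change and is
  biased by it — reproducing that bias is one of the package's validation
  targets. Out-of-range values (e.g. negative under a male-biased
  bottleneck) are returned flagged, not rejected: they are evidence of
  misspecification.
* The "$\theta$ test" (`qThetaTest`): the conventional bootstrap test of
  $\hat Q = \hat\theta_X/\hat\theta_A$ against 0.75; kept as a comparison
  baseline.

## What the simulator emulates

`simulateDataset` scales a *census* trajectory $N_t$ into the two locus
classes, $N_{tA} = f_A(p_t)N_t$ and $N_{tX} = f_X(p_t)N_t$, with per-epoch
sex ratios, then samples independent-sites Poisson spectra (default) or
linked per-locus coalescent trees. `scaledRates` exposes the corresponding
$\theta$ and $\rho$ scalings ($\rho_X$ carries the extra $2p/(1+p)$ factor
because the X recombines only in females; recombination affects only the
variance of linked summaries, not any expectation used here).

The shipped study designs (`experimentConfig`) are fixed once:

* **constant** — 1000 unlinked 5 kb regions; 40 autosomal and 30 X
  chromosomes (ten males plus ten females); per-site $\theta$ set so the
  design's expected total segregating-site count is 427 (the small-sample
  regime). The empirical 95% critical value of $\Lambda_0$
  computed from this design is $\approx 3.8$, just below the $\chi^2_1$
  quantile 3.841 — counts this small leave a visible discreteness effect.
* **expansion** — 55-fold instantaneous growth 205 generations ago,
  500 chromosomes, $\mu = 1.5\times10^{-8}$, 1000 × 5 kb. Published
  European recent-growth models estimating this 55-fold/205-generation
  expansion put the pre-growth effective size near 7,700 (55 × 7,700
  matches their current-size estimate, and 205 generations ≈ 5.1 kya at
  25 y/generation), so the preset anchors the ancestral size at 7,700.
  Under this model the deterministic diversity ratio gives
  $p_\pi \approx 0.22$ at a true $p = 0.2$ — an upward bias of the
  expected sign whose magnitude depends strongly on the ancestral size: a
  closed-form pairwise-coalescent calculation (independent of this
  package's engine) shows the bias would reach $+0.1$ only for ancestral
  sizes near 1,400 individuals.
* **expansion_methods** — the smaller ten-fold/100-generation variant.
* **bottleneck** — ancestral 14,500; 1,861 between 2,040 and 920
  generations ago; recovery to 100,000; 100 chromosomes;
  $\mu = 1.5\times10^{-8}$; 100 kb loci. Estimator-bias replicates use
  100-locus datasets; the likelihood-ratio power experiments use 300-locus
  datasets, a scaled-down stand-in for the original protocol's
  $10^5$-iteration aggregated spectra that keeps the test in the same
  power-saturated regime while fitting in minutes.

Simulations are independent sites (or single-tree loci); real data add
linkage, mutation-rate heterogeneity, selection at linked sites and
call-quality artifacts. Passing tests therefore validate the estimators'
behavior under the model's own assumptions, not robustness to those
features; the block bootstrap (`blockBootstrap`, intact 1 Mb blocks) is
the recommended guard against linkage when fitting genomic data.

## Numerical and design choices

* $p$ is validated to the open interval $(\varepsilon, 1-\varepsilon)$,
  $\varepsilon = 10^{-9}$; data-derived estimates are exempt and flagged
  instead.
* Optimization is Nelder–Mead on log parameters with profile-$\theta$,
  seeded by a log-spaced grid (top three starts, simplex restarted once at
  its own optimum); bound hits trigger multiplicative restarts, uniform in
  $\times[1/2, 2]$, with a budget of five. Recent-growth magnitudes sit on
  a genuinely flat likelihood ridge at small sample sizes; such fits are
  flagged (`converged = FALSE`) rather than hidden.
* A slightly negative $\Lambda$ (within $10^{-6}$, optimizer tolerance) is
  clamped to zero with a warning; anything lower raises an error.
* Epoch durations are taken in generations at the interface and converted
  to coalescent units of each class's own $2N_{ref}$, which resolves the
  time-scaling ambiguity between the published constraint sets.
* Masked SFS entries are excluded from likelihoods and from every
  $\sum F$ denominator consistently; folding and the hypergeometric
  projection conserve totals and non-negativity, with projected
  monomorphic mass dropped and logged.
* The VCF reader restricts to biallelic SNPs, sets half-calls to missing,
  drops sites above 5% missingness, projects the remainder to a common
  sample size, folds by default, and adjusts the callable length by the
  surviving-SNP fraction; mixed-ploidy X genotypes are a hard error rather
  than a silent miscount. Pseudo-autosomal regions are excluded via a
  user-supplied BED mask, since their coordinates are assembly-dependent.

## A worked example

```{r example, eval = FALSE}
set.seed(7)
d <- simulateDataset(experimentConfig("bottleneck", p = c(0.8, 0.2, 0.8)))
fa <- fitAutosomal(d$sfsA, "bottleneck")
f0 <- fitXConstrained(d$sfsX, fa, "M0")
f1 <- fitXConstrained(d$sfsX, fa, "M1")
fT <- fitXConstrained(d$sfsX, fa, "MT")
lrtSexBias(f1, fT)          # changing-bias test
fT@pEstimates               # per-epoch proportion of females
pPiEstimator(piFromSFS(d$sfsA), piFromSFS(d$sfsX))$pPi  # the biased ratio
```

The diversity-ratio estimator returns a single intermediate value near
0.47 for this female-bias-with-male-biased-bottleneck scenario — a
constant slight male bias and a changing bias are indistinguishable to it —
while the model-based per-epoch estimates recover both the female bias
outside the bottleneck and the male bias during it.

## Limitations

Single population only (no migration or admixture), neutral sites only, a
single $\alpha$ shared across epochs, and inbreeding effective sizes from
the two-sex Wright–Fisher model (no overlapping generations or
offspring-variance corrections). Fits assume the demographic family is
well-specified; the misspecification diagnostics are the out-of-range
$p$ estimates and the nested-test ladder itself.
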