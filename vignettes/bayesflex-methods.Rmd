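---
title: "Flexible hyperparameter priors in Bayesian genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flexible hyperparameter priors in Bayesian genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

All methods in this package fit the same whole-genome regression

$$ y = Xb + Z\alpha + e, \qquad e \sim N(0, I\sigma_e^2), $$

where $y$ holds $N$ phenotypes, $X$ carries fixed effects (an intercept in
simulation runs; herd/year/season classes for field data), $Z$ is the
$N \times P$ matrix of additive genotype codes 0/1/2, and $\alpha$ the $P$
SNP effects.  The Bayesian-alphabet members differ only in the prior on
$\alpha_j$:

* **BayesA** — every SNP has an effect, $\alpha_j \sim N(0, \sigma_j^2)$ with
  a locus-specific variance $\sigma_j^2 \sim$ scaled-inv-$\chi^2(v, S_a^2)$;
  marginally the effects are $t$-distributed.
* **BayesB** — a spike-and-slab mixture: $\alpha_j = 0$ with probability
  $\pi$, otherwise normal with its own scaled-inv-$\chi^2$ variance.
* **BayesC$\pi$** — the same mixture but one variance $\sigma_a^2$ common to
  all non-zero effects; $\pi$ may be fixed or given a Uniform(0,1) prior and
  sampled from Beta$(P-q+1,\,q+1)$, $q$ being the count of non-zero effects.

Conventionally $v$ is fixed at 4.2 and the scale is derived from an assumed
per-locus variance via $S_a^2 = (v-2)\,E(\sigma_j^2)/v$; the package derives
$E(\sigma_j^2) = h^2_{\text{prior}}\mathrm{Var}(y) / \big((1-\pi)\sum_j
2p_jq_j\big)$ from an assumed heritability.

The **flexible variants** (BayesFA, BayesFB, BayesFC$\pi$) treat both
hyperparameters as unknown: $S_a^2 \sim$ Gamma(1, 1), and $v \sim$
Exponential(0.25) for FA/FC$\pi$ or Gamma(4, 1) for FB.  Their full
conditionals are

* scale: $S_a^2 \mid \cdot \sim$ Gamma$\big(\tfrac{vq}{2}+1,\ \text{rate} =
  \tfrac{v}{2}\sum_j \sigma_j^{-2} + 1\big)$ — exactly conjugate when the
  second Gamma argument is read as a rate on the kernel
  $(S^2)^{qv/2}e^{-S^2(\frac{v}{2}\sum\sigma_j^{-2}+1)}$;
* degrees of freedom: $f(v \mid \cdot) \propto (v/2)^{qv/2}\,
  \Gamma(v/2)^{-q} e^{-\eta v}$ (times $v^3$ under the Gamma(4,1) prior),
  with $\eta = \tfrac12\sum_j \ln(\sigma_j^2/S_a^2) + \tfrac12\sum_j
  S_a^2/\sigma_j^2 + \lambda$ (or $+1$).  Because $t - \ln t \ge 1$,
  $\eta \ge q/2 + \lambda$ always.

Here $q$ counts the variance terms entering the likelihood: all $P$ loci for
FA, the currently included loci for FB, and for FC$\pi$ the single common
variance counted once per included locus (the common-variance model treats
the $q$ active loci as $q$ identical variance observations).

## Accept-reject sampling of the degrees of freedom

$f(v\mid\cdot)$ is non-standard, so $v$ is drawn by accept-reject under an
exponential envelope $g(x;\theta) = \theta e^{-\theta x}$.  Writing
$Q(x,\theta) = \ln f - \ln g$ and substituting the stationarity condition
$\theta = 1/x$ gives

$$ h(x) = \tfrac{q}{2}\big[\ln(x/2) + 1 - \psi(x/2)\big] + \tfrac{1}{x}
   - \eta \;\;(+\,3/x \text{ under Gamma(4,1)}), $$

with $\psi$ the digamma function.  $h$ is strictly decreasing, diverges at
$0^+$ and tends to $q/2 - \eta < 0$, so it has a unique root $x^\*$; the
envelope constant is $\ln M = \ln f(x^\*) - \ln g(x^\*; 1/x^\*)$.  The root
is found by exponential bracketing (doubling/halving from 1 until the sign
flips — our reading of the cited "exponential dichotomy") followed by
bisection to $|h| < 10^{-10}$.  Proposals $c \sim$ Exp($1/x^\*$) are accepted
with probability $f(c)/(M g(c))$; domination $\ln f(c) \le \ln M + \ln g(c)$
is asserted for every proposal and a retry cap of $10^6$ guards against
construction bugs.  With $q = 0$ the conditional collapses to the prior and
is drawn directly.  All density work is in log space.

Within each Gibbs cycle the order is: fixed effects (flat prior), SNP
effects and their variances (family-specific), then $S_a^2$ by Gibbs, $v$ by
accept-reject, $\pi$ (if sampled), and $\sigma_e^2$ from
$e'e/\chi^2_{N-2}$ — the flat-prior scaled-inv-$\chi^2(-2, 0)$ update, which
the source algorithm leaves unspecified; we follow the convention of the
original spike-and-slab implementation.  BayesB/FB sample each locus
variance by 100 Metropolis-Hastings cycles (proposal = prior mixture,
acceptance by the likelihood with the effect integrated out), then the
effect given the variance.

## GBLUP baseline

The genomic relationship matrix follows the centered cross-product
construction $G = WW'/\sum_j 2p_jq_j$.  Variance components are estimated by
EM-REML in the eigenbasis of $G$ (monotone in the REML likelihood,
convergence at relative change $10^{-8}$ or 200 iterations), and GEBVs of
unphenotyped individuals come from the mixed-model identity
$\hat g = \sigma_g^2 G_{\cdot,o} V_o^{-1}(y_o - X_o\hat b)$, which equals
ridge regression on the centered markers with shrinkage
$k\sigma_e^2/\sigma_g^2$ — an identity the test suite checks to $10^{-8}$.
Variance components are re-estimated inside every reference set rather than
carried over from a full-data analysis.

## The simulator

The generator reproduces the standard forward-in-time design used to
benchmark these methods:

* 100 founders (50 of each sex), 2000 non-overlapping historical generations
  of constant size with random monogamous pairing and two offspring per
  pair;
* five 1-Morgan chromosomes carrying 2000 uniformly placed SNPs each, with
  one candidate QTL at the midpoint of every adjacent SNP pair (9995
  candidates for 10000 SNPs);
* Haldane meiosis — Poisson(map length) crossovers, uniform breakpoints, no
  interference — and recurrent allele-flip mutation;
* expansion to 2000 individuals in generation 1 (50 pairs x 40 progeny),
  then 50 sires x {250, 500, 1000} dams with two offspring per dam giving
  generations 2-6 of size 500/1000/2000;
* causal QTL drawn among candidates segregating in generation 1, effects
  standard normal, TBV = dose x effect, and generation-1 phenotypes
  TBV + $N(0, \sigma_e^2)$ with $\sigma_e^2 =
  \mathrm{Var(TBV)}(1-h^2)/h^2$.

**Mutation rate.**  The historical phase is meant to reach mutation-drift
equilibrium with most loci segregating.  With effective size 100 that
requires $\theta = 4N\mu \approx 1$; the package therefore defaults to
$\mu = 2.5\times10^{-3}$ per locus per meiosis, which leaves the stationary
allele-frequency distribution near-uniform and >95% of loci polymorphic in a
100-animal base.  (Rates of order $10^{-5}$, sometimes quoted for such
designs, give $\theta \approx 0.01$ and an almost entirely monomorphic
panel unless loci are ascertained afterwards.)  The rate is a plain argument
and can be lowered if an ascertained-marker workflow is preferred.

**Scaling rule for reduced panels.**  Tests and the acceptance script run
miniatures with fewer markers.  Marker-QTL linkage disequilibrium — the
quantity the regressions exploit — depends on marker spacing through
$r^2 \approx 1/(1+4Nc)$, so shrinking the panel at fixed map length changes
the genetic architecture being tested.  Reduced runs therefore keep the
full-scale density of 2000 SNPs/Morgan and shrink the map instead
(`length_morgan = snps_per_chr / 2000`, the default in `run_experiment()`).
With this rule a 1000-marker miniature reproduces the full-scale accuracy
range and method ordering; without it all sparse methods degrade toward
GBLUP.

**What the generator does not emulate:** selection during history, sex
chromosomes, genotyping error, non-additive gene action, and family
structure beyond the stated mating designs.  Passing tests on these data
show the samplers target the right posteriors and that the methods rank as
expected under the stated architecture — not that the same margins will
appear in any particular livestock population.

## Mixture weight in simulation runs

For the mixture methods the experiment driver fixes $\pi$ (the prior
probability of a *zero* effect) at $1 - n_{\text{QTL}}/P$, so the expected
number of included loci matches the simulated architecture.  Field-data
defaults are $\pi = 0.996$ (B family) and $0.8$ (C$\pi$ family).  The
Uniform(0,1) treatment of $\pi$ is available via `sample_pi = TRUE`; both
behaviours are exposed because fixed-$\pi$ and sampled-$\pi$ protocols are
both in circulation for the C$\pi$ family.

## Numerical choices and degenerate inputs

* Monomorphic loci carry no information and are forced to zero effect (with
  a warning) in the samplers and excluded from $G$.
* Root finding: bisection to $|h(x^\*)| < 10^{-10}$ after exponential
  bracketing; densities and acceptance ratios in log space; `lgamma` and
  `digamma` from the R math library.
* EM-REML adds a $10^{-8}$ jitter when $G$ is not positive definite and
  floors both components at $10^{-10}\,\mathrm{Var}(y)$; non-convergence
  returns the last iterate, flagged.
* One root seed drives every chain and simulation; populations, chains and
  experiments are bit-reproducible given the seed.
* No thinning by default: posterior means average all post-burn-in samples.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run the simulation study at a
desk-scale miniature chosen once: $P = 1000$ markers (5 chromosomes x 200
SNPs at full density) and 10,000 MCMC cycles with 2,000 burn-in.  The
method-ordering check uses a 500-animal generation-1 reference
($N/P = 0.5$, matching the full-scale ratio regime where shrinkage priors
matter) over 5 replicates at QTL = 5 / $h^2$ = 0.1; the value-level
reproduction in the acceptance script uses the full 2000-animal
generation-1 reference over 2 replicates, plus the QTL = 200 /
$h^2$ = 0.5 cell for hyperparameter inference.  The full 48-scenario grid
at 10,000 markers and 50,000 cycles is expressible through the same
`run_experiment()` call and is an overnight-scale computation.

## Known limitations

* The accuracy margins between flexible and conventional methods are small
  (a few points at most in the original study); at miniature scale single
  replicates can invert the ordering, which is why the shipped checks
  compare replicate means.
* The HWE filter uses the asymptotic 1-df chi-square test, not the mid-p
  exact test some QC pipelines apply; for common variants the two agree
  closely.
* EM-REML is robust but slow near the boundary of the parameter space;
  heritabilities close to 0 or 1 may hit the iteration cap (flagged, with
  the last iterate returned).
* The real-data accuracy estimator takes any EBV proxy supplied by the
  caller; the choice of proxy (adjusted phenotype vs pedigree EBV) is
  deliberately left open.
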