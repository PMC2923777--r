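---
title: "Multinomial inference on the spatial patterning of peaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multinomial inference on the spatial patterning of peaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakpattern)
```

## The question the package answers

Mass-univariate analysis of statistic maps (SPMs) asks, voxel by voxel,
*did this location respond?*  It cannot answer the complementary question of
functional segregation: *is region Q more engaged than region R?* — because
accepting a null ("R did not respond") is outside its logic.  `peakpattern`
addresses segregation directly.  It reduces each statistic map to its
supra-threshold local maxima ("events"), counts them over a pre-specified
partition of the search volume, and asks whether the counts are spatially
patterned beyond what chance predicts.  The inference concerns the
*relative* density of events across regions, not the existence, height or
extent of any individual activation.

## The null model

For a smooth null statistic field, high local maxima behave like a
homogeneous Poisson process — not in physical space, but in *resel* space,
where volume is discounted by local smoothness.  If region $j$ has
statistical volume $|A_j|$ (its resel count), the null event counts are
independent $d_j \sim \mathrm{Poisson}(\lambda |A_j|)$.  The unknown rate
$\lambda$ is removed by conditioning on the total count
$k = \sum_j d_j$, which leaves a multinomial likelihood

$$p(d \mid a) = \frac{k!}{d_1! \cdots d_n!} \prod_j a_j^{d_j},
  \qquad a_j = \frac{|A_j|}{\sum_j |A_j|}.$$

Everything in the package flows from this conditional multinomial: the
classical Pearson $\chi^2$ pattern test and the small-volume binomial
p-value (`chisq_pattern_test()`, `binomial_svc_pvalue()`), the Bayesian
model comparison (`ffx_fit()`), and the hierarchical population model
(`rfx_fit()`).

### Regional resel counts

`estimate_rpv()` implements the conventional resels-per-voxel estimator:
residual fields are standardized to unit sum of squares per voxel, spatial
derivatives are formed by forward differences (a voxel contributes on an
axis only when its $+1$ neighbour is in-mask), and
$\mathrm{rpv} = (4\log 2)^{-3/2}\, |\Lambda|^{1/2}$ where $\Lambda$ is the
$3\times 3$ covariance of the derivatives across volumes.  `region_resels()`
sums the RPV image over an integer atlas.  Two numerical choices deserve
note:

* **Boundary voxels.**  A voxel whose forward neighbour is missing on any
  axis cannot supply a full three-dimensional $\Lambda$.  A determinant
  over the remaining axes would estimate a lower-dimensional resel density
  (in units of $\text{resel}^{2/3}$) and systematically inflate boundary
  contributions, so such voxels are instead imputed with the mean RPV of
  the computable in-mask voxels.  Regional sums are therefore unbiased to
  first order, at the cost of slightly smoothing regional boundaries of the
  smoothness map itself.
* **Discretization bias.**  Forward differences underestimate the
  derivative variance of a smooth field by a factor
  $(1 - e^{-\alpha})/\alpha$ per axis with
  $\alpha = 1/(4\sigma^2_{\mathrm{acf}})$.  On simulated stationary fields
  the total resel count agrees with the closed form $V/\mathrm{FWHM}^3$ to
  within 10% for smoothness of about 4 voxels FWHM and above; at 3 voxels
  the shortfall grows to roughly 12%.  Because the inference conditions on
  *relative* resel counts, a shared multiplicative bias cancels; only
  strong regional differences in smoothness near the 3-voxel floor would
  distort the null pattern appreciably.

When the field can be assumed stationary, `isotropic_rel_volume()` skips
smoothness estimation and uses voxel counts.

### Events

`find_peaks()` declares a voxel an event when it is inside the mask, above
the height threshold, and strictly higher than all in-mask neighbours
(26-connectivity by default; 18 available).  Ties on exact-valued plateaus
— a measure-zero event for continuous fields, but routine in integer test
fixtures — are resolved to the lexicographically smallest coordinate of
each plateau, and a plateau touching strictly higher ground yields no peak.
The default threshold is $t = 3$: low enough to harvest many events (power
grows with the number of events), high enough that excursions are mostly
unimodal.  For higher thresholds, or when multiple near-coincident maxima
per excursion are a worry, `one_per_excursion = TRUE` keeps only the global
maximum of each supra-threshold connected component.

## Fixed-effects inference

With several subjects believed to share one spatial pattern, regional event
and resel counts are pooled over subjects (`pool_counts()`), and two models
are compared by exact evidence:

* $M_0$ (uniform per resel): $\theta = a$, a Dirac prior, so
  $p(d \mid M_0)$ is the multinomial pmf at $a$;
* $M_1$ (free pattern): $\theta \sim \mathrm{Dirichlet}(\tfrac12, \ldots,
  \tfrac12)$, the Jeffreys prior, integrated in closed form
  (Dirichlet–multinomial).

The Bayes factor $p(d\mid M_1)/p(d \mid M_0)$ is reported with the
conventional "very strong evidence" decision at $\mathrm{BF} \ge 20$.  The
integrated likelihood automatically penalises the $n-1$ free parameters of
$M_1$ (Occam's razor): for a bipartition the prior-predictive variance of a
regional count is $k a(1-a)\bigl[1 + (k-1)/(c+1)\bigr]$, monotonically
decreasing in the prior concentration $c$, so the sharper null wins
whenever the data sit near its expectation.

Parameter-level inference uses the marginal posteriors
$\theta_j \sim \mathrm{Beta}\bigl(d_j + \tfrac12,\; k - d_j +
\tfrac{n-1}{2}\bigr)$ with *penalised* central credible intervals: at
credible level $x$ over $n$ regions the excluded tail mass is
$\varepsilon = (1 - x)/(n - 1)$, split equally between tails (the
Bonferroni-like $n-1$ penalty; the split is a package choice, as "central"
does not dictate one).  A region is flagged `rich` when $a_j$ falls below
the interval and `sparse` when above; exclusion is strict, which is the
conservative reading of "inconsistent with the null".  With a single
region there is no free parameter and the interval machinery is disabled.

## Random-effects inference

When subjects plausibly differ in their true patterns, each subject's
pattern is modelled as $\theta_i \sim \mathrm{Dirichlet}(c\,m)$: $m$ is the
population mean pattern and $c$ the concentration (inverse heterogeneity).
The subject patterns integrate out analytically
(Dirichlet–multinomial conjugacy), leaving a posterior over $(m, c)$ only.
Model-level Bayes factors are *not* computed for the free-$m$ model — its
integrated likelihood has no analytic solution — so inference is restricted
to the population means, exactly as in the fixed-effects interval logic but
on $m_j$.

Choices the model statement leaves open, and what the package does:

* **Prior on $(m, c)$.**  $\log c \sim \mathrm{Uniform}[\log 0.1,
  \log 10^4]$, and for the population mean the fitting wrappers default to
  the *null-centred logistic-normal* prior:
  $\mathrm{alr}(m) \sim N(\mathrm{alr}(a), \sigma^2 I)$ with $\sigma = 1$,
  so the prior's median pattern is exactly the chance pattern $a$ and each
  regional log odds (against the reference region) sits within about
  $e^{\pm 2}$ of chance at 95% prior probability.  Two failure modes of
  simpler choices motivated this.  First, a uniform-mean prior (e.g.
  $\mathrm{Dirichlet}(1,\ldots,1)$): a typical partition pairs $N$ regions
  with one large rest-of-volume region whose null share can be 0.7 or
  more, and with few events per subject the prior drags that region's
  population mean towards $1/n$ — the null value lands outside the
  penalised interval and a departure from chance is manufactured out of
  the prior alone.  Second, a null-centred *Dirichlet*,
  $m \sim \mathrm{Dirichlet}(n a)$: a tiny region then carries a
  concentration far below 1, i.e. a spike-at-zero marginal whose
  log-ratio tail is nearly flat over hundreds of units — it traps any
  random-walk sampler and collapses the region's penalised interval to
  absurd magnitudes.  The logistic-normal form has neither problem: it is
  smooth and log-concave in exactly the coordinates the sampler moves in.
  Centring at the null can only be conservative for detecting departures
  (it shrinks *towards* chance).  The uniform Dirichlet remains the
  `rfx_prior()` default for explicit use, and any Dirichlet concentration
  vector may be supplied.  All priors are proper, so the posterior is
  proper for any data.
* **Sampler.**  Component-wise Gaussian random-walk Metropolis on the
  unconstrained parameters (additive-log-ratio transform of $m$, $\log c$),
  with the log-Jacobian included.  Per-coordinate step sizes adapt towards
  an acceptance rate of 0.3 during burn-in and are then frozen, preserving
  detailed balance afterwards.  Component-wise updates matter here: with
  20 or more regions a joint proposal mixes so slowly that the extreme
  penalised quantiles (tail mass $\varepsilon/2 \approx 10^{-4}$) come out
  too narrow, which silently inflates the frequentist error rate.  Five
  percent of coordinate updates use a 40-fold wider step: when a tiny
  region carries concentration $\alpha_j \ll 1$, its marginal has a
  near-flat tail spanning hundreds of log-ratio units which a fixed-scale
  walk cannot cross, and the wide moves let the chain mix between the bulk
  and that tail instead of sticking in one of them.
  Defaults are 4 chains of 10 000 sweeps (2 000 burn-in); convergence is
  summarised by split-$\hat R$ per coordinate and any value above 1.1
  flags the result.  Correctness is checked against a dense
  two-dimensional grid posterior (Kolmogorov–Smirnov distance of the
  $m_1$ marginal below 0.02).
* **Null reference for flags.**  Subject-specific relative volumes
  $a_{ij}$ are accepted, but flags compare $m_j$ to the resel-weighted
  (pooled) relative volume — a single chance value per region.
* **Informed models.**  When a precise alternative pattern is available,
  pinning it with a Dirac prior restores exact model comparison.  In the
  random-effects case the package interprets the pinned quantity as the
  *population mean* $m$ (a population-level hypothesis); the subject
  patterns still vary around it, and only the scalar $c$ remains to
  integrate, done by adaptive quadrature on $\log c$
  (`informed_rfx_evidence()`).  Pinning each subject's $\theta_i$ instead
  would collapse the model to fixed effects, which
  `informed_ffx_comparison()` already covers.

## The null simulator and what the validation shows

`simulate_null_subject()` generates signal-free subjects with realistic
non-stationary smoothness: each of `n_scans` volumes starts as iid
standard-normal noise on a regular lattice; a subject-specific Voronoi
layout of 20 cells assigns each cell its own smoothing kernel with FWHM
drawn uniformly from [4, 10] voxels; the composed image is re-smoothed at 2
voxels to preclude sharp transitions at cell boundaries; and a mean-effect
GLM over scans yields the subject's $t$-field (lattice units are treated as
mm, so only relative smoothness matters).  Smoothing uses separable
truncated-Gaussian convolution with periodic (wrap-around) boundaries, a
package choice that keeps the null field exactly stationary within a
smoothness cell — the per-voxel marginal is exactly Student-$t$, and the
$V/\mathrm{FWHM}^3$ calibration holds without edge artefacts; zero padding
is available as an option.  Piecewise smoothing is realised by composing
whole-volume smoothings under the cell masks, avoiding edge
renormalisation inside cells.

`run_fwer_experiment()` assembles the frequentist validation: a corpus of
null subjects; per experiment a random group, a random selection of $N$
regions from a seeded Voronoi "anatomical" parcellation (a stand-in for a
labelled atlas, which can be supplied instead — the null calculus depends
only on resel counts, not anatomy) plus the rest-of-volume union as the
final region; pooled fixed-effects or random-effects inference at
$x = 0.99$; and the family-wise error rate, the fraction of experiments
with at least one flagged region.

Two profiles are built in.  The `"full"` profile reproduces the reference
study conditions (a $64^3$ lattice, 84 scans, a corpus of 1 000 subjects,
150 groups of 20, a 116-region parcellation).  The package's own tests and
the acceptance script use the `"desk"` profile — a $32^3$ lattice, 24
scans, 300 subjects, 100 groups of 10, a 60-region parcellation — chosen
as the smallest design that still exercises every moving part with
non-trivial event counts (a median of a few supra-threshold peaks per
subject).  Passing validation at desk scale shows that the machinery is
calibrated under the model's own assumptions — Gaussian noise,
GLM residual smoothness, a correct atlas alignment.  It does not certify
behaviour on real data, where noise is non-Gaussian, smoothness estimates
carry error correlated with anatomy, and the partition may misalign with
true functional boundaries.  Note also that at desk scale event counts per
region are small, so the $\chi^2$ pattern test's moderate-expected-count
warning is routinely triggered; the Bayesian machinery needs no such
approximation.

## Other numerical and design choices

* All pmf and evidence computations are in log space with `lgamma`; pooled
  counts in the thousands are safe.
* The Pearson form of the $\chi^2$ statistic is used (the likelihood-ratio
  variant is asymptotically equivalent and was not chosen).
* The binomial small-volume p-value includes the observed count in the
  upper tail, as the excess-tail sum runs from $d_1$ to $k$; the deficit
  version mirrors to the lower tail.
* Model priors default to $p(M_0) = p(M_1) = \tfrac12$ and are
  configurable.
* Pooling across subjects sums counts and resels over *subjects* within
  region; relative volumes are recomputed from the pooled resels.
* Empirical interval quantiles are sort-based (type 1), matching the
  definition tested against a sorting oracle.
* Every stochastic entry point (`rfx_sample()`, `simulate_*()`,
  `run_fwer_experiment()`, and the corresponding CLI subcommands) requires
  an explicit seed and is bit-reproducible given it.

## Known limitations

* Set-level and cluster-extent random-field p-values are out of scope; the
  package compares patterns, not absolute activation.
* The resel estimator assumes reasonably smooth fields; below about 3
  voxels FWHM its discretization bias becomes material (see above).
* Random-effects model evidence is only available for informed
  (pinned-mean) models.
* Non-parametric random effects, covariate effects on patterning, and
  recursive partition refinement are natural extensions not implemented
  here.
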