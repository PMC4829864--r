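---
title: "Testing island effects on trait evolution: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing island effects on trait evolution: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(islandpcm)
```

## The question

Island colonisation is widely expected to release lineages from
competitors and predators and thereby accelerate phenotypic evolution —
the "island effect". `islandpcm` implements the comparative-methods
toolkit needed to test that expectation in a mainland–island radiation
for which one has an ultrametric phylogeny, discrete island/continent
assignments of the tips, and continuous traits (a body-size measure and
several size-correlated shape measures). Three complementary questions
are addressed:

1. **Position**: do island and continental species occupy different
   regions of morphospace? (phylogenetic ANOVA/MANOVA)
2. **Extent**: are island assemblages more disparate than continental
   ones? (disparity ratios against a Brownian null; pseudo-community
   range resampling)
3. **Tempo**: did island lineages evolve faster? (single- vs multi-rate
   Brownian and Ornstein–Uhlenbeck model selection, parametric
   bootstrap, contrasts through time)

## Trait models

All continuous-trait machinery rests on the Gaussian process view of
trait evolution on a tree. Under single-rate Brownian motion (BM1) the
tip values are multivariate normal with mean equal to the root state and
covariance $\sigma^2 C$, where $C_{ij}$ is the shared root-to-MRCA time
of tips $i$ and $j$ (`vcv_tree()`). The likelihood is evaluated in
$O(n)$ by Felsenstein's pruning recursion, which factorises the density
into $n-1$ independent contrasts plus the GLS root estimate; the same
decomposition yields the standardized independent contrasts
(`pic_contrasts()`), the ML and REML rate estimates (`fit_bm1()`), and
ancestral states (`asr_bm()`).

The multi-rate model (BMS) assigns each *regime* (continent, or one of
the islands) its own rate $\sigma^2_r$. Regimes live on the tree as a
*painting*: an assignment of every instant of every branch to one
regime, exactly what a stochastic character map produces. The BMS
covariance is $\sum_r \sigma^2_r C_r$ with $C_r$ the per-regime
shared-time matrices (`regime_vcv()`); equivalently, BMS is BM1 on a
tree whose branch segments are stretched by their regime's rate, which
is how `fit_bms()` evaluates the likelihood. The overall scale and the
root are profiled out in closed form and only the $R-1$ relative
log-rates are optimised numerically (golden-section search for two
regimes, Nelder–Mead with three deterministic starts — all-equal, and
the non-reference rates shrunk/inflated tenfold — otherwise). Because
the all-equal start is always included, the fitted BMS likelihood can
never fall below the nested BM1 likelihood.

The single-optimum Ornstein–Uhlenbeck model (OU1) adds a pull of
strength $\alpha$ toward a global optimum $\theta$:
$V_{ij} = \frac{\sigma^2}{2\alpha} e^{-\alpha d_{ij}}
(1 - e^{-2\alpha t_{ij}})$, with $d_{ij}$ the patristic distance and
$t_{ij}$ the shared time, the root sitting at the optimum. This closed
form assumes an ultrametric tree, and `fit_ou1()` refuses
non-ultrametric input rather than silently switching root treatments.
$\theta$ and $\sigma^2$ are profiled; $\alpha$ is searched on
$[10^{-8}, 50/T]$ ($T$ = tree depth) on the log scale. A fit with
$\alpha$ at the upper bound is flagged (`at_bound`), since beyond that
the tips are essentially independent draws and $\alpha$ is not
identifiable. As $\alpha \to 0$ the model collapses to BM1, which the
test suite verifies numerically.

Models are compared by the small-sample Akaike criterion,
$AICc = -2\log L + 2k + 2k(k+1)/(n-k-1)$, with $k = 2$ (BM1),
$k = 1 + R$ (BMS), $k = 3$ (OU1) — parameter counts are stated
explicitly because different software traditions count the root
differently.

## Regime histories

Island/continent assignments of ancestral lineages are unknown, so
regime paintings are sampled rather than asserted. `fit_mk()` estimates
a continuous-time Markov (Mk) model of the discrete character by
maximum likelihood — by default all-rates-different, with the
stationary distribution of $Q$ as root prior (a uniform prior is
available). `stochastic_map()` then draws complete character histories
conditional on the tip states: node states by backward pruning and
forward sampling from the joint conditional distribution, and
within-branch histories exactly, conditional on branch endpoints, by
uniformization (dominating rate $\Omega = \max_i |Q_{ii}|$, virtual
jumps merged away). Sampled histories serialise to a painted-Newick
dialect in which each branch carries `[&regimes=state:duration|...]`
after its length; the annotation is a standard Newick comment, so
painted files remain readable by ordinary Newick parsers.

## Hypothesis tests and null models

All significance tests are simulation-based, mirroring how these
analyses are done in practice on trees with deep phylogenetic
correlation:

* `phylo_anova()` / `phylo_manova()` recompute the classical $F$ /
  Wilks' $\Lambda$ statistic on datasets simulated under BM1 (rate = ML
  estimate from the data) or multivariate BM (rate matrix =
  `evol_vcv()` estimate), with group labels held fixed across
  simulations. $F$ is upper-tailed, $\Lambda$ lower-tailed.
* `disparity_ratio_test()` compares the island/continent ratio of mean
  pairwise squared trait distance with the same ratio in Brownian
  simulations.
* `pseudo_community_test()` asks whether random $k$-species continental
  assemblages reproduce the island trait range; when
  $\binom{n_{cont}}{k}$ does not exceed the requested resamples the
  enumeration is exhaustive and the p-value exact (ties count as
  "reached", the conservative choice).
* `parametric_bootstrap_bms()` tests BMS against BM1 with the
  log-likelihood difference, refitting both models to data simulated
  under the fitted BM1; power at 95% confidence is the fraction of
  datasets simulated under the fitted BMS whose statistic exceeds the
  empirical 95th percentile of the null sample (no chi-square
  approximation anywhere).
* `contrasts_through_time()` plots |standardized contrast| against node
  height and flags nodes exceeding the per-node `level` quantile of
  simulated |contrasts| — a one-sided envelope, since contrasts enter in
  absolute value; about $1-\mathrm{level}$ of nodes are flagged under a
  homogeneous rate, which the calibration tests confirm.

Monte-Carlo p-values use the add-one convention
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + N)$: p-values are
never zero and floor at $1/(N+1)$ — $10^{-4}$ at the conventional
$N = 10{,}000$.

A deliberate design choice: group labels are never permuted. The null
hypothesis is "one Brownian process over the whole tree", not
"exchangeable species", so traits are re-simulated and labels kept.

## The synthetic study system

Real specimen data sets of this kind are rarely redistributable, so the
package ships a generator. `study_fixture()` emulates a 48-species
arid-adapted gecko radiation containing two island clades: a 2-tip
clade ("AbdAlKuri") and a disjoint 5-tip clade ("Socotra") on a
unit-depth Yule tree. Log body size evolves under BMS with rates
continent : Socotra : AbdAlKuri = 1 : 2 : 20 — the "about twice" and
"more than twenty-fold" island accelerations this class of analyses is
designed to detect — and three head dimensions evolve as single-rate
multivariate BM correlated 0.8 with the neutral component of size
(head–head correlation 0.64, i.e. exactly the correlation induced by
the shared size factor). Sizes and rates are on an arbitrary scale:
every statistic computed here is invariant to the tree's absolute time
units, so the depth is normalised to 1 and rates are per total depth.

Technical conventions: island clades are the first clades of the
required sizes in node-id order (redrawing the tree deterministically
if a draw has no disjoint 2- and 5-tip clades); the stem branch of each
island clade switches regime mid-stem; the rate excess on islands is
added as an independent Brownian increment so that head-trait rates
stay exactly homogeneous. What the fixture does *not* emulate: real
trees are not Yule, empirical island clades are not painted with known
certainty, measurement error and intraspecific variance are absent, and
sample sizes per species are infinite in effect. Passing calibration
and recovery tests on the fixture therefore demonstrates correctness of
the machinery under its own assumptions, not robustness to the ways
real data violate them.

## Numerical choices

* Covariance factorisations use Cholesky; on failure a single jitter of
  $10^{-10}\max(\mathrm{diag})$ is added, then the computation errors.
* Zero-length branches are tolerated in trees (polytomies are resolved
  into zero-length binary branches deterministically), but a zero
  pooled variance at a contrast raises an error — no silent epsilon.
* Ultrametricity is judged at relative tolerance $10^{-6}$ of tree
  depth; painting durations must sum to branch lengths within relative
  $10^{-9}$.
* All stochastic functions require an explicit seed. Pipelines derive
  per-stage sub-seeds by a 31-bit rolling hash of the stage name
  (`derive_seed()`), so adding an analysis never shifts another
  analysis' random stream, and identical configurations reproduce
  reports byte-for-byte.
* ML rate estimates divide by $n$ by default; the REML ($n-1$)
  variants are available via arguments, since both conventions are
  common and the difference matters at $n \le 50$.

## Problem sizes used in the test suite

The packaged tests scale the classical 10,000-simulation designs down
so the whole suite stays interactive: calibration studies use 199
null simulations per test and 100–250 trials, the bootstrap power
check uses 199 replicates, and the contrast-envelope coverage check
uses 500 simulations per replicate. These sizes were chosen as the
smallest at which the binomial noise of a rejection-rate estimate still
fits comfortably inside the documented acceptance bands; the
acceptance script (`scripts/acceptance.R`) runs the headline analyses
at the full 10,000-simulation scale.

## A worked example

```{r example}
fx <- study_fixture(seed = 1)
svl <- setNames(fx$traits$svl, fx$traits$species)

fits <- list(fit_bm1(fx$tree, svl),
             fit_bms(fx$tree, fx$painting, svl),
             suppressWarnings(fit_ou1(fx$tree, svl)))
compare_models(fits)
fits[[2]]$sigma2_by_regime
```

The multi-rate model wins and the fitted rates recover the generating
1 : 2 : 20 ordering. The parametric bootstrap quantifies the evidence:

```{r bootstrap}
parametric_bootstrap_bms(fx$tree, fx$painting, svl, n_boot = 199,
                         seed = 42)
```

## Known limitations

* Only a single global optimum OU model is fitted; multi-optimum OU
  variants are deliberately out of scope for data sets of this size.
* No measurement-error variance is modelled.
* Mk models have no hidden rate classes; ambiguous tips are supported
  only as `?` (uniform likelihood).
* The disparity statistic is the average pairwise squared Euclidean
  distance; disparity-through-time curves are not implemented.
* p-values for several traits are reported without multiplicity
  correction, matching standard practice in this literature; combine
  with `p.adjust()` if a family-wise claim is needed.
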