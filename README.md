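# islandpcm

Phylogenetic comparative tests of "island effects" on trait evolution.

Island colonisation is classically expected to free lineages from
competitors and predators and thereby accelerate phenotypic evolution.
`islandpcm` is an R toolkit for testing that expectation in a
mainland–island radiation, given an ultrametric phylogeny, an
island/continent assignment of the species, and continuous traits
(a body-size measure plus size-correlated shape measures). It asks, and
answers with simulation-based tests throughout:

1. **Do island and mainland species differ in position?** Phylogenetic
   ANOVA (`phylo_anova()`) and MANOVA (`phylo_manova()`), with null
   distributions of the *F* statistic and Wilks' Λ from Brownian-motion
   simulations on the tree.
2. **Are island assemblages more disparate?** Disparity ratios
   (mean pairwise squared trait distance, island / continent) against a
   Brownian null (`disparity_ratio_test()`), and pseudo-community range
   resampling (`pseudo_community_test()`).
3. **Did island lineages evolve faster?** Model selection by AICc among
   single-rate Brownian motion (BM1), regime-specific multi-rate
   Brownian motion (BMS) and single-optimum Ornstein–Uhlenbeck (OU1)
   (`fit_bm1()`, `fit_bms()`, `fit_ou1()`, `compare_models()`), a
   parametric bootstrap of BMS vs BM1 with power estimation
   (`parametric_bootstrap_bms()`), and independent contrasts through
   time with a simulation envelope (`contrasts_through_time()`).

## The models in brief

Under BM1 the tip values are multivariate normal with covariance
σ²C, where C holds shared root-to-ancestor times; the likelihood is
computed by Felsenstein pruning in O(n). Under BMS each regime *r*
(continent, or an island) has its own rate σ²ᵣ and the covariance is
Σᵣ σ²ᵣ Cᵣ with Cᵣ the per-regime shared-time matrices (`regime_vcv()`).
Regimes live on the tree as *paintings* — per-branch regime segments,
the output of stochastic character mapping (`fit_mk()`,
`stochastic_map()`), serialised in a painted-Newick dialect
`[&regimes=state:duration|...]`. OU1 adds a pull α toward a global
optimum θ: V·ᵢⱼ = σ²/(2α)·exp(−α dᵢⱼ)(1 − exp(−2α tᵢⱼ)) on an
ultrametric tree. AICc = −2 log L + 2k + 2k(k+1)/(n−k−1) with k = 2,
1 + #regimes, and 3 respectively.

Monte-Carlo p-values use the add-one convention
p = (1 + #{null ≥ obs})/(1 + N), flooring at 1/(N+1).

Because empirical specimen data of this kind are rarely
redistributable, the package includes a synthetic study system:
`study_fixture()` generates a 48-species radiation with a 2-tip island
clade ("AbdAlKuri", 20× body-size rate) and a 5-tip island clade
("Socotra", 2× rate) plus three size-correlated head dimensions, the
structure all calibration and power tests run on.

## Worked example

```r
library(islandpcm)
fx <- study_fixture(seed = 1)
svl <- setNames(fx$traits$svl, fx$traits$species)

fits <- list(fit_bm1(fx$tree, svl),
             fit_bms(fx$tree, fx$painting, svl),
             fit_ou1(fx$tree, svl))
compare_models(fits)
#>   model      logL k     aicc delta_aicc
#> 1   BMS -38.71086 4 86.35195   0.000000
#> 2   BM1 -43.65979 2 91.58625   5.234300
#> 3   OU1 -43.65979 3 93.86504   7.513088

round(fits[[2]]$sigma2_by_regime, 2)
#> continent AbdAlKuri   Socotra
#>      1.52     17.08      2.55
```

The multi-rate model is AICc-best and the fitted rates recover the
generating 1 : 2 : 20 ordering (continent < Socotra < AbdAlKuri). The
parametric bootstrap quantifies the evidence and the test's power:

```r
parametric_bootstrap_bms(fx$tree, fx$painting, svl, n_boot = 199, seed = 42)
#> Parametric bootstrap, BMS vs BM1
#>   observed logL difference = 4.9489
#>   p = 0.03   power(95%) = 0.513  ( 199 replicates, 0 failed, seed 42 )
```

So a single-rate Brownian process would produce a log-likelihood gap
this large about 3% of the time, and at this problem size the test
detects the simulated rate shift in roughly half of replicates. The
small island's inflated disparity is likewise detectable:

```r
g <- setNames(fx$groups$group, fx$groups$species)
disparity_ratio_test(fx$tree, svl, names(g)[g == "AbdAlKuri"],
                     names(g)[g == "continent"], n_sims = 999, seed = 7)
#> Monte-Carlo test of disparity_ratio
#>   observed = 1.1817   p = 0.023  ( upper tail, 999 simulations, seed 7 )
```

`run_pipeline()` chains all stages (stochastic mapping, size-correction
residuals, the tests above) over a single tree or a whole posterior
tree set, with per-stage sub-seeds derived deterministically from one
master seed and results aggregated across trees
(`aggregate_over_trees()`).

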