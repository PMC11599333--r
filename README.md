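# darkaffinity

Bayesian estimation of **dark diversity affinity (DDA)** for species-site
metacommunities: which species tend to be *absent from sites that suit
them*, and which sites tend to *lack species suited to them*.

The package targets presence-absence metacommunity data of the kind arising
in parasite ecology — flea or mite assemblages recorded on small-mammal
hosts across regions (component metacommunities, sites = regions) or across
host species within a region (compound metacommunities, sites = host
species) — but any binary species x site matrix with species traits and
site attributes fits.

## The model

For each species-site cell with observed occupancy `prab`:

- **Suitability** `suit ∈ [0, 1]` is estimated from pairwise co-occurrence:
  each pair's observed shared-site count is compared to its hypergeometric
  null (mean `nᵢnⱼ/N`, variance `nᵢnⱼ(N−nᵢ)(N−nⱼ)/(N²(N−1))`) to give a
  standardized effect size; a cell's raw score is the mean SES of the
  species against the other species present at the site, rescaled
  monotonically into [0, 1].
- **Affinity submodels**, logit-linear in standardized predictors
  (quantitative: mean 0, sd 0.5; categorical: full one-hot):

  `logit(dda_sp) = a_sp + x·b_sp`, `logit(dda_site) = a_site + e·b_site`

- **Unified affinity**: `logit(DDA) = [logit(dda_sp) + logit(dda_site)]/2`
  (DDA odds = geometric mean of component odds); 0.5 is the neutral
  threshold.
- **Presence likelihood**: `logit(p) = logit((1−DDA)·suit) + δ` with the
  balancing constant `δ = logit(mean(prab)) − logit(0.5·mean(suit))`, and
  `prab ~ Bern(p)`.

Coefficients get normal(0, 0.5) priors (intercepts) and normal(0, 2.5)
priors (slopes) and are sampled by adaptive Metropolis (compiled cell
likelihood), retaining 3 chains x 333 draws by default, with Gelman-Rubin
R-hat ≤ 1.1 gating and automatic burn-in/thinning escalation up to
25000 / 75.

## Worked example

Simulate a metacommunity with known structure (60 species x 40 sites, an
injected trait effect of +2 and a site-attribute effect of −2), fit, and
summarise:

```r
library(darkaffinity)

scn <- dda_scenario()
sim <- simulate_metacommunity(scn, seed = 7)
fit <- dda_fit(sim$mc, suit = sim$suit,
               control = dda_control(burnin = 2000, thin = 6), seed = 7)
tidy(fit)
#> # A tibble: 12 x 8
#>    term              side       mean  median  lower  upper significant  rhat
#>  1 a_sp              species -0.0141 -0.0269 -0.913  1.01  FALSE       1.01
#>  2 a_site            site     0.0234  0.0390 -0.884  0.905 FALSE       0.999
#>  3 b_sp:trait_q1     species  2.24    2.23    1.66   2.88  TRUE        1.00
#>  8 b_site:attr_q1    site    -2.07   -2.05   -2.80  -1.42  TRUE        0.999
#>  ...
```

The injected coefficients (+2 on `trait_q1`, −2 on `attr_q1`) are recovered
with credible intervals excluding 0; all other slopes are correctly
unresolved. Contrast the absent (`prab = 0`) and present (`prab = 1`)
cells:

```r
compare_subsets(fit)
#> # A tibble: 5 x 7
#>   quantity median_absent median_present     H  p_value n_absent n_present
#> 1 p                0.201          0.344 281.  4.85e-63     1784       616
#> 2 suit             0.456          0.621 185.  4.82e-42     1784       616
#> 3 DDA              0.510          0.417 102.  6.34e-24     1784       616
#> 4 dda_sp           0.527          0.405  48.6 3.08e-12     1784       616
#> 5 dda_site         0.509          0.389  48.0 4.23e-12     1784       616
```

Absent cells show higher affinity and lower suitability/presence
likelihood — the direction the model is built to expose. Per-entity
classification and plots:

```r
posterior_affinity(fit, "species")  # median, CI, dark-/presence-affine label
autoplot(fit)                       # coefficient intervals
plot_affinity(posterior_affinity(fit, "species"))
```

For real data: `read_metacommunity()` (CSV matrix + trait/attribute
tables) or `apply_selection_thresholds()` (survey records with examined
host counts), then `validate_metacommunity(strict = TRUE)`,
`suitability()`, `dda_fit()`, `dda_results()` and `write_dda_results()`.

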