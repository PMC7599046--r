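# nichenb

Hybrid niche-neutral models of microbiota species-abundance distributions,
with model-based biodiversity estimation and downstream cohort statistics.

## The problem

The alpha diversity of a gut microbial community is usually summarized by
indices computed directly from relative abundances (Shannon, Simpson,
Pielou, Hill numbers). These inherit the full sampling noise of the count
data. An alternative is to *model* the Relative Species Abundance (RSA)
distribution — the number of OTUs observed with exactly *n* reads — and
read biodiversity off the fitted model. Under a neutral
birth–death–immigration process with birth rate *b*, death rate *d* and
immigration influx *s*, the stationary RSA is a zero-truncated Negative
Binomial in the ratios *x* = *b*/*d* and *r* = *s*/*b*:

    P(n) = x^n Γ(n + r) / ( n! Γ(r) [ (1 − x)^(−r) − 1 ] ),   n ≥ 1

Real gut communities are poorly served by a single neutral community, so
`nichenb` fits mixtures of one to three such niches. In the two-niche
case the components separate into a **rare** and an **abundant** niche,
each contributing a Hubbell fundamental biodiversity number

    θ = N_obs / ( [ (1 − x)^(−r) − 1 ] · Γ(r) )

reported as `theta_rare` and `theta_abundant`.

Fitting is likelihood-free: an ABC rejection sampler proposes parameters
from (hyper)priors, simulates a community with the sample's observed
richness, and accepts proposals whose Preston (log2-octave) histogram
matches the data under a bin-tolerance rule plus a Skellam-motivated χ²
criterion. A two-step hierarchy pools accepted draws across the samples of
a dataset into Beta/Gamma hyperpriors and refits each sample under them.
The package also implements the downstream statistics such an analysis
needs — natural-cubic-spline age trends with per-dataset deviation
contrasts, covariate adjustment, Mann–Whitney group tests, an elderly
health classifier, a principal-component health score, and leave-one-out
health prediction with ROC AUC — plus a synthetic-data generator that
produces communities and cohorts with known ground truth.

## Worked example

```r
library(nichenb)

# a synthetic two-niche community: 500 OTUs, rare niche mean ~1.5 reads
# (weight 0.7), abundant niche mean ~50 reads (weight 0.3)
model <- default_recovery_model()
fx <- make_community(model, n_obs = 500, seed = 42)
fx$truth$theta
#>       rare   abundant
#> 1000.00000   10.20408

preston_histogram(fx$av)
#> preston_histogram:
#>     [1,2)     [2,4)     [4,8)    [8,16)   [16,32)   [32,64)  [64,128) [128,256) [256,512)
#>       228       117        29        16        34        31        33        11         1

diversity_profile(fx$av)
#>   richness shannon    pielou    simpson    hill1    hill2
#> 1      500 4.90536 0.7893273 0.01142694 135.0114 87.51247

# two-step hierarchical ABC fit (desk scale; production would use 1e6-1e7)
fit <- two_step_fit(fx$av, model_kind = 2,
                    config = abc_config(n_sims = 1e5, seed = 1))
fit$results[, c("theta_rare", "theta_abundant", "n_accepted")]
#>   theta_rare theta_abundant n_accepted
#> 1   651.7455       12.15639       2415
```

The fitted `theta_rare` ≈ 652 and `theta_abundant` ≈ 12.2 recover the
generating values (1000 and 10.2) within the posterior spread expected at
this proposal count: the rare-niche biodiversity is the larger by nearly
two orders of magnitude, which is the substantive readout. `n_accepted` is the
number of accepted step-2 draws behind the medians; zero acceptances would
be flagged, not an error.

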