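# slimediv

Succession analysis for subsurface microbial communities exposed to
dihydrogen — the situation created when H₂ is stored in, or leaks into,
deep aquifers used for underground gas storage (UGS). Communities in
these reservoirs (SLiMEs: subsurface lithoautotrophic microbial
ecosystems) reorganize sharply when H₂ arrives: fermenters are
suppressed, H₂-fed sulfate reducers, methanogens and acetogens bloom.
`slimediv` is for microbial ecologists asking whether communities from
*different* aquifers, given the same forcing, converge taxonomically —
deterministic assembly — or stay apart — dispersal limitation.

## The statistic at the core

Between-experiment beta diversity is the incidence-based Jaccard
dissimilarity of ASV presence sets,

d_J(A, B) = 1 − |A ∩ B| / |A ∪ B|,

computed at three matched time categories per experiment pair (Before /
After / Furthest, relative to the first H₂ injection at day 0). Raw d_J
is uninterpretable across pairs with different richness, so each
observed value is normalized against a **mock-community null model**:
the two experiments' total observed ASV sets are pooled (all samples,
regardless of time), 10,000 mock communities are drawn as uniform
subsets with richness matched to the two observed samples, and 1,000
disjoint mock pairs yield a null distribution of Jaccard values. The
observed dissimilarity becomes

z = (d_obs − μ_null) / σ_null,

with z < −1.96 meaning the pair shares more ASVs than random assembly
from its pooled biodiversity predicts. Each pair's z-triple is
classified as `persistent_convergence`, `progressive_convergence`,
`transient_convergence` or `null_like`. Around this core the package
provides alpha-diversity trajectories (richness, Stoddart = inverse
Simpson, Shannon, Pielou), a Spearman check that z is not confounded
with sampling-day gaps, genus-level metabolic guild profiling with a
chord-diagram edge-list export, sampling-loss correction for closed-
reactor chemistry series, and a seeded synthetic-data generator
emulating multi-experiment ASV time series.

## Worked example

The default configuration simulates five experiments in the observed
richness range (27–86 ASVs per sample) with an engineered shared pool
for experiments 2–4, then runs the full analysis:

```r
library(slimediv)

report <- run_pipeline(run_config(sim = sim_config(), seed = 1))
report
#> SLiME succession report
#>   5 experiments, 30 pair-category beta results
#>   patterns:
#>     exp1-exp2: null_like
#>     exp1-exp3: null_like
#>     exp1-exp4: null_like
#>     exp1-exp5: null_like
#>     exp2-exp3: persistent_convergence
#>     exp2-exp4: persistent_convergence
#>     exp2-exp5: null_like
#>     exp3-exp4: persistent_convergence
#>     exp3-exp5: null_like
#>     exp4-exp5: null_like
```

The three engineered pairs — and only those — are recovered as
persistently convergent. Looking at one of them:

```r
dplyr::filter(report$beta, pair == "exp2-exp3") |>
  dplyr::select(pair, category, observed_jaccard, z, significant)
#> # A tibble: 3 × 5
#>   pair      category observed_jaccard     z significant
#>   <chr>     <fct>               <dbl> <dbl> <lgl>
#> 1 exp2-exp3 Before              0.62  -6.71 TRUE
#> 2 exp2-exp3 After               0.602 -7.46 TRUE
#> 3 exp2-exp3 Furthest            0.606 -7.51 TRUE
```

Even though the two communities look 60% dissimilar in raw Jaccard
terms, they sit 6.7–7.5 standard deviations *below* the null — they
share far more ASVs than chance assembly from their pooled biodiversity
would produce. The bias check confirms the normalization is not driven
by sampling-day gaps:

```r
report$bias
#> # A tibble: 1 × 4
#>       n    rho p_value biased
#>   <int>  <dbl>   <dbl> <lgl>
#> 1    30 -0.177   0.350 FALSE
```

`plot_alpha(report$alpha)`, `plot_beta_z(report$beta)` and
`plot_guilds(report$guild_trajectories)` draw the standard figures;
`write_report(report, "out/")` emits everything as TSV/CSV/JSON. See the
vignette (`vignettes/hydrogen-succession.Rmd`) for the model, its
assumptions and the design choices.

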