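---
title: "Null-model beta diversity for hydrogen-amended aquifer communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Null-model beta diversity for hydrogen-amended aquifer communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slimediv)
library(dplyr)
```

## The scientific question

Deep aquifers used for underground gas storage (UGS) host subsurface
lithoautotrophic microbial ecosystems (SLiMEs) fed by dissolved gases
rather than photosynthesis. Injecting dihydrogen into such a reservoir is
a strong environmental forcing: H2 is the preferred electron donor of
sulfate reducers, hydrogenotrophic methanogens and acetogens, while high
H2 partial pressure inhibits many fermenters. A central question for H2
storage is whether communities from *different* aquifers, subjected to
the same forcing, converge taxonomically (deterministic assembly) or stay
apart (dispersal limitation, stochastic assembly).

`slimediv` implements the statistical machinery for answering that
question from amplicon sequence variant (ASV) time series of several
independent incubation experiments:

* per-sample **alpha diversity** (richness, the Stoddart index, Shannon,
  Pielou) through time;
* **incidence-based beta diversity** between experiments at matched time
  categories, normalized against a **mock-community null model**;
* **classification** of each experiment pair's dynamics into four
  convergence patterns;
* **metabolic guild profiling** via a static genus-to-guild/KEGG-module
  table, with core-community extraction and a chord-diagram edge list;
* a seeded **synthetic-data generator** so that the whole pipeline can be
  exercised, tested and calibrated without sequencing data.

## Time categories

Within each experiment, samples are reduced to three categories relative
to the first H2 injection (day 0): **Before** is the latest pre-injection
sample, **After** the earliest sample with day ≥ 0, and **Furthest** the
latest post-injection sample strictly before the next perturbation (a
second injection or the first post-injection water refill), falling back
to the last sample when no such event exists. The published convention of
"one day prior to injection" is generalized to "latest pre-injection
sample" so arbitrary sampling grids work; day 0 belongs to After. For
experiments with several injections, Furthest is anchored to the *first*
injection with the next-injection cutoff — an explicit choice, since the
alternative anchoring is equally defensible; users with multi-injection
designs should check `assign_timepoints()` output.

## The mock-community null model

Observed Jaccard dissimilarity between two communities,
$d_J = 1 - |A \cap B| / |A \cup B|$, is hard to interpret on its own:
its neutral expectation depends on the sizes of the two presence sets and
of the regional pool. `build_null()` therefore constructs, for each
experiment pair, a null distribution by resampling:

1. pool the two experiments' total observed ASV sets (union over **all**
   their samples, regardless of time);
2. draw `n_mock` (default 10,000) mock communities, each a uniform
   without-replacement subset of the pooled ASVs, with richness
   alternately matched to the observed richness of the two real samples
   being compared;
3. form `n_pairs` (default 1,000) disjoint pairs from consecutive draws
   and record their Jaccard dissimilarities, discarding surplus
   communities (10,000 mocks support at most 5,000 disjoint pairs; the
   first 1,000 are used).

The observed dissimilarity is then expressed as
$z = (d_{obs} - \mu_{null}) / \sigma_{null}$. `|z| > 1.96` marks
departure from the central 95% band; *convergence* calls use the lower
tail only (`z < -1.96`), since a negative z means the two communities
share more ASVs than random assembly from their pooled biodiversity
predicts.

Two conventions deserve emphasis:

* **Richness matching.** Mock richness is matched to the two observed
  samples, preserving the set sizes that Jaccard is sensitive to. This
  is a documented choice — published analyses of this kind do not always
  state their convention, and z magnitudes are not comparable across
  conventions.
* **Abundances are ignored.** Mock sampling is uniform over ASV
  identities, matching the incidence-based statistic. No
  abundance-weighted dissimilarity (Bray–Curtis, UniFrac) is provided.

The z normalization is calibrated: when observed pairs are drawn by the
null's own scheme, z has mean ≈ 0 and `|z| > 1.96` occurs with
probability ≈ 0.05. The band is asymptotically normal; at small pools
(tens of ASVs) the Jaccard null is discrete and skewed, and the 95% band
is only approximate. The test suite checks calibration at a pool of 500
ASVs with richness 150 and 200, where the exact exceedance of the band
is 0.047.

Degenerate nulls (`sd = 0`, e.g. when both mock richnesses saturate the
pool) are flagged and the z reported as missing with a reason code
rather than as infinite.

## Convergence patterns

Each pair's three z-scores (Before / After / Furthest) are classified
with lower-tail significance `sig = z < -1.96` (strict, with a 1e-9
floating-point guard at the boundary):

| label | rule |
|---|---|
| `persistent_convergence` | sig at all three categories |
| `progressive_convergence` | not sig Before, sig Furthest |
| `transient_convergence` | not sig Before, sig After, not sig Furthest |
| `null_like` | otherwise |

Precedence is persistent > progressive > transient > null_like.
Combinations outside the four narrative cases (e.g. sig Before only) map
to `null_like` with an `atypical` flag; missing categories are treated as
not significant and flagged `partial`.

Because samples compared "at equivalent times" are rarely taken on the
same day, `time_differential_bias_check()` runs a two-sided Spearman
correlation between the day gap `|day_a - day_b|` and z; a small p-value
indicates the normalization is confounded with sampling asynchrony.
Exact p-values are not attempted under ties (`exact = FALSE` in
`cor.test()`); an all-tied gap vector yields a missing result rather
than a spurious one.

## Alpha diversity

The Stoddart index is implemented as the reciprocal of Simpson's
concentration, $1 / \sum_i p_i^2$ — the standard reading of "an analog
of the Simpson index" (Stoddart & Taylor's genotypic diversity). It is
insensitive to the artificial richness inflation that ASV-level
resolution can produce, which is why it is preferred over raw richness
for these data; a Gini–Simpson variant ($1 - \sum p_i^2$) is available
via `stoddart(type = "gini")` for sensitivity analyses. Shannon uses the
natural logarithm (the vegan default), which makes Pielou evenness
exactly $H / \ln S$. Indices are computed on counts as given — no
rarefaction is applied, and all indices are invariant to per-sample
scaling.

## Sampling-loss correction

Each sampling withdraws liquid or gas from a closed reactor, so raw
molar time series understate what the system produced.
`correct_sampling_loss()` adds back the cumulative withdrawn amounts:
`corrected(t_k) = measured(t_k) + sum(removed(t_j), j <= k)`, taking the
measured value to reflect the post-withdrawal content at each sampling
event. This minimal mass-balance form makes a non-reacting analyte in a
closed system exactly constant, which is the property the test suite
checks.

## The guild layer

Sequence-based functional inference (placement, hidden-state prediction)
is out of scope. It is replaced by a transparent, editable
genus-to-guild table shipped with the package: sulfate reducers
(dissimilatory sulfate reduction, KEGG module M00596), hydrogenotrophic
methanogens (M00567), Wood–Ljungdahl acetogens (M00377) and fermenters
(`FERM`), seeded with genera recurrently observed in H2-amended aquifer
incubations (*Thermodesulfovibrio*, *Desulfocucumis*,
*Methanothermobacter*, *Acetobacterium*, *Rectinema*, ...). The
fermentation KO list is a placeholder — curated enrichment lists exist
but are not redistributable here — and must be replaced for real
analyses (`read_guild_table()` accepts any TSV in the same shape).
Multi-guild genera are allowed; trajectory summaries dual-count them
with full weight per guild, so only single-guild tables partition
per-day abundance exactly (the `unannotated` fraction completes the sum
to 1).

`chord_edges()` exports one edge per (present ASV, time point, KO of the
ASV's guild modules), weighted by relative abundance — edges are
attribute fan-outs, not weight splits — ordered within genus by
decreasing weight, ready for generic circular-layout tools. The layout
itself (hierarchical clustering, edge bundling) is not reproduced.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure the analysis
assumes, not the biology of any particular aquifer. Each sample is a set
of ASVs of configured richness (default uniform per experiment in
27–86, the observed range in these incubations), composed of three
layers:

* an **engineered shared core** for designated experiments (default
  experiments 2–4): a nested prefix of a reserved pool block, so that
  designated pairs share `shared_pool_fraction * min(r)` ASVs at every
  time point. These ASVs are assigned to the H2-fed guilds, mirroring
  the observation that convergent cores in H2-fed incubations are built
  from sulfate reducers, methanogens and acetogens — and making the core
  robust to the injection response;
* a **persistent private part** that evolves with per-ASV turnover 0.05
  per sampling step (keeping consecutive samples similar, hence strongly
  negative within-experiment z);
* a **transient slice** (default 0.50 of the private part) redrawn fresh
  every sampling day from the experiment's large private pool. This
  emulates the rare, flickering detections that dominate real ASV tables
  and controls the ratio of cumulative experiment pool to per-sample
  richness (~2–2.5x here). The ratio matters: the null model pools
  *cumulative* ASV sets, and if it barely exceeds per-sample richness,
  mock communities overlap so heavily that even complete engineered
  sharing cannot fall below the −1.96 band. At 0.30 the engineered
  convergence of richness-asymmetric pairs (e.g. 30 vs 80 ASVs) sits
  right at the detection boundary; 0.50 places the generator in the
  regime the analysis assumes and matches the cumulative-to-sample
  ratios typical of such time series.

The injection response has two independent dials, so alpha and beta
effects can be toggled separately: each fermenter-guild ASV is lost with
probability 0.45 at the first injection (driving the post-injection
richness drop), and sulfate-reducer/methanogen abundances are multiplied
by 5 from day 0 on (driving guild-fraction shifts and post-boost
dominance). Counts are drawn by multinomial resampling of log-normal
relative abundances (sdlog 1.5) at fixed depth 10,000, with a detection
floor: any engineered-present ASV that the multinomial zeroes out
receives one count moved from the most abundant ASV, so realized
presence equals engineered presence and depth stays exact.

Default sampling days, injection schedules (one 10% injection for
experiments 1–2, three smaller ones for 3 and 5, one for 4) and refill
days mirror the five-reactor design the package targets. All randomness
descends from one root seed through labelled child seeds
(`child_seed()`), one per experiment and one per experiment pair, so
adding a sixth experiment leaves the first ten pairs' results bit-
identical.

**What passing tests do not show.** The generator draws ASVs
exchangeably from a pool: it has no phylogenetic structure, no
compositional correlation between taxa, no PCR/chimera artifacts beyond
an optional singleton spike, and the log-normal abundance model is a
stand-in (the real communities' abundance distribution is unknown).
Tests passing on synthetic data demonstrate that the *statistics* behave
as designed under their own assumptions, not that any particular real
community will show convergence.

## Numerical and design choices

* One root seed; per-stage child seeds via a 31-ary rolling hash of the
  stage label modulo 2^31 − 1 (`child_seed()`); `build_null()` saves and
  restores the caller's RNG state.
* Strict inequality at the ±1.96 band edge, with a 1e-9 guard against
  floating-point rounding.
* Within-experiment comparisons default to consecutive samples (all
  pairs available via `consecutive = FALSE`); the null is built from the
  experiment's own cumulative pool.
* The singleton filter removes ASVs with total count 1 per experiment
  table, not across experiments, and is idempotent.
* cDNA profiles are the default analysis substrate (they track the
  active community); DNA tables can be generated (`emit_dna`) and
  selected (`nucleic_acid = "DNA"`).
* Test problem sizes: property checks run the null at 2,000 mocks /
  1,000 pairs across 100 generator seeds, calibration at 10,000 / 1,000
  with 1,000 replicates, and exhaustive Jaccard enumeration up to
  universe size 6 — sizes chosen so the whole suite completes in a few
  minutes while keeping standard errors far below the margins being
  asserted.

## Limitations

* z magnitudes depend on the richness-matching convention; results are
  comparable only within one convention.
* The 95% band is approximate for pools below ~100 ASVs.
* The guild table is genus-level and static; it cannot capture
  strain-level metabolic variation, and its fermentation KO list is a
  placeholder.
* `Furthest` anchoring for multi-injection designs is a convention (see
  above).
* No abundance-weighted or phylogenetic beta diversity.
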