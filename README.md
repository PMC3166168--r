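# fissionet

Social-structure analysis for fission-fusion animal populations from
repeated scan samples of group membership.

Many animal societies — the motivating system is wild-caught guppy shoals
observed in laboratory arenas — are *fission-fusion*: groups split and
merge continuously, and the interesting biology lives in who associates
with whom, how strongly, and for how long. `fissionet` implements the
full analysis stack for such data:

* **Association indices.** From scans recording which individuals shared
  a group (the 4-body-length chain rule defines "a group"), the simple
  ratio index `AI = x / (x + y_AB + y_A + y_B)` estimates the proportion
  of time a dyad spends together (half-weight variant included).
  Population summaries: gregariousness (mean experienced group size − 1)
  and social differentiation S, the CV of the *true* association
  probabilities after removing binomial sampling noise,
  `S² = max(0, var(AI) − mean(AI(1−AI)/d)) / mean(AI)²`, with a power
  diagnostic.
* **Permutation null models.** Margin-preserving checkerboard swaps on
  the group-by-individual matrix (group sizes and each individual's
  group count conserved) test for non-random association via the CV of
  the indices, for group-size preferences via the spread of typical
  group size, and flag individual dyads as preferred/avoided at the
  97.5% / 2.5% quantiles of their own null distributions.
* **Weighted network measures.** Strength, eigenvector centrality,
  reach, clustering coefficient and affinity, with bootstrap SEs over
  sampling periods.
* **Temporal structure.** The lagged association rate g(τ) — the
  probability an association persists τ time units — on minute and day
  scales with jackknife SEs, fitted by binomial quasi-likelihood to
  exponential decay models (constant companions, casual acquaintances,
  and the two-timescale `g(τ) = a·e^(−bτ) + c·e^(−dτ)`), selected by
  QAIC (`−2 lnQL/ĉ + 2k`), and compared between population classes with
  pooled t-tests under Benjamini–Yekutieli FDR control.
* **Synthetic data with known ground truth.** Four seeded generators
  emulate the study design (12 individuals, 30 scans/day, 4 days):
  exchangeable noise, Beta-distributed dyadic preferences, a
  two-timescale bonded-Markov society, and a spatially explicit arena
  with chain-rule grouping.

## Worked example

A packaged synthetic population (generated by the bonded-Markov model
with mostly-casual plus 15% bonded dyads — the file is labelled
synthetic; no real observations are distributed):

```r
library(fissionet)
obs <- read_observations(system.file("extdata",
  "synthetic_highrisk_population.csv", package = "fissionet"))
obs
#> observation_set: 12 individuals, 120 sampling periods over 4 day(s), 1440 group-membership rows

summ <- association_summary(obs)
# mean AI 0.066 | gregariousness 0.726 | S 1.589 (power r = 0.98)

permutation_test_cv(obs, permutation_config(1000, 500, seed = 1))
#> Permutation test: cv_of_association_indices
#>   observed = 1.6189, null mean = 0.3400 (1000 permutations)
#>   p_high = 0.0000, p_low = 1.0000 (attainable min 0.001)

dyadic_significance(obs, permutation_config(1000, 500, seed = 1))
#> Dyadic significance: 66 dyads; 7 preferred, 19 avoided, 0 untestable

bs <- bootstrap_network_ses(obs, n_boot = 1000, seed = 1)
round(rbind(mean = bs$means, se = bs$se), 3)
#>      strength eigenvector reach clustering affinity
#> mean    0.726       0.243 0.674      0.196    0.898
#> se      0.035       0.007 0.057      0.017    0.042

set.seed(1)
sel <- select_lar_model(lar_curve(obs, "minute"))
sel$best
#> lar_fit: rd_2ca (k = 4), lnQL = -10624.441, converged = TRUE
#>   theta: a = 0.3977, b = 1.743, c = 0.6023, d = 0.01318
#>   timescales: 1/b = 0.5736, 1/d = 75.85
```

Reading: the observed CV of association indices (1.62) is far above its
permutation null (0.34, p at the attainable minimum), so companionship is
non-random; 7 dyads show significant preference and 19 avoidance. Mean
strength (0.726) equals (N−1) × mean AI exactly, an identity the package
asserts. The QAIC-best temporal model is rapid disassociation with two
levels of casual acquaintances: about 40% of associations dissolve on a
sub-minute time scale (1/b ≈ 0.6 min) and 60% on a ~76-minute scale
(1/d), against a null association rate of 0.066 — short-lived shoals
embedded in a slowly decaying bonded structure, which is exactly how the
generator built the population.

## The analysis workflow

`analysis/01_simulate.R` … `07_compare_classes.R` run a complete
twelve-population study (7 "high-risk" and 5 "low-risk" populations with
class-specific fission dynamics), writing tables under `results/`:
association summaries, permutation tests, a network-measures-by-class
table, LAR curves with jackknife SEs, QAIC model selection per
population, and the between-class comparison of the fitted decay
parameters (pooled t, df = n₁+n₂−2 = 10, BY-adjusted critical value
0.024 for the four dependent comparisons). Run them in order from the
repository root:

```sh
Rscript analysis/01_simulate.R
...
Rscript analysis/07_compare_classes.R
```

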