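# bruiseAge

Forensic age determination of human-inflicted bruises in slaughter pigs, from
semi-quantitative histology to between-lesion agreement statistics.

When pigs arrive at slaughter with multiple blunt-trauma bruises, the key
forensic question is *when* the lesions were inflicted — during transport and
lairage (the slaughterhouse's responsibility) or earlier, on the farm. The
age of a bruise is read from its inflammatory response: neutrophils invade
the subcutis within the first hours, macrophages accumulate in the underlying
muscle somewhat later. `bruiseAge` implements this pipeline end to end for
veterinary pathologists and epidemiologists:

1. **Data model** — a validated CSV schema for per-bruise histology: presence
   or absence of hemorrhage and hyper-leukocytosis in dermis, subcutis and
   muscle; neutrophil and macrophage infiltration scored 0–3 in the densest
   40× field (0 = absent, 1 = 1–10 cells, 2 = 11–30, 3 = >30); muscle
   necrosis scored 0–3 by area; leukocyte localization.
2. **Age estimation** — each score maps to a calibrated age interval in hours
   (neutrophils, subcutis: 1 → [1, 3], 2 → [1, 8], 3 → [4, 10]; macrophages,
   muscle: 1 → [2, 9], 2 → [2, 10], 3 → [4, 10]). The two intervals are
   combined: intersection when they overlap (the narrowest interval
   consistent with both), the higher score's interval when disjoint, the
   single available interval when one score is 0, inconclusive when both are.
   The combined interval is classified as *<4 h*, *>4 h*, *overlapping 4 h*
   or *inconclusive*.
3. **Agreement analysis** — for two bruises (a, b) sampled from each pig,
   unweighted Cohen's kappa per histological variable and for the age
   category, computed from the defining formulas:
   κ = (p_o − p_e)/(1 − p_e), with SE(κ) = √(p_o(1 − p_o)/(n(1 − p_e)²)) for
   the 95 % CI, a one-sided test of κ = 0 under the null variance, and
   Landis–Koch interpretation labels gated on significance.
4. **Synthetic cohorts** — a seeded generator in which all bruises on a pig
   share one latent infliction-to-slaughter time (transport + lairage, each
   truncated-normal), and scores are emitted around the calibrated value with
   a tunable noise parameter. It supports the sampling-design question: how
   many lesions must be examined before a consensus age is trustworthy?

## Worked example

Agreement in the estimated age of two bruises across the packaged 81-pig
cohort cross-tabulation:

```r
library(bruiseAge)
cohen_kappa(published_age_crosstab())
#> Cohen's kappa (unweighted)
#>   kappa = 0.24, 95% CI [0.08, 0.40], n = 81
#>   one-sided test of kappa = 0: z = 3.363, p = 0.0004 (fair)
```

Only *fair* agreement: the two lesions of the same pig — inflicted minutes
apart — often land in different age categories, which is why sampling only
two bruises is a thin basis for one overall age call. The simulator
quantifies that directly:

```r
consensus_probability(simulation_config(seed = 3), k = 2, reps = 10000)$estimate
#> [1] 0.5387
consensus_probability(simulation_config(seed = 4), k = 4, reps = 10000)$estimate
#> [1] 0.2508
```

At the default emission noise, even two bruises agree on a single category
only ~54 % of the time, and demanding unanimity from four drops to ~25 % —
more lesions give more information precisely because they disagree.
A full synthetic cohort analysis:

```r
sim <- generate_cohort(simulation_config(n_pigs = 81, seed = 2))
fit <- bruise_agreement(sim$cohort)   # per-variable kappas, crosstab, marginals
fit$results$age_category$kappa        # 0.24 at the default noise regime
combine_intervals(2, 3)
#> Bruise age: [4, 8] h (over_4h; rule: intersection)
#>   neutrophils (subcutis) score 2, macrophages (muscle) score 3
```

A command-line front end (`inst/cli/bruise-age`) exposes the same pipeline as
`simulate`, `estimate`, `agree` and `report` subcommands.

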