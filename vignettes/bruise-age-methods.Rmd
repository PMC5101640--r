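---
title: "Methods: bruise age estimation and between-lesion agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bruise age estimation and between-lesion agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bruiseAge)
```

## The problem

Human-inflicted bruises on slaughter pigs are multiple, uniform in pattern
and located on the back or upper sides, consistent with repeated strikes over
a period of minutes. The forensic question is the lesions' age relative to
slaughter, answered histologically from the inflammatory response in skin and
underlying muscle. This vignette documents the models and numerical choices
the package makes, and what its synthetic cohorts can and cannot show.

## Scoring scheme and data contract

Each bruise contributes one row: hemorrhage and hyper-leukocytosis (capillary
pavement of leukocytes) recorded present/absent in dermis, subcutis and
muscle; leukocyte infiltration in the dermis present/absent; neutrophil and
macrophage infiltration in subcutis and muscle on the ordinal scale 0
(absent), 1 (1–10 cells), 2 (11–30), 3 (>30) counted in the densest 40×
field; muscle necrosis 0 (none), 1 (<12.5 % area), 2 (12.5–50 %), 3 (>50 %);
and the predominant leukocyte localization in muscle (interstitial,
intramuscular, or not applicable when no muscle leukocytes were seen).

Validation is total: every cell of every row is checked on load, out-of-range
ordinals are rejected with the offending row and column named, and presence
variables are serialized as the strings `present`/`absent` rather than 0/1 so
they cannot be confused with scores. `(pig_id, bruise_label)` must be unique.
Labels beyond `a`/`b` are allowed so that k-bruise simulations reuse the same
schema.

## Age estimation

The calibration maps scores to closed integer-hour intervals post-infliction:

```{r}
full_combination_table()
```

Two pieces of evidence per bruise — the subcutis neutrophil score and the
muscle macrophage score — are combined as follows:

* both 0: inconclusive (no interval);
* exactly one 0: the other interval is used alone. A single zero does not
  make the bruise inconclusive; only the joint absence of both cell types
  does;
* both nonzero, intervals overlapping: their set intersection. The
  intersection is the narrowest interval consistent with both observations,
  which is the stated intent of the combination;
* both nonzero, intervals disjoint: the interval of the strictly higher
  score. Under the calibration above, only the pair (neutrophil 1,
  macrophage 3) is disjoint, so a *tie* of equal scores with disjoint
  intervals is unreachable; the implementation still defines its behaviour —
  a contract error — rather than silently guessing a rule that was never
  specified.

The combined interval is assigned to one of four mutually exclusive
categories: `inconclusive`, `under_4h` (upper bound < 4), `over_4h` (lower
bound ≥ 4), `overlapping_4h` (anything straddling 4). Two boundary
conventions are fixed here because no reachable interval decides them: an
interval with lower bound exactly 4 is `over_4h`, and an interval with upper
bound exactly 4 would be `overlapping_4h` (no calibrated interval has upper
bound 4, so the choice is documentation, not behaviour). Intervals are kept
as printed integer bounds; no continuous-time interpolation is attempted, and
necrosis, hemorrhage and localization never enter the age call — they are
descriptive and feed only the agreement report.

## Agreement statistics

For paired calls on bruises a and b over the same category set, with observed
agreement $p_o$ (diagonal proportion) and chance agreement
$p_e = \sum_i p_{i\cdot} p_{\cdot i}$,

$$\kappa = \frac{p_o - p_e}{1 - p_e},\qquad
\widehat{SE}(\kappa) = \sqrt{\frac{p_o(1-p_o)}{n(1-p_e)^2}}.$$

The 95 % confidence interval is $\kappa \pm z_{0.975}\,\widehat{SE}$. The
test of $\kappa = 0$ uses the null-variance standard error
$\sqrt{p_e + p_e^2 - \sum_i p_{i\cdot}p_{\cdot i}(p_{i\cdot}+p_{\cdot i})}
/ ((1-p_e)\sqrt{n})$ and reports the one-sided upper-tail p-value, the
convention of the common R implementations of this test. Note that a
two-sided convention would double these p-values; published tables built with
either convention agree on which variables are significant at the usual
levels, so the package treats small p-value discrepancies as display-level,
not substantive.

Choices worth calling out:

* **Unweighted kappa everywhere**, including the ordinal 0–3 scores, which
  are treated as nominal. A weighted kappa would credit near-misses, but the
  reference analyses of this design report a single unweighted kappa per
  variable, and mixing conventions across rows would make the report
  incoherent.
* **Degenerate tables** — a variable constant across all bruises puts all
  mass in one cell, $p_e = 1$, and kappa is undefined. Real cohorts produce
  these (e.g. hyper-leukocytosis absent in every muscle sample), so the
  result is flagged `degenerate` (kappa reported as 0, CI and p as NA) and
  the report still renders, instead of the whole analysis throwing.
* **Significance gate before banding**: a result whose one-sided p ≥ α *or*
  whose CI covers 0 is labelled `not_significant`; only significant results
  are banded on the Landis–Koch scale ((0, 0.2] slight, (0.2, 0.4] fair,
  (0.4, 0.6] moderate, (0.6, 0.8] substantial, (0.8, 1] almost perfect).
  With a one-sided test and an α-level CI these two gates can disagree near
  the boundary; requiring both keeps the label conservative.
* **Localization** is expanded into two binary indicators (predominantly
  interstitial yes/no, predominantly intramuscular yes/no), mirroring the
  two-row presentation of this variable in agreement reports;
  `not_applicable` counts as "no" for both.
* Pigs missing either paired bruise are excluded and *listed* in the result;
  per-variable n is the number of complete pairs.
* Display rounding: kappa and CI bounds to 2 decimals, p to 4; marginal
  percentages round half away from zero to integers.

## The synthetic cohort generator

The generator encodes the study's structural premise: all bruises on a pig
are inflicted near-simultaneously, at one latent time $t$ hours before
slaughter. Its defaults are the study conditions:

* **Time model**: $t$ = transport + lairage, each normal truncated at 0,
  with means 2.13 h and 3.03 h and SDs 3.33 h and 3.44 h — the herd-level
  logistics reported for the cohort. Both components are overridable.
* **Emission model**: at time $t$, each cell type has a modal score — the
  lowest score whose calibrated interval contains $t$ (the tie at
  $t \in [4,8]$ h between neutrophil scores 2 and 3 breaks toward 2),
  score 0 before any interval opens, and score 3 beyond 10 h. Observed
  scores leak geometrically around the mode:
  $P(k) \propto \eta^{|k - s(t)|}$ with noise $\eta \in [0, 1)$, so
  $\eta = 0$ is deterministic and $\eta \to 1$ approaches uniform. This
  one-parameter family is a documented stand-in: the source data show
  *substantial* between-lesion variation but no distributional form. The
  default $\eta = 0.35$ was chosen as a moderate-noise regime producing
  visible between-lesion disagreement; `calibrate_noise_to_kappa()`
  confirms it sits near the noise level that reproduces the observed
  between-lesion kappa of 0.24 at n = 81.
* **Ancillary variables** exist so agreement reports have every row, and are
  deliberately simple conditionals on $t$: hemorrhage present with
  probability 0.95/0.90/0.80 by layer (a bruise is a hemorrhage, with
  sampling/sectioning loss); hyper-leukocytosis with probability
  $\mathrm{logit}^{-1}(t - 2)$ (an early vascular sign); dermal leukocyte
  infiltration with probability $\mathrm{logit}^{-1}(t - 3)$; necrosis
  emitted with the same geometric leak around a base that steps 0/1/2/3 at
  1/4/8 h; localization interstitial with probability 0.7 when any muscle
  leukocytes are present, `not_applicable` otherwise. The two non-age cell
  scores (subcutis macrophages, muscle neutrophils) are emitted from the
  same timing maps as their age-determining counterparts.

`consensus_probability()` estimates, by Monte Carlo with a binomial standard
error, the probability that all $k$ bruises of a pig land in the same age
category. `calibrate_noise_to_kappa()` bisects the empirical noise→kappa
curve; the curve's monotone decrease over the bracket is verified from
endpoint and midpoint estimates before the search begins, and targets outside
the achieved range produce a diagnostic error rather than a boundary value.

### What the simulator does and does not emulate

It reproduces the *structure* of the design — shared latent time, independent
per-bruise score variation, the calibrated score→interval map — and is
therefore a valid test bed for the pipeline's logic and for sampling-design
questions (how consensus degrades with k, how agreement degrades with noise).
It does not model inflammation kinetics, spatial correlation between nearby
lesions, observer effects, or lesion ages beyond the 1–10 h calibration
window, and its noise family is a convenience choice. Passing simulation
tests therefore validates the method's internal consistency, not the
biological calibration itself.

## Numerical and testing choices

Problem sizes were chosen to make Monte-Carlo checks decisive while keeping
the default test run fast: noise-grid checks use 500-pig cohorts averaged
over 20 replicates per grid point; calibration self-consistency uses 40
cohorts per bisection step at n = 81 and 50 replicates for the recovery
check (tolerance ±0.10, reflecting the sampling spread of kappa at n = 81);
marginal-recovery checks use 10,000 pigs against a numerically integrated
(grid convolution, step 0.01 h) analytic marginal, with a 3-standard-error
band. Kappa is validated against a brute-force recomputation from the
defining sums on 1000 random tables to 1e-12. All simulations are seeded;
identical configuration and seed give byte-identical cohorts.

## Known limitations

* The score→interval calibration is taken as given; the package does not
  re-derive it from experimental data, and ages outside 1–10 h are only
  representable as censored endpoints of the calibrated intervals.
* The one-sided p-value convention can differ by a factor of ~2 from
  two-sided reports of the same tables.
* Gross lesion patterns (tramline, tattoo-hammer, paddle, double-U, circle,
  chain) are carried as free-text metadata only; pattern recognition is out
  of scope.
* Unweighted kappa understates partial agreement on the ordinal scores.
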