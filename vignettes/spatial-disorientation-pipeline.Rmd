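---
title: "Scoring spatial-navigation tests and predicting real-world disorientation risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring spatial-navigation tests and predicting real-world disorientation risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navdis)
```

## The problem this package models

Spatial disorientation — not knowing where you are or how to reach an
intended place — is among the earliest and most consequential behavioural
symptoms of Alzheimer's disease: patients get lost in their own
neighbourhoods, with serious downstream harms. Tablet-based virtual-reality
navigation tests are attractive screening tools because they are cheap and
standardised, but whether performance on them predicts *real-world*
disorientation risk is an open question. This package implements, as
reusable and tested code, the full measurement and analysis chain of a
study design that asks exactly that: two VR tests and one accompanied
real-world walking test, scored per participant, compared between a patient
and a control group, and linked by regression and risk-classification
models. Because individual-level data from such studies are not publicly
deposited, the package ships a synthetic-cohort generator that reproduces
the published group-level summary statistics, so every stage of the
pipeline can be exercised and validated end to end.

## The three test scores

**Virtual Supermarket Test (VST).** Fourteen passive-viewing trials; after
each, three answers are scored: the egocentric direction of the start
location (percent correct), the destination marked on a blank map
(allocentric; mean Euclidean displacement between answer and truth,
expressed as a percentage of map size), and the final heading direction
(percent correct). `score_vst()` computes all three over the trials
present. The map-size normaliser for displacement is the map **diagonal**
by default, so 100 is the largest possible error and the score is bounded
in [0, 100]; dividing by map width instead is available via
`normalizer = "width"` because "percent of map size" admits either reading.
Direction answers are closed categorical sets compared by exact equality —
the published outcome is plain percent correct, so no partial credit is
given.

**Sea Hero Quest (SHQ).** Wayfinding levels (memorise a map, then steer a
boat through numbered checkpoints) yield total distance travelled and
duration; both are divided by per-level reference constants
(`shq_wayfinding_scores()`), higher meaning worse. The reference constants
are deliberately configuration, defaulting to 1: the published normalisation
is not recoverable from the summary statistics alone, and every downstream
group contrast (t, rank-sum, Cohen's d) is invariant to a positive rescale,
so the default changes nothing that this pipeline tests. Only level 6 feeds
the analysis — the one wayfinding level administered to every participant.
Flare levels (shoot a flare back toward the start after a series of turns)
earn 1–3 stars; `flare_accuracy()` weights each level's stars by its number
of turns (one 90° turn in levels 9/14/19, four in level 49), i.e.
`sum(stars * turns) / sum(turns)`, so the hard four-turn level carries four
times the weight of any one-turn level. Participants who never attempted
the wayfinding level receive the **worst observed score** at the regression
stage (`impute_worst()`): the assumption is that non-attempters would not
have outperformed the weakest completer, and imputation is restricted to
the regression input — group comparisons use observed data only.

**Detour Navigation Test (DNT).** The participant walks a habitual route to
a familiar landmark, then is asked to return home by a non-overlapping
detour. On a street graph (`street_graph()`, GeoJSON round trip provided),
a *wrong turn* is a move at an intersection onto an edge that is neither on
a viable route marked by the experimenter nor in an explicit
`allowed_overlap` set (e.g. the only exit of a cul-de-sac). Two consecutive
wrong turns trigger a reset to the intersection where the first error was
made; in a recorded node sequence this appears as a teleport, which
`detect_wrong_turns()` validates. Two behavioural conventions are needed to
make detection well defined on recorded node paths and are our own: (i) an
immediate backtrack along the edge just taken is self-correction, not a
second wrong turn; (ii) the reset destination is the intersection at which
the first of the two consecutive errors occurred. *Moments of hesitation*
are observer-recorded events carried in the walk's event log.

Each route's disorientation score normalises the two event types by their
opportunity structure (`route_disorientation_score()`): wrong turns per
intersection plus hesitations per km. This "split" normalisation is chosen
because the published component rows (wrong turns, hesitations) sum to the
published route score; a pooled alternative — total events divided by
(distance × intersections) — is available as `mode = "combined"`. The
composite is

$$\mathrm{composite} = \frac{\mathrm{detour\ score} + 1}{\mathrm{original\ score} + 1},$$

with the +1 continuity correction avoiding division by zero for the
(typical) disorientation-free original route. A composite of exactly 1
means no differential disorientation and maps to "low risk";
any departure beyond a numerical tolerance (default `1e-9`; the inputs are
exact rationals of counts, so the tolerance only guards floating-point
division) maps to "high risk". Participants with equal *non-zero* route
scores also produce a composite of 1; we classify them as written (low),
note that the situation did not arise in the motivating cohort — original
routes were essentially error-free — and expose the tolerance should a user
want a different rule.

## The four-step analysis

1. **VR group differences** (`compare_groups()`): per variable, a
   Shapiro–Wilk check at α = 0.05 on each group gates between a
   pooled-variance Student's t-test and the Wilcoxon rank-sum test. The
   rank statistic uses the Mann–Whitney convention (rank sum of the first
   sample minus $n_x(n_x+1)/2$, range $[0, n_x n_y]$), which is the scale
   of the published W values. A pooled-SD Cohen's d,
   $d = |\bar x_1 - \bar x_2| / s_p$ with
   $s_p^2 = ((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)$, is always attached
   and is computable from printed summary statistics alone
   (`cohens_d_pooled()`, `reproduce_reference_effect_sizes()`). Because
   map-view time can drive wayfinding performance, the two wayfinding
   contrasts are re-tested by one-way ANCOVA controlling for map-view
   duration (`ancova_adjusted()`); the positively skewed outcomes are
   inverse-transformed first, and the group effect is the marginal F on
   (1, n − 3) df.
2. **DNT group differences**: the same gated comparison on the two route
   scores. All-zero variables (no events in either group) are tabulated
   without a test, as a rank test is undefined there.
3. **Composite prediction** (patients only,
   `linear_regression_standardized()`): the composite score regressed on
   each VR variable after z-scoring both; reported are β, its two-sided p,
   R², $f^2 = R^2/(1-R^2)$, and a Shapiro–Wilk residual-normality flag.
   Wayfinding non-attempters enter via worst-score imputation.
4. **Risk prediction** (`logistic_risk()`): binomial logistic regression of
   the high/low label on each predictor significant in step 3, reporting
   the odds ratio with its **Wald** p-value. At fifteen patients both Wald
   and likelihood-ratio inference are fragile; complete separation is
   raised as an error rather than returned as a divergent estimate.

No multiple-testing correction is applied anywhere — deliberately matching
the modelled analysis, and worth remembering when reading the per-variable
p-values.

## The synthetic cohort generator

`gen_cohort_scores()` draws each score variable from a truncated normal on
its natural support (percentages on [0, 100], displacement on
[0, 100√2], flare on [1, 3], rates on [0, ∞)). Published means and SDs are
*truncated-distribution* targets, not underlying-normal parameters:
`fit_truncnorm()` solves for the underlying (μ, σ) so that the truncated
mean equals the target exactly and the truncated SD is as close as the
family allows. This distinction matters — feeding the published values in
as underlying parameters would shift the controls' egocentric mean from
81.5 down to about 74 after truncation at 100. Some published moment pairs
are not achievable by any truncated normal (the generator records this per
variable in the `"generator"` attribute): a left-skewed
(mean 81.49, SD 21.67) on [0, 100] caps at SD ≈ 17.6, and the zero-bounded
DNT rates print coefficients of variation up to 8 where the family caps at
1. Recovery tests therefore compare samples against the generator's
*achieved* moments; means are always exact.

The DNT route scores are additionally **zero-inflated**: a point mass at
zero with per-group probabilities matching the published cohort structure
(all controls and 15/16 patients error-free on the original route; 20/21
controls and 8/15 patients error-free on the detour — the published
low-risk group), with the non-zero component moment-matched so the mixture
mean still equals the published mean. Without this, a continuous generator
would make every patient "high risk" and the risk-classification step
degenerate.

A Gaussian copula couples the two wayfinding scores to the detour score
(rank-preserving, applied before the zero-inflation threshold so low
latent navigation ability maps to both worse wayfinding and more detour
disorientation). Its default correlation, 0.55 ≈ √0.29, is back-derived
from the one published R²; the true joint structure is unobserved and this
is an explicit assumption, exposed as `copula_rho`. Map-view duration is
never summarised in the publication; we fixed controls at 40 s (SD 20) and
patients at 55 s (SD 30), plausible for a memorise-then-navigate task in
which patients study the map longer, and these defaults are ordinary
parameters.

One global seed fans out to per-participant substreams (independent
per-group seed vectors), so enlarging a group never perturbs existing
participants' draws. Event-level walks are simulated separately
(`gen_dnt_walks()`): Bernoulli(p) deviations at intersections onto
non-viable edges — with self-correction after one error and the reset
sequence after two consecutive errors — and Poisson(rate × distance)
hesitations; planted events re-detect exactly under `detect_wrong_turns()`.

### What passing tests do and do not show

The generator emulates marginal group distributions, the published
missingness pattern, and one assumed cross-test coupling. It does not
emulate real street networks, gait or GPS measurement noise, observer
subjectivity in hesitation coding, disease-severity gradients, or the
discrete star/trial structure of the raw instruments (flare accuracy is
simulated on its continuous [1, 3] scale, not built from star draws).
Recovery of the published effect-size pattern from synthetic cohorts
validates the *pipeline arithmetic*, not the instruments.

One consequence of simulating at larger n deserves emphasis: published
significance patterns are sample-size statements. The flare-accuracy
contrast (2.30 vs 2.12, pooled SD 0.54, d ≈ 0.33) is non-significant at the
study's n = 21/16, but a two-sample test at n = 200 per group has ≈ 0.9
power for that difference, so simulated cohorts at that size will usually —
correctly — reject. A faithful generator cannot reproduce "flare ns" at
large n while matching the published moments; our recovery suite asserts
mean recovery and effect-size behaviour, and treats the p-value pattern at
inflated n as the sample-size artefact it is.

## Numerical and testing choices

- Truncated-normal sampling is inverse-CDF, with survival-function
  arithmetic in the upper tail so that intervals far from the underlying
  mean neither cancel to zero nor round to probability 1.
- Moment fitting restricts |z-scores| of the bounds to ≤ 36 to stay inside
  double-precision range; the Wilcoxon exact p delegates to the standard
  implementation (exact for small untied samples, tie-corrected normal
  approximation otherwise) and is cross-checked against brute-force
  enumeration of all rank assignments in the test suite.
- Simulation sizes in the suite were chosen so that assertion bands sit at
  ≥ 3 Monte-Carlo standard errors under fixed seeds: e.g. 5 000
  participants for the ±1.0 egocentric-mean check, 3 000 walk pairs for the
  ±2 % hesitation-rate check, n = 2 000 (regression) and n = 1 000
  (logistic) for parameter recovery, and 20 seeds × 200 per group for
  cohort recovery.
- Degenerate inputs fail loudly and specifically: empty trial lists,
  out-of-map coordinates (naming the trial), incomplete wayfinding levels
  (pointing to imputation), duplicate flare levels, negative event counts,
  walks over absent edges (naming the step), zero outcomes under the
  inverse transform, zero-variance predictors, perfect fits, and separated
  logistic models.

## Limitations

Reference wayfinding constants and the exact published displacement
aggregation are unavailable from summary statistics and are configuration
here; the patient n differs between published effect-size rows (the
wayfinding-distance d reproduces only with the 14 attempters, duration and
detour only with all 16), which we reproduce as printed rather than
resolve; and with 15 analysable patients the step-4 logistic regression is
under the conventional ten-events-per-variable guideline — on many
synthetic cohorts it is, rightly, not even attempted because no step-3
predictor reaches significance.
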