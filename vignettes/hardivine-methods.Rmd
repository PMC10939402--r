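---
title: "Modelling grapevine bud cold hardiness with hardivine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling grapevine bud cold hardiness with hardivine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hardivine)
```

## The modelling problem

Dormant grapevine buds track winter with their freezing tolerance, the bud
LT50 (°C, negative). Acclimation in autumn deepens it; warm spells in late
winter, once the chilling requirement is met, rapidly reverse it. The
package treats LT50 prediction as supervised tabular regression: every
(site, date, cultivar) sample is described by 117 features derived from the
hourly temperature history of its dormancy season plus the cultivar
identity, and an ensemble regressor maps these to LT50. This vignette
documents the model, its tunable parameters, and the design decisions a
maintainer would want to know about.

## From daily weather to hourly temperatures

Most long weather records hold only daily minima and maxima.
`interpolate_hourly()` expands them with an idealized diurnal curve:

* **Day** (sunrise 06:00 to sunset 18:00 local standard time): a sine
  rising from tmin at sunrise, with the period stretched by 4 h so the
  peak — exactly tmax — falls at 14:00.
* **Night**: logarithmic decay from the sunset temperature toward the next
  morning's tmin.

Fixed anchors are used rather than latitude-dependent sun times: the
features built downstream are window sums over weeks, which are
insensitive to ±1 h of day geometry, and fixed anchors keep the grid an
exact 24 h/day with no daylight-saving discontinuities. Boundary
convention: the first day reuses itself as "previous day" and the last as
"next day", which makes identical consecutive days produce identical
profiles and keeps a constant day exactly constant. Gaps in the daily
record are an error in strict mode; permissive mode linearly imputes runs
of at most 3 days and records them, because multi-source field archives
routinely drop a day or two and silent behaviour differences would
corrupt cumulative features.

## The 117-feature representation

| block | count | notes |
|---|---|---|
| one-hot cultivar indicators | 45 | roster order fixed, serialized with models |
| days in season | 1 | days since 1 September (season key) |
| daily descriptors | 3 | that day's mean / max / min, °C |
| chilling accumulation | 3 | Utah, North Carolina, chilling hours |
| growing degree hours | 4 | bases 0, 4, 7, 10 °C |
| freezing degree hours | 1 | Σ max(0, −T), cold-load magnitude |
| EWMA / REWMA temperatures | 60 | windows 2–20 d × mean/max/min × 2 directions |

All accumulators reset on 1 September, the season anchor; dates in
January–August count from the previous year's 1 September.

**EWMA convention.** For window size `n` the per-day weight ratio is
`1 − α` with `α = 2/(n + 1)` — the span convention that standard tabular
tooling defaults to — applied over a *hard* window of exactly `n` days and
renormalized to sum to one. REWMA is the same computation on the reversed
window, so the oldest day dominates; it encodes the cold-priming idea that
the *entry* temperature of a window matters, not only the recent past.
Early in the season, windows that would reach before 1 September fall back
to the available days with `α` still anchored to the requested span and
the truncated weights renormalized; `build_feature_matrix()` flags such
rows in the `partial_window` attribute. Since accumulations are all zero
at the season start, this is the only defensible zero-information
boundary.

**Chilling tables.** The Utah (Richardson) and North Carolina
(Shaltout–Unrath) per-hour weight tables are embedded as constants; both
carry negative weights at warm temperatures, so chilling can regress
during warm spells. The third model is plain chilling hours, counted in
(0, 7.2] °C — the conventional reading of the "CU" chilling-hours model.
Band edges are closed on the right (a 2.4 °C hour earns the 1.5–2.4 °C
weight).

## The ensemble regressor

`train_ensemble()` implements bagged stacking with per-level greedy
weighted ensembles:

1. Rows are assigned to `num_bag_folds` folds (default 10) by a seeded
   permutation. Each base learner is fitted on k−1 folds and predicts the
   held-out fold, so every training row gets a leak-free out-of-fold (OOF)
   prediction; at inference the k fold-fits predict as their average.
2. Level ℓ > 1 learners see the original features plus the level ℓ−1 OOF
   predictions (default `num_stack_levels = 5`).
3. Each level closes with forward selection with replacement over its
   members' OOF predictions, 50 iterations, initialized at the single best
   member; weights are selection frequencies. The initialization makes the
   dominance property structural: an ensemble can never validate worse
   than its best member.
4. `select_model()` picks the lowest stack level whose validation RMSE is
   within `tolerance` (default 0.01 °C) of the global best — levels beyond
   the first typically tie within a few hundredths of a degree, and the
   shallower model predicts faster for identical skill.

The default base-learner menu — gradient-boosted trees (xgboost), random
forest (ranger), ridge (glmnet), k-NN (caret) — is a deliberately small,
configurable zoo spanning the main inductive-bias families for tabular
data; all run single-threaded and draw their randomness from seeds derived
from the one master seed recorded in the artifact, so a fixed seed
reproduces the trained model bit for bit. Degenerate inputs are handled
explicitly: near-constant labels short-circuit to a constant model
(several learners reject zero-variance responses), non-finite features are
an error, and folds with fewer than 2 rows are rejected.

## Feature importance

`permutation_importance()` reports, per feature, the mean increase in RMSE
over shuffle sets when only that column is permuted on a row subsample
(defaults 100 sets × 1000 rows) — importance in the model's own units
(°C). A constant column is provably zero: permutation is the identity on
its values. `shapley_values()` samples feature permutations with an
interventional background-marginal value function; because each
permutation's contributions telescope from the background mean to the
instance prediction, local accuracy (base value + Σ φ = prediction) holds
exactly, not just in expectation, and sampling error affects only the
attribution *among* features. The background defaults to ≤ 100
seed-sampled training rows; tests verify agreement with exact subset
enumeration for small feature counts.

## Freezing-damage potential

Deployment converts a predicted LT50 and a daily minimum temperature into
a damage potential via a logistic in the gap `T − LT50_pred`, with
`P_h = 0.9` and `g = 2` °C by default: 10% at +2 °C, 50% at the LT50, 90%
at −2 °C. The constants are overridable; `P_h` must lie in (0.5, 1) and
`g > 0` or the curve loses its interpretation as a damage ramp.

## The synthetic benchmark

`make_benchmark()` emulates the structure of multi-region hardiness
datasets: sites with mid-winter troughs from −16 to −8 °C (sinusoidal
seasonal course anchored to days-in-season, AR(1) deviations with
coefficient 0.65 and stationary SD 3.5 °C, 9 °C diurnal range), a mixed
roster of hardy hybrid-like cultivars (max hardiness ≈ −32 °C, faster
rates) and tender vinifera-like ones (≈ −24 °C, slower), weekly
observations from early October to mid-April, and 1.0 °C Gaussian
observation noise — values chosen once as representative of continental
cool-climate viticulture and of the scatter of differential thermal
analysis. The latent dynamics are a *threshold* model: below 10 °C daily
mean, hardiness deepens proportionally to the cold; above it, it relaxes
proportionally to the warmth times a logistic chilling gate
(half-response at the chilling requirement). The generator is
deliberately **not** the feature set's inverse — it contains no EWMA — so
when the ensemble learns the benchmark to near the noise floor, that is
evidence of genuine signal extraction, not of a self-fulfilling
round-trip.

What the generator does *not* emulate: measurement-protocol differences
between labs, microclimate and soil effects, cultivar × site interactions
beyond climate, missing-data patterns, and the skewed cultivar frequencies
of real archives. Tests passing on the benchmark therefore demonstrate
pipeline correctness and learnability, not field accuracy on real data.

## Problem sizes used by the test suite

The packaged tests train on a 4-site × 6-cultivar × 3-season benchmark
(~2100 rows) with 5 bag folds and 2 stack levels — enough to exercise
bagging, stacking, dominance and selection while keeping the full suite
under two minutes; the paper-scale defaults (10 folds, 5 levels) remain
the function defaults. The end-to-end check asserts held-out RMSE within
[0.8, 1.8] × the 1.0 °C observation noise: the lower bound guards against
leakage (beating the noise floor would mean the model saw the noise), the
upper bound demands the temperature signal was actually learned.

## Known limitations

* The hourly interpolation ignores latitude, cloud cover and frontal
  passages; where real hourly records exist they should be preferred.
* The trainer is a transparent reimplementation of the bag/stack/weight
  mechanism, not a full Auto-ML system: no per-learner hyperparameter
  search, no dynamic resource allocation.
* Sampling Shapley values scale as instances × permutations × features ×
  background rows; for the full 117-feature model, explain a subsample.
* Chilling models are applied with their published constants; no local
  recalibration is attempted.
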