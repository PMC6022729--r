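---
title: "Model and methods behind mdbs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind mdbs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdbs)
```

## The process model

`mdbs` models a multiattribute choice as a race of evidence
accumulators, one per choosable alternative, fed by pairwise ordinal
comparisons of single attribute values. The decision maker's working
memory holds a pool of values per dimension: the choice set's values
plus any context values (prior trials, phantom alternatives, long-term
memory samples). One comparison step proceeds as:

1. a target cell (alternative × dimension) is selected with probability
   proportional to its summed similarity `exp(-alpha * D)` to the other
   pool values on its dimension;
2. a partner value is selected from that pool with the same similarity
   weighting;
3. the target wins one evidence unit for its alternative with the soft
   ordinal probability `plogis(beta1 * (D - beta0))` if it is strictly
   preferable under the dimension's polarity, and never otherwise;
4. accumulation stops when the maximum evidence count exceeds the mean
   count by `theta`.

Distances are fractional, `D(a, x) = |a - x| / |x|`, which makes every
prediction invariant to the units of a dimension but pathological as
values approach zero; all magnitudes are therefore required to be
strictly positive, and packaged value sets quoted with a zero member
encode it as a small positive placeholder (0.01) that every positive
value still beats.

Context values participate as similarity contributors and comparison
partners but are never evaluated and never accumulate evidence. A
missing value has zero evaluation probability, as does any cell whose
comparator pool is empty — which is what makes non-aligned (unique)
attributes inert and generates the intransitive pairwise cycle of the
packaged missing-value fixture.

Self-comparison is excluded by ownership: a target cell's comparators
are all pool entries not owned by the target's alternative. For
ordinary problems (one value per alternative per dimension) this is
identical to removing the one pool instance equal to the target; it
generalizes more predictably when values coincide across alternatives
(an equal-valued rival stays in the pool as a tie that is never beaten)
and in the collapsed commensurable space below.

## Parameters

| parameter | default | units | role |
|-----------|---------|-------|------|
| `alpha`   | 3.0     | per unit fractional distance | similarity decay of target and partner selection; 0 = similarity-blind |
| `beta0`   | 0.1     | fractional advantage | advantage at which a comparison is won with probability .5 (a "just meaningful difference" of 10%) |
| `beta1`   | 50      | inverse fractional advantage | sharpness of the soft comparison; large values approach a hard step |
| `theta`   | 0.1     | evidence units | relative stopping threshold (max minus mean) |

The whole scenario battery runs at these defaults; only the phantom
preset raises `alpha` (to 10), mirroring the observation that strong
similarity weighting is a precondition of that effect.

## Choice probabilities

With `n` alternatives and `theta <= 1 - 1/n`, the first evidence unit
already lifts its accumulator `1 - 1/n` above the mean, so the race
ends on the first favorable comparison: choice probabilities are the
normalized accumulation rates and the expected number of comparison
steps is the geometric waiting time `1 / sum(rates)` (2.5 steps at a
total rate of 0.4). For larger `theta` the conditioned walk (null steps
rescale time but not absorption) is propagated exactly over
evidence-count states until absorption, truncated at 200 total units
with a residual-mass tolerance of 1e-12; an absorbing increment always
creates a strict maximum, so the winner is unambiguous. The solver is
validated in the test suite against the two-alternative ruin formula
and against seeded Monte Carlo at three binomial standard errors.

Degenerate inputs raise errors rather than NaNs: a problem in which no
cell has a comparator cannot be evaluated, and an all-zero rate vector
(e.g. two identical alternatives) is a non-decision.

`fixed_horizon_choice()` models time pressure: an exact dynamic program
over count vectors after a fixed number of comparison steps (null steps
included), with uniform tie-breaking among count maxima; horizons above
25 fall back to seeded simulation. Note that the forced-horizon
distribution does not converge to the untimed one as the horizon grows:
the untimed rule (at default `theta`) absorbs on the first unit, while
a long horizon aggregates many units and concentrates on the rate
leader. What is preserved — and tested — is the ordering and the
strengthening of the context effects with more comparisons.

## A structural property of similarity-weighted partner selection

The probability that a specific partner is selected shares its
`exp(-alpha * D)` weighting with target selection. Writing a cell's
evaluation weight `w` and total weight `W`, the cell's rate contribution
is `(w / W) * sum(exp(-alpha * D) * win) / w`: the evaluation weight
cancels, so

> under similarity-weighted partner selection, accumulation rates are
> sums of pairwise similarity-weighted win probabilities divided by the
> total pool weight; evaluation frequency never matters independently.

Most phenomena survive this reduction — the attraction, compromise and
similarity effects, the decoy-location and alpha-sweep trends, the
intransitive cycle, perceptual focus — and the similarity effect in
fact requires it (with uniform partners the near-clone fixture loses
the effect entirely). Two mechanisms do not:

- **Phantom decoy.** The effect is supposed to run through evaluation
  frequency: the phantom's values are most similar to its dominated
  neighbor A, so A is evaluated most often. Under the cancellation
  above, a dominating phantom can only ever add win terms for A's
  rival, so the effect is impossible at any `alpha`. The phantom preset
  therefore uses the documented `partner = "uniform"` option of
  `accumulation_rates()`, under which evaluation frequency is a
  separate factor; the effect then appears and grows with `alpha`
  (near-indifference at 3, decisive at 10).
- **Less is more.** A bundled attribute that never wins lowers its
  owner's accumulation rate, but under the relative stopping rule the
  loss is shared multiplicatively through normalization and the untimed
  probabilities are unchanged. The effect expresses itself whenever
  comparisons are limited, so the preset reports the strict rate drop
  together with choice probabilities under a five-comparison horizon,
  where the leader's share strictly falls.

## Scenario construction choices

**Synthetic car market.** The big-three fixture (A = \$24,000 / 32 mpg,
B = \$16,000 / 24 mpg, compromise-maker C = \$32,000 / 40 mpg,
attraction decoy D = \$28,000 / 29 mpg, near-clone S = \$16,500 /
23 mpg, sweep endpoint E = \$32,000 / 26 mpg) is calibrated so the
binary choice is exactly indifferent at the default parameters, with
the decoys built by the same constructions used for experiment stimuli:
a dominated decoy worsens the favored alternative by 25% of the
attribute differences, a near-clone perturbs the rival by ±2% (within
the comparison threshold, so its differences are mostly unrecognized),
and a compromise-maker extends the rival-through-favored line by one
attribute difference. What the generator emulates is the *structure* of
consumer choice sets — trade-offs, dominance, clones — under exactly
known rates; what it does not emulate is measurement noise, attribute
correlations in real markets, or individual differences, so passing
tests certify the mechanics of the model, not its empirical adequacy.

**Attribute balance.** The collapsing construction for commensurable
dimensions admits several readings. Full pooling of both dimensions' values
into one comparison space makes an *unbalanced* alternative maximal in
the asymmetric rating triads, contradicting the documented prediction
that the balanced car Q wins all three. Collapsing is therefore
implemented as cross-dimension comparison: each attribute value is a
target whose partners are the other alternatives' values on the other
dimension(s) of the commensurable group. This is the literal reading of
"comparing values across dimensions", and it makes the balanced
alternative the compromise of the collapsed value set
({40, 50, **60, 60**, 70, 80}), maximal in all three triads.

**Background contrast.** The computer stimuli are synthesized to honor
the three published trade-off rates ($0.22, $2.50 and $17.50 per KB of
RAM) and the published rank shifts: the RAM-rich prior pair demotes A's
RAM rank from 1.0 to 1/3 while leaving B's ranks alone, and the cheap
prior pair does the reverse to B's price rank. The preference between
the unchanged focal pair then reverses with the prior context alone.

**Long-term-memory dilution.** Familiarity is modeled by sampling
context values from a multivariate normal centered on A's attribute
values, with standard deviation equal to the absolute A–B difference
per dimension and a between-dimension correlation of −0.2 (attributes
trade off), truncated to positive values by rejection. Each replication
draws a fresh pool, computes closed-form probabilities, and effect
sizes are averaged over seeded replications; all three effects shrink
as the sample count grows.

**Decoy-distance sweep.** With the packaged fixture the attraction
effect declines from the far endpoint and collapses (and eventually
reverses toward a similarity effect) as the decoy enters the
just-meaningful-difference band around A — at that point A's advantages
over the decoy go unrecognized while the decoy still donates price wins
to B. The rising limb near the far endpoint depends on fixture geometry
and is not asserted.

## Inference

Because choice probabilities are closed-form, the likelihood of
aggregated choice counts is multinomial; `fit_mle()` maximizes it with
multi-start bounded `L-BFGS-B` (bounds: `alpha` in [0, 10], `beta0` in
[0, 1], `beta1` in (0, 500], `theta` in (0, 5]). `theta` is fixed by
default: whenever `theta <= 1 - 1/n` the probabilities are normalized
rates and carry no information about it (and `beta1` is only weakly
identified through the softness of near-threshold comparisons).
`recovery_report()` wraps the simulate-and-refit loop; at the study's
generating values (`alpha = 3`, `beta0 = 0.1`) and 10,000 choices over
the three car triads, the mean estimates recover the truth well within
±0.5 and ±0.03 respectively.

## Problem sizes used by the test suite

The suite runs the closed-form-versus-Monte-Carlo check on 20 random
problems at 100,000 trials each, the dilution scenario at 500
replications per sample count, and parameter recovery over 20 seeded
replicates of 10,000 choices; the whole suite completes in about a
minute on one core. These sizes were chosen so that three-standard-error
bands are decisive for the assertions being made; all randomness is
seeded and reproducible.

## Known limitations

- Response times are modeled only as comparison counts; no
  millisecond-scale distributions.
- The endowment and polarization effects are outside the model's
  explanatory range, and the weaker-phantom-with-far-decoy asymmetry is
  not reproduced.
- The alternative stopping rule (maximum minus next-best) is available
  in principle through the same walk machinery but is not exposed or
  tested.
- Fitting is per-dataset maximum likelihood; no hierarchical pooling
  across participants.
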