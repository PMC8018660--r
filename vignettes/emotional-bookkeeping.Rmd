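---
title: "Emotional bookkeeping dynamics: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emotional bookkeeping dynamics: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emobook)
```

## The scientific question

Group-living primates maintain differentiated affiliative relationships: a
few strong bonds and many weak ones, with the strong ones stable over
months to years. Emotional bookkeeping is the hypothesis that such structure
can emerge without episodic memory: each individual integrates the
emotional effect of received grooming into a single partner-specific
valuation (here called LIKE) that in turn biases its own grooming-partner
choice. `emobook` simulates this loop and asks how the *functional form*
and *speed* of the valuation update determine whether differentiated,
stable relationships form at all.

## The attitude update rules

A LIKE value is a directed, dimensionless valuation in a bounded range.
Two increase shapes (applied per minute of *received* grooming) and two
decrease shapes (applied per minute *without* grooming) are crossed into
four dynamics:

* linear increase, constant speed `a` — forming and strengthening a
  relationship costs the same at every level;
* logistic increase — strangers gain value slowly, established partners
  quickly (the empirical stress/oxytocin picture);
* exponential decrease — strong relationships decay fastest in absolute
  terms;
* logistic decrease — strong and weak relationships are both sticky, the
  middle is volatile.

All constants derive from two speed parameters with exact timing
semantics, so that "speed" is comparable across shapes:

* `linc_period` (LINC): minutes of uninterrupted grooming from the minimum
  to the maximum value — 10, 30 or 60. For the linear rule
  `a = (upper − lower)/linc_period`; for the logistic rule
  `k_inc = 2 ln(99) / linc_period`, because the calibrated sigmoid spans
  logit(0.01) to logit(0.99) = 2 ln 99 in scaled time.
* `lhw` (LIKE-history weight): exponential decay halves any value every
  `lhw` minutes; logistic decay from the upper bound first crosses 0.5
  after exactly `lhw` minutes, giving `k_dec = ln(99)/lhw`.

Purely linear/exponential bookkeeping (the original dynamics) uses the
range [0, 1]; any dynamics with a logistic component uses [0.01, 0.99],
since a sigmoid only approaches its asymptotes. `lhw = 0` is special-cased:
with exponential decrease it selects a linear decay that empties the full
range in exactly 50 minutes (the half-life form is undefined at 0); with
logistic decrease it maps to `lhw = 25`, the matching very-fast setting.
Updates invert the sigmoid in closed form (logit), so composing an update
over split durations equals one update over the summed duration to rounding
error; this semigroup law is what makes the engine's lazy, timestamped
attitude storage exactly equivalent to eager per-minute decay, and it is
property-tested against a fourth-order Runge–Kutta integration of the curve
derivatives.

```{r curves}
d <- make_dynamics("alternative", "slow", 2880)
d
time_to_reach(d$lower, d$upper, "increase", d)  # the LINC contract, minutes
idle_decay(0.99, 2880, d)                       # the LHW contract
```

## The simulated world and behaviour engine

Twenty identical individuals live on a continuous 300 × 300 torus; one grid
unit is 1 m and one time step 1 min, with a 720-minute active day and a
350-day year. The environment is purely social: no foraging, no hunger.
The scheduler is event-driven — the individual with the smallest activation
clock acts next (ties broken by index) and is rescheduled one minute later,
except that grooming bouts occupy both partners for the bout length.

Each activation runs a fixed decision cascade:

1. **Arousal gate.** With probability `myAROUSAL` (baseline 0.5, bumped by
   interactions, half-life 60 min) an active behaviour is drawn; otherwise
   the individual rests. A committed approach survives a rest pause.
2. **Aggression response.** A recently attacked individual avoids its
   aggressor with probability equal to its anxiety.
3. **Committed approach.** An individual en route to a chosen partner keeps
   approaching (1 unit/min) until within arm's reach (1 unit), abandoning
   the chase with probability 0.03/min.
4. **Agonism.** With probability 0.02 an active individual attacks a random
   lower-ranked visible individual: the victim's anxiety rises by 0.2
   (half-life 120 min), it signals submission and is primed to avoid.
   Agonism never touches LIKE values — an invariant the engine asserts by
   counting attitude writes.
5. **Satiation gate.** With probability `mySATISFACTION` the individual has
   no grooming motivation; if crowded (nearest neighbour within 5 units) it
   moves away, if adrift (further than 20 units from the group centroid) it
   drifts back, otherwise it rests.
6. **Affiliative encounter.** A candidate is drawn uniformly at random from
   the visible individuals (preferring those within ordinary perception
   range) and the affiliative act toward it proceeds with probability
   `(1 − LPS) + LPS · LIKE`. The realized partner distribution is therefore
   exactly the normalized `partner_weights()` mixture, while the *overall*
   grooming rate itself grows as valuations build — groups with strong
   bonds groom more, cold-start groups little. Fear damps the act toward
   higher-ranked partners (probability `FEAR · (0.2 + 0.8 · anxiety)` of
   avoiding instead), the partner is groomed if in reach and approached
   otherwise.

Grooming bouts continue minute-by-minute with probability 0.9 and are
terminated by the receiver at 15 minutes at the latest; the receiver's LIKE
toward the groomer is advanced by the calibrated increase over the bout,
its satisfaction rises, and it is primed — with probability equal to that
updated LIKE — to return one bout, so session-level reciprocity is itself
bookkeeping-driven and return bouts do not chain. A satiated receiver
declines fresh bouts (an affiliative signal is exchanged instead).

Perception combines a 120° forward cone of radius 50 units with scheduled
scan events (probability 0.2 per activation) that survey the whole group;
scans are what lets a spatially spread group still find every potential
partner, and the centroid-drift rule keeps the 20 individuals one coherent
troupe rather than scattered pairs.

### Parameters that matter, and why these defaults

| parameter | default | role |
|---|---|---|
| `linc`, `lhw`, `lps`, dynamics | study grid | the scientific factors |
| `arousal_baseline` | 0.5 | share of active decisions |
| `groom_continue_p` | 0.9/min, capped 15 min | bout length (mean ≈ 7 min) |
| `satisfaction_gain` | 0.002 per received min | grooming tempo (see below) |
| `satisfaction_halflife` | 180 min | satiation recovery |
| `anxiety_gain` / halflife | 0.2 / 120 min | response to aggression |
| `agonism_p` | 0.02 | agonism rate, spacing only |
| `perception_radius`, `view_angle`, `pscan` | 50, 120°, 0.2 | local vs scan perception |
| `grooming_reach`, `step_length` | 1, 1 | arm's reach; 1 m/min movement |
| `leave_radius`, `cohesion_radius` | 5, 20 | satiated spacing vs troupe coherence |

Two calibration choices deserve explanation. The **bout cap** (15 min)
exists because an uncapped geometric bout has a heavy tail: a single rare
40-minute bout would carry a stranger dyad across the entire slow logistic
increase in one step, erasing precisely the slow-formation property the
alternative dynamics encodes; receivers ending long bouts restore it. The
**satisfaction gain** (0.002/min) sets the group's grooming tempo through
the satiation gate: it was calibrated once so that, across the full LHW
range, bond formation and decay run to completion within the protocol's
stabilization and recording durations — very fast decay then empties every
dyad, very slow decay saturates virtually every dyad, and the intermediate
settings differentiate. Activity budgets in bond-rich regimes sit at the
high end of what is reported for wild macaques; the regime *structure*, not
the absolute grooming budget, is the quantity this model is used for.

## Recording and analysis

After stabilization (`max(6000, 30·lhw)` minutes — slower decay needs a
longer burn-in) a run records for two model years: five LIKE snapshots half
a year apart, daily LIKE samples, directed grooming-minute totals and
pairwise proximity (fraction of 10-minute samples within 2 units). The
analysis stage averages the samples over the second year, classifies the
380 directed dyads (high ≥ 0.75, low ≤ 0.25, boundary values inclusive as
stated), and scores stability as the mean over the four consecutive-pair
squared Pearson correlations across all directed dyads. Zero-variance
snapshots make a transition undefined; such transitions are excluded from
the mean with a warning rather than coerced. All statistics are computed on
directed dyads — grooming and LIKE are genuinely asymmetric and are never
symmetrized.

For testing the analysis stage without simulation,
`generate_fixture_snapshots()` plants a known structure (a fixed number of
high dyads per individual) and evolves it as a stationary AR(1) process on
the dyad deviations, so persistence ρ maps to an expected transition R² of
ρ² and ρ = 0 sits at the null level 1/(n·(n−1) − 1).

## Scaled-down runs

`run_config(..., scale = s)` divides the stabilization and recording
durations and all sampling spacings by `1/s` while leaving the attitude
dynamics untouched — the dynamics are the object of study, not simulation
conveniences. Scaled runs are therefore *not* miniature replicas: regimes
whose formation time is set by slow decay need proportionally more of the
full protocol, and the package's own regime tests use `scale = 0.1` where
the qualitative pattern is already established. Test and example problem
sizes (scale 0.005–0.1 for unit tests, full length for the stability
contrast) were chosen so the complete suite runs in about a minute while
still exercising genuine 2-year runs.

## What the synthetic tests do and do not show

The engine's behavioural sub-rules (satiation, reciprocity, cohesion, fear
damping) are this package's own re-specification: they are constrained by
the published qualitative statements, not by an upstream rule-by-rule
description, so emergent quantities that depend on their details — absolute
grooming budgets, proximity levels, the exact stability score of the
churn-prone original dynamics — should be read as model-class results
rather than replications. The timing calibration of the four dynamics, by
contrast, is exact and closed-form, and the analysis suite is deterministic
given its inputs. Passing tests demonstrate internal consistency and
reproduction of the published regime structure; they do not validate the
behaviour engine against empirical macaque data.

## Known limitations

* The hierarchy is fixed; no rank dynamics, coalitions, kinship or
  sex/age classes.
* FEAR is a static function of the dominance gap; it is never learned.
* Grooming is the only LIKE-relevant behaviour; affiliative signals are
  bookkeeping-neutral.
* One RNG stream per run: runs are bit-reproducible from (config, seed),
  but per-agent streams would be needed for variance-reduction experiments.
* The LHW = 0 fast-decay rule is implemented as linear emptying in 50
  minutes; only its 50-minute contract, not its historical functional form,
  is documented.
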