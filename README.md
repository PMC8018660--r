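# emobook

An event-driven, agent-based simulator of **emotional bookkeeping** in a
primate-like social group, together with the analysis suite needed to study
how the *dynamics* and *speed* of relationship-quality updating shape the
differentiation and temporal stability of affiliative relationships.

## The model in brief

Twenty identical individuals move on a continuous 300 × 300 torus (1 grid
unit = 1 m, 1 time step = 1 min, a day = 720 active minutes, a year = 350
days). Each individual holds a directed, partner-specific valuation — its
**LIKE** attitude — that rises with grooming *received* from that partner
and erodes during periods without grooming. A fixed **FEAR** attitude
encodes the dominance gap (dominance ladder 1.00 down to 0.05). Partner
choice is biased by LIKE through the selectivity parameter **LPS**: the
probability of affiliative behaviour toward an encountered partner is
`(1 − LPS) + LPS · LIKE`.

Four bookkeeping dynamics are supported, the cross of two increase and two
decrease shapes, each with exact timing semantics:

| dynamics      | increase | decrease    |
|---------------|----------|-------------|
| `original`    | linear `LIKE(x) = a·x` | exponential `LIKE(x) = 0.5^(x/LHW)` |
| `alternative` | logistic `1/(1+e^(−k·x))` | logistic `1 − 1/(1+e^(−k·x))` |
| `dynamics3`   | linear   | logistic    |
| `dynamics4`   | logistic | exponential |

**LINC** fixes the increase speed: uninterrupted grooming drives LIKE from
its minimum to its maximum in exactly 10 (`fast`), 30 (`intermediate`) or 60
(`slow`) minutes. **LHW** fixes the decrease speed: exponential decay halves
LIKE every `LHW` minutes, and logistic decay starting at the upper bound
first reaches 0.5 after exactly `LHW` minutes (`LHW = 0` selects a special
rule that empties the full range within 50 minutes). Logistic curves live on
[0.01, 0.99]; steepness constants follow from the timing contracts
(`k_inc = 2·ln 99 / LINC`, `k_dec = ln 99 / LHW`).

Runs follow the study protocol: a stabilization period of
`max(6000, 30·LHW)` minutes, then a 2-year (504 000 min) recording period
with five LIKE snapshots half a year apart, daily LIKE samples, directed
grooming-minute totals and proximity rates. The analysis suite averages the
second recording year, classifies the 380 directed dyads into high
(LIKE ≥ 0.75), intermediate and low (LIKE ≤ 0.25) quality, and scores
temporal stability as the mean squared Pearson correlation (R²) between
consecutive snapshots.

## Worked example

A duration-scaled run of the alternative dynamics with slow increase,
intermediate decrease (`LHW = 2880`) and very high selectivity:

```r
library(emobook)
cfg <- run_config("alternative", "slow", 2880, lps = 0.99, seed = 1, scale = 0.05)
run <- run_simulation(cfg)
res <- analyze_run(run)
res$categories
#> <emo_categories> 380 dyads: 48 high (mean 0.977), 4 intermediate (mean 0.423), 328 low (mean 0.0122)
res$stability
#> <emo_stability> transition R2: 0.771, 0.957, 0.916, 0.912 | mean 0.889
```

Each individual ends up with roughly two strong partners (48 of 380 directed
dyads high, valued near the 0.99 ceiling), almost no intermediate-quality
relationships, and a dyadic structure that barely changes between snapshots
(mean transition R² ≈ 0.89): slowly formed bonds that are well retained.
With the original dynamics at the same settings the network keeps churning
and the stability score collapses; with very fast decay (`LHW ≤ 180`) all
dyads end low, and with very slow decay (`LHW ≥ 5400`) virtually all end
high.

The same functionality is available from a shell:

```sh
Rscript inst/cli/emobook.R run --dynamics alternative --linc slow \
    --lhw 2880 --lps 0.99 --seed 1 --scale 0.05 --out outdir
Rscript inst/cli/emobook.R curves --out curves.csv   # LIKE(t) for all dynamics
Rscript inst/cli/emobook.R sweep --out sweepdir --scale 0.02
Rscript inst/cli/emobook.R analyze --like outdir/like_second_year.csv
Rscript inst/cli/emobook.R fixtures --out fixdir --n 20 --nhigh 2 --rho 0.9
```

`sweep` executes the full factorial design (2 dynamics × 3 LINC × 6 LHW ×
4 LPS = 144 cells, 2 replicates each, plus the dynamics-3/4 subset) with
per-run CSV/JSON products and a resumable manifest.

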