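# pggscore

Tools for studying when reputation-based matching sustains cooperation in a
public goods game played in groups.

## The problem

Many social dilemmas — public goods provision, common-pool resource
management — are group interactions in which contributing is socially
beneficial but individually costly. Reputation can rescue cooperation if it
lets cooperators find each other: players who are known to contribute get
matched with other contributors and out-earn defectors, who are left playing
with their own kind. But real groups are often opaque: observers see how a
*group* performed, not what each member did, so a defector can hide behind
the efforts of their group-mates. This package implements and analyzes a
model of exactly this tension.

A population of `n` players is partitioned each period into `k` groups of
size `s = n/k` by the ranking of their binary reputation scores (random
tie-breaking). Every group plays a linear public goods game: player `i`
earns

```
phi_i = (1 - c_i) + (r/s) * sum_{j in group(i)} c_j,     c_i in {0, 1}
```

with rate of return `r in [1, s]`. Scores are then refreshed by one of three
rules — **image scoring** (score 1 iff your own contribution beat the
population average), **group scoring** (all members of a group share its
standing: score 1 iff the group contributed visibly at all), or a per-player
**hybrid** that applies image scoring with probability `p` and group scoring
otherwise. Strategies evolve by pairwise Fermi imitation: a random player
`j` adopts a random player `i`'s strategy with probability
`1 / (1 + exp((phi_j - phi_i)/K))`, `K = 0.1`.

The package provides the agent-based Monte Carlo dynamics (a compiled
engine, bit-reproducible from a seed, with a pure-R mirror used to verify
it), ensemble experiments and parameter sweeps, and a four-class
(action × score) mean-field replicator analysis with closed-form-checked
interior rest points and perturbation stability probes.

## Worked example

Image scoring at strong synergy: cooperators always take over.

```r
library(pggscore)

params <- pgg_params(n = 150, s = 5, r = 4, p = 1)
params
#> Public goods game with score-ranked matching
#>   n = 150 players in k = 30 groups of size s = 5
#>   rate of return r = 4 (marginal per-capita 0.8)
#>   image-scoring probability p = 1, Fermi noise K = 0.1

sim <- run_pgg(params, rule = "image", init_coop_fraction = 0.5,
               mc_steps = 2000, realizations = 20, seed = 1)
summary(sim)
#> image scoring (n = 150, s = 5, r = 4, p = 1):
#>   stationary cooperator fraction 1.0000 +/- 0.0000 over 20 realizations
#>   fixed at cooperation: 20, fixed at defection: 0 (median absorption step 21)
```

All 20 independent runs, each started from a half-cooperative population,
fix at full cooperation (median fixation after 21 Monte Carlo steps). The
ensemble defector fraction decays with a fitted exponential rate:

```r
fit <- defector_decay_fit(sim)
sprintf("decay rate %.3f per MC step (R^2 = %.2f)", fit$rate, fit$r_squared)
#> [1] "decay rate -0.055 per MC step (R^2 = 0.78)"
```

(At this small population the fit falls back to the noisy absorption tail;
at `n >= 600` the selection-driven regime gives R^2 > 0.99 — see the
vignette.) Group scoring at the same parameters sends cooperation to
extinction instead (`experiment_group()`), and the mean-field analysis
locates the interior rest point that image scoring stabilizes:

```r
stationary_pD0_image(pgg_params(n = 1500, s = 5, r = 4))
#> [1] 0.0008354219   # = 1/1197: cooperation level 0.99916 > (s-1)/s
```

A thin command-line front end ships in `inst/cli/pggscore`
(`simulate`, `analyze`, `sweep`, `fixtures` subcommands; CSV/JSON output
with a full config echo so any run can be reproduced bit-exactly).

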