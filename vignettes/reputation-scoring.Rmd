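---
title: "Reputation scoring and the evolution of cooperation in group interactions"
author: "pggscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reputation scoring and the evolution of cooperation in group interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pggscore)
```

## The model

A population of $n$ players repeatedly plays a linear public goods game in
$k$ groups of fixed size $s = n/k$. Each period, player $i$ either
contributes their unit budget ($c_i = 1$, "cooperate") or keeps it
($c_i = 0$, "defect"); a group's pot is multiplied by the rate of return $r$
and shared equally, so

$$\phi_i \;=\; (1 - c_i) \;+\; \frac{r}{s}\sum_{j \in \mathrm{group}(i)} c_j .$$

With $r \in [1, s]$ contributing is socially beneficial but individually
costly: within any group a defector earns exactly one unit more than a
cooperator, while the marginal per-capita return $r/s < 1$ makes defection
the dominant one-shot action. Two exact identities follow directly from the
payoff form and are asserted in the tests: total payoffs equal
$n + (r-1)\sum_i c_i$, and the within-group defector-cooperator gap is
exactly 1.

What makes the game interesting is reputation. Every player carries a binary
score, and each period the population is re-partitioned by *score ranking*:
players are sorted by score (uniformly random tie-breaking) and cut into $k$
consecutive groups, so high-reputation players play together and at most one
boundary group mixes the two scores.

Three scoring rules are implemented:

* **Image scoring** (`p = 1`): a player's next score reflects their *own*
  last contribution — 1 if it exceeded the population-average contribution,
  0 if below, previous score retained on exact equality (which, with binary
  contributions, can only happen in a monomorphic population).
* **Group scoring** (`p = 0`): individual actions are invisible; all members
  of a group are scored by how the *group* performed. A group's total
  contribution is compared against the same population-average contribution:
  since group totals are integers and the average contribution lies in
  $[0,1]$, any group that contributed at all is marked up and only visibly
  idle groups are marked down. This is the deliberate informational weakness
  of group-level reputation: a free-rider in a contributing group inherits
  its good standing.
* **Hybrid scoring** (`0 < p < 1`): each player independently is scored by
  the image rule with probability $p$ and by the group rule otherwise. The
  degenerate mixtures are bit-identical to the pure rules.

On the choice of the group-scoring threshold: comparing a group's total
against the *average group total* is a superficially natural alternative,
but it makes group reputation a surprisingly sharp instrument — a single
free-rider drags an otherwise cooperative group of $s-1$ contributors below
the average, so free-riders are exposed and demoted after one period, and
with score-ranked matching this produces group-level selection that *favors*
cooperation at high $r$. Under that reading, high-score defectors cannot
persist, which contradicts the defining property of group-level reputation
(that free-riders share their group's standing) and inverts the rule's
intended phenomenology. The average-contribution threshold used here keeps
the two pure rules on the same scale (both compare a contribution statistic
against $\bar c$) and makes group scoring exactly the coarse signal it is
meant to be.

## Evolutionary dynamics

Strategies evolve by pairwise Fermi imitation. An elementary event draws an
ordered pair $(i, j)$ uniformly from the whole population; both compute
their payoffs in their current groups, and $j$ adopts $i$'s strategy with
probability

$$W = \frac{1}{1 + \exp\!\big[(\phi_j - \phi_i)/K\big]},$$

where $K = 0.1$ by default — imitation is then nearly deterministic for
payoff gaps of order one and maximally undecided ($W = 1/2$) at equality.
Time is organised in *periods*: `events_per_period` imitation events are
followed by a full rescoring of every player and a re-matching of all groups
by score rank. One *Monte Carlo step* spans $n$ events, so every player
revises once per step on average. The default `events_per_period = n` makes
one period coincide with one Monte Carlo step; the knob exists because the
ratio of reputation-updating to strategy-updating is a genuine modeling
degree of freedom (see the limitations section), and `events_per_period = 1`
gives the opposite extreme at a much higher computational cost (every event
then triggers an $O(n \log n)$ rematch).

Strategy adoption copies the strategy only; scores evolve solely through the
scoring rules. Both monomorphic populations are absorbing — there is no
mutation — so runs that fix are finished early and padded, which cannot
change any recorded value.

The simulator doubles as the package's synthetic-data generator: ensembles
(`run_pgg()`) are the study populations, and the experiment wrappers pin the
conditions — `experiment_image()` and `experiment_group()` run the
image/group ensembles at $s = 5$, $r = 4$ with a desk-scale default of
$n = 150$ and 20 realizations (the full-scale population of $n = 1500$ and
200 realizations remains a parameter choice away), and the hybrid sweeps use
$p = 0.01$, $r = 1.1$, $10^4$ Monte Carlo steps and 10 realizations per
cell. Initial populations place exactly `round(n * init_coop_fraction)`
cooperators uniformly at random and give everyone score 1, so the first
matching is uniformly random and leaks no strategy information; the
alternative initialisations (all-zero, Bernoulli) are exposed but change
nothing qualitatively, since scores are refreshed after the first period
anyway.

Everything is bit-reproducible: the compiled engine and a pure-R mirror
consume the RNG stream identically (three uniforms per event, $n$ for a
hybrid mask, $n$ for tie-breaking — the adoption uniform is drawn even when
the pair already agrees, precisely to keep the two engines aligned), and the
test suite asserts their bit-equality.

## Mean-field stability analysis

For the analytic component, actions are hardwired and only scores move:
the population is summarised by the masses of the four action-score classes
$(p_{C1}, p_{D1}, p_{C0}, p_{D0})$. Class payoffs under score-ranked
matching are computed by `expected_class_payoffs()`: score-1 mass fills the
top groups, score-0 mass the bottom, with one mixed boundary group. For a
class holding at least one whole head, the focal player's expected
group-mates follow the hypergeometric (without-replacement) expectation with
the focal excluded from the mate pool — this is the *exact* expectation of
the stochastic matcher, and the suite verifies it against brute-force
sampling on $n = 60$ with a deliberately misaligned boundary. For a class
holding less than one head (slivers that arise along the replicator flow),
the focal is measure-zero inside its stratum and no self-exclusion applies;
this continuum limit reproduces the reference closed forms
$\pi_{C1} = r$, $\pi_{C0} = (s - n\,p_{D0})\,r/s$ and
$\pi_{D0} = 1 + (s - n\,p_{D0})\,r/s$ at arbitrary sub-unit masses.

Class masses grow in proportion to their payoff excess over the population
average, aggregated per action:

$$\frac{\partial p_a}{\partial t} \;=\; \sum_{\sigma \in \{0,1\}}
  p_{a\sigma}\,\big(\pi_{a\sigma} - \bar\pi\big), \qquad a \in \{C, D\},$$

and the two rates sum to zero. Three executable results follow.

**Universal defection is stable under every rule.** A lone cooperator earns
$r/s < 1$ against an average just above 1, so its growth rate is negative
and the flow from a near-all-defect state settles at $p_C = 0$; the
acceptance script reports this limit.

**Image scoring admits a high-cooperation rest point.** Along the family
$p_{C1} = (n-s)/n$, $p_{D1} = 0$, $p_{C0} + p_{D0} = s/n$ (all but one group
purely high-score cooperators, one bottom group mixing low-score cooperators
and defectors), the cooperator growth rate vanishes at a unique
$p_{D0}^\ast \in (0, s/n)$, located by bisection to machine precision:

```{r root}
pr <- pgg_params(n = 1500, s = 5, r = 4)
stationary_pD0_image(pr)          # equals 1/1197 here
```

Eliminating the quadratic terms by hand from the three closed-form payoffs
gives the independent oracle $p_{D0}^\ast = s / (s + r(n-s))$, which the
tests freeze against the bisection root; the cooperation level
$1 - p_{D0}^\ast$ exceeds $(s-1)/s$ whenever $r > 1$.

**Perturbation probes separate the two rules.** `stability_probe()` injects
a small mass of score-1 defectors and integrates the coupled dynamics:
replicator substeps (explicit Euler, masses clipped at zero and
renormalised, drift beyond $10^{-6}$ an error) alternating with the rule's
one-period score-transition map. Under image scoring any mixed state sends
every cooperator to score 1 and every defector to 0, so the injected
free-riders are exposed after one period and their mass then shrinks — the
probe reports *stable*, with cooperation still above $(s-1)/s$. Under group
scoring the free-riders sit in cooperator-rich strata whose expected totals
exceed the average contribution, keep their scores, keep outgrowing
everyone, and the probe reports *unstable* with cooperation collapsing.

```{r probe}
root <- stationary_pD0_image(pr)
ref <- class_state(pC1 = 1495/1500, pC0 = 5/1500 - root, pD0 = root)
stability_probe(ref, pr, "image", epsilon = 1e-4)$verdict
stability_probe(ref, pr, "group", epsilon = 1e-4)$verdict
```

Note that the rest point is a rest point of the *replicator flow at fixed
scores*, not of the coupled flow: the image-scoring transition immediately
promotes the $C0$ mass to $C1$, after which the flow drifts to full
cooperation. The interleaving of growth and score transitions is a modeling
choice — the transition maps are defined at the expectation level per
stratum — and the probe's verdicts, not mass constancy, are the meaningful
output.

## Numerical and statistical choices

* **Root finding**: bisection on $(0, s/n)$, 200 iterations (machine
  precision); the growth rate at the returned root is below $10^{-10}$.
* **Integration**: explicit Euler with `dt = 0.1` inside each unit of time,
  one score transition per unit; masses renormalised every substep.
* **Tie rules**: equality with the relevant average always retains the
  previous score; matching ties are broken by fresh uniform draws each
  period.
* **Stationary estimate**: mean cooperator fraction over the trailing 10%
  of the run (exactly the absorbed value for absorbed runs).
* **Defector decay rate** (`defector_decay_fit()`): log-linear fit of the
  ensemble defector fraction from the end of the transient (first period at
  or below $1/e$ of the start) down to the last period with at least one
  group's worth of defectors per population ($s/n$). Below that floor the
  survivors necessarily sit in the mixed boundary group, where they
  free-ride at payoffs above $r$ and die by imitation noise rather than
  selection, so that regime is excluded; if the selection regime is shorter
  than four periods (small $n$), the fit falls back to the whole positive
  post-transient range and labels itself accordingly.
* **Critical thresholds** (`experiment_hybrid_thresholds()`): the critical
  $r$ or $p$ is the first grid value at which the ensemble-mean stationary
  cooperator fraction exceeds 0.5 — an operational estimator chosen here,
  not a quantity the model defines.
* **Horizons**: image-scoring ensembles at $r = 4$ fix within hundreds of
  steps; the group-scoring ensemble at $s = 5$, $r = 4$ first settles into a
  defection-dominated quasi-stationary state (cooperator fraction about 0.2)
  and is absorbed at 0 by fluctuation on a $10^4$–$10^5$-step timescale at
  $n = 150$, so `experiment_group()` defaults to $3\times10^5$ steps —
  a convergence requirement for reporting stationary outcomes, cheap in
  practice because absorbed realizations exit early.

## What the simulations do and do not show

The desk-scale ensembles reproduce the model's qualitative separation of
informational regimes: under image scoring cooperators rise to fixation
(strict fixation at $r = 4$ for all tested $n$; at weak synergy
$r = 1.5$ a high-cooperation stationary state of 0.78–0.96, increasing with
$n$, in which a small minority of boundary-group free-riders persists), and
under group scoring cooperators die out — quickly at $r = 1.5$ for all
tested $s$ and $n$, and through the slow fluctuation-driven route described
above in the hardest case $s = 5$, $r = 4$, where the marginal per-capita
return approaches 1.

Two full-scale claims are *not* reproduced at desk scale, and the package
reports them as such rather than glossing over them:

* The ensemble defector decay under image scoring is cleanly exponential
  ($R^2 > 0.99$) for $n \ge 600$, where the selection-driven regime spans
  enough periods to measure; at $n = 150$ the $s/n$ floor is reached within
  three periods, the measurable range is dominated by the absorption
  staircase of a 20-realization ensemble, and the fallback fit yields
  $R^2 \approx 0.8$.
* Under hybrid scoring at a minute information rate ($p = 0.01$, $r = 1.1$)
  every tested ensemble ($n$ from 50 to 3000) goes extinct under the
  default cadence: selection moves each player once per period on average
  while image exposures arrive at rate $p$ per player per period, so
  segregation (timescale $1/p$ periods) loses the race regardless of $n$.
  The population-size dependence survives only in its degenerate form
  (survival frequency non-decreasing in $k$, extinction below the $2/n$
  information bound). A cadence in which reputations update much faster
  than strategies (`events_per_period = 1`) makes the size effect plausible
  on dimensional grounds — $np$ image exposures per strategy revision — but
  at desk scale ($n \le 1000$) it still shows extinction at these
  parameters, and its $O(n^2 \log n)$ per-step cost puts larger populations
  out of reach here. Mapping the survival phase at full scale is the main
  open computational task.

A further honest caveat: under the alternative group-total-vs-average-total
threshold discussed above, score-ranked matching turns group reputation into
an effective group-selection mechanism and *stabilises* cooperation at high
$r$ — the opposite phenomenology. The sensitivity of this model class to the
exact reputation threshold is itself a finding worth keeping in mind when
interpreting any single variant.

## Limitations

Beyond the scale limitations above: contributions are binary by
construction, scores are binary, the matching mechanism is strict score
ranking (how a score hierarchy is turned into a group hierarchy is treated
as given, not designed), imitation is the Fermi rule only, and the
mean-field analysis treats strata at the expectation level — group-to-group
composition fluctuations, which drive the agent-based results at small $n$,
are outside it.
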