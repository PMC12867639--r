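---
title: "Asymmetric public goods games: models, dynamics, and fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Asymmetric public goods games: models, dynamics, and fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asympgg)
```

## The game

A repeated public goods game among $n$ players. Each round, player $i$
receives an integer endowment $e_i$ and chooses a contribution
$c_i \in \{0, 1, \dots, e_i\}$. Contributions are scaled by individual
productivity factors $p_i > 0$; the collective contribution is
$C = \sum_i p_i c_i$. Payoffs are

$$\pi_i = (e_i - c_i) + r_i,$$

where the reward $r_i$ depends on the reward function:

* **linear**: $r_i = C/n$ — the group shares the public good equally. The
  game is a social dilemma exactly when $1 < p_i < n$ for every player:
  each contributed unit grows the group's payoff by $p_i - 1 > 0$ but costs
  its contributor $1 - p_i/n > 0$.
* **threshold**: $r_i = r \cdot \mathbb{1}[C \ge \theta]$ — a fixed reward
  paid to everyone iff the collective contribution reaches a tipping point.
  This is a coordination game with many one-shot equilibria.

`pgg_game()` constructs games; `payoffs()` and `collective_contribution()`
evaluate profiles. Productivities are stored as exact rationals (e.g. $1.6$
as $8/5$), so the threshold comparison $C \ge \theta$ is an exact integer
comparison, never a floating-point tolerance. Contributions are integers
only, matching the integer action set of the laboratory implementation.

## Treatments

The built-in registry (`inst/extdata/treatments.yaml`) covers five
two-player scenarios crossed with both reward functions: full equality
(FE), endowment inequality (EI), productivity inequality (PI), aligned
inequality (AI — the more productive player holds the larger endowment),
and misaligned inequality (MI). Endowments are normalized to
$e_1 + e_2 = 48$ (equal split $24/24$, unequal split $36/12$), mean
productivity is $1.6$, thresholds default to
$\theta = \tfrac12 \sum_i p_i e_i$ — so contributing half of every
endowment is guaranteed to reach the threshold — with reward $r = 20$.
Four-player treatments (FE/AI/MI) duplicate each two-player role.

The *individual* productivity values of the asymmetric scenarios are not
fixed by those normalizations alone. The registry ships the pair
$(p_{\text{hi}}, p_{\text{lo}}) = (1.9, 1.3)$, derived once from the
constraints the design imposes: mean $1.6$; both factors inside the
two-player social-dilemma band $(1, 2)$; and the repeated-game asymmetry
that full cooperation is individually rational under aligned but not under
misaligned inequality, which with $e = (36, 12)$ pins
$p_{\text{lo}} < 1.4 \le p_{\text{hi}}$. Entries carry a `source:` field
(`printed` vs `reconstructed`); any value left as the placeholder `"FIG1"`
makes `make_treatment()` refuse with an error naming the missing parameter
rather than guess.

## Equilibrium analysis

`enumerate_pure_nash()` does exhaustive best-response checking over the
full profile grid (guarded at $10^7$ profiles). `minimax_payoffs()`
computes each player's pure-action security level
$\min_{c_{-i}} \max_{c_i} \pi_i$ by brute force. For the repeated game with
patient players, `spe_region()` applies the Folk theorem: the subgame
perfect equilibrium payoffs are the **feasible** payoffs (convex hull of
the stage payoff vectors, implementing long-run averages over contribution
sequences) that are **individually rational** ($\pi_i \ge$ minimax).

Three deliberate choices:

* Individual rationality uses the *weak* inequality. The Folk theorem is
  usually stated for strictly IR payoffs, but boundary points reachable by
  repeating stage Nash equilibria — full defection in the linear game pays
  exactly the minimax $e_i$ — must be included to reproduce the equilibrium
  pattern of the treatments.
* Minimax is over pure stage actions only; mixed minimax is out of scope.
  In all shipped treatments the two coincide for the quantities we report.
* For $n = 2$ the region is an explicit counterclockwise polygon (convex
  hull via `grDevices::chull`, then Sutherland–Hodgman clipping by the two
  IR half-planes). For $n = 4$ vertex enumeration in four dimensions is
  not needed: the region is queried by membership, with a Frank–Wolfe
  projection onto the hull of the (up to $\sim\!2 \times 10^5$) stage
  payoff points deciding feasibility. Note that the full-cooperation payoff
  is itself a stage payoff, so `full_cooperation_is_spe()` reduces to the
  exact IR comparison and involves no geometry at all.

With the registry parameters, full cooperation is sustainable as a subgame
perfect equilibrium in the linear FE/EI/PI/AI treatments but *not* under
misaligned inequality, where the high-endowment, low-productivity player
would earn less than their endowment:

```{r}
vapply(c("FE", "EI", "PI", "AI", "MI"), function(sc)
  full_cooperation_is_spe(make_treatment("linear", sc)), logical(1))
```

## Reactive strategies and the learning model

Players use deterministic reactive strategies: an initial contribution plus
a full response table to the coplayer's previous contribution
(`reactive_strategy()`, `constant_strategy()`, `random_strategy()`). Two
strategies determine play for any horizon (`rollout()`); all traces are
eventually periodic with period at most $(e_1+1)(e_2+1)$.

Round outcomes are evaluated with an inequity-averse utility,

$$u_i = \pi_i \;-\; \beta\,\frac{|c_1 - c_2|}{\max\{e_1, e_2\}}
      \;-\; \gamma\,\left|\frac{c_1}{e_1} - \frac{c_2}{e_2}\right|,$$

with $\beta \ge 0$ penalizing unequal absolute and $\gamma \ge 0$ unequal
relative contributions; $\beta = \gamma = 0$ recovers pure payoff
maximization. The third term is implemented with an absolute value: an
"aversion" penalty must be symmetric in sign, and a signed term would
reward one-sided inequity.

`run_introspection()` implements introspection dynamics: each time step the
current strategy pair plays a block of `rounds_per_step = 20` rounds (each
block restarts from round 1, as a fresh experimental session would); one
player, chosen uniformly, draws a uniformly random alternative strategy;
the counterfactual block is re-rolled deterministically against the
coplayer's unchanged strategy (exact, no approximation); and the player
switches with the logistic (Fermi) probability
$\varphi(\tilde u, u) = (1 + e^{-s(\tilde u - u)})^{-1}$. Selection
strength $s = 0$ is neutral drift; large $s$ approaches best response.
"Random alternative" is uniform over the full product strategy space —
equivalently i.i.d. uniform entries — the minimal-assumption reading;
`strategy_mode = "constant"` restricts the draw to memoryless strategies,
the no-reciprocity ablation. $\varphi$ is evaluated piecewise
(`stats::plogis` in R, a guarded exponential in the C++ core), so it never
overflows.

**Block-utility aggregation.** The utilities compared are the realized
20-round totals (`aggregation = "sum"`, the literal reading of comparing
realized block utilities); `"mean"` is available because the choice only
rescales effective selection strength by the block length, and neither
convention is canonical. The default matters at large $s$ — see the
limitations below.

The simulation core is C++ (Rcpp) and uses R's RNG, so every run is
reproducible from `set.seed()`/the `seed` field of
`introspection_config()`. $10^6$ steps take well under a second, so the
published scale of $10^7$ steps per parameter point is within reach;
package tests and examples use $10^5$–$10^6$ steps, which we found ample
for stable surplus estimates on these games.

## The exact chain as an oracle

Introspection dynamics is a Markov chain on strategy profiles with a unique
invariant distribution for finite $s$. On tiny games (e.g. $e = (1,1)$: 8
strategies per player, 64 profiles) `stationary_distribution_exact()`
builds the full transition matrix through the independent R-level
`rollout()`/`block_utility()` path and solves for the stationary
distribution — an oracle for the C++ simulator.

The stationary solve uses the Grassmann–Taksar–Heyman state-reduction
algorithm rather than a linear solve. GTH performs no subtractions and
achieves componentwise relative accuracy regardless of conditioning; this
is essential because at strong selection the transition matrix contains
entries of order $e^{-s\,\Delta u}$ and the naive solve of the stationary
equations is singular to working precision *while still producing small
residuals* — a silently wrong answer. The GTH implementation was verified
against a 120-digit-precision solve of the same chain (total variation
$\sim 10^{-15}$).

**Metastability at strong selection.** When $s$ times the block-utility
gaps is large (e.g. penalty weight 5 on 20-round sums gives gaps
$\sim 100$), escape probabilities from locally optimal strategy profiles
are of order $e^{-100}$. The invariant distribution still exists, but no
simulated trajectory of $10^6$ steps can traverse between metastable
modes: different seeds then produce near-disjoint occupancy measures, and
occupancy-versus-stationary comparisons fail *by the nature of the
dynamics*, not by implementation error. The simulator matches the GTH
oracle (total variation $< 0.01$ at $10^6$ steps) on every tested
parameter combination whose chain actually mixes, under both aggregation
conventions. At $s = 10$ with penalty weights of 5 on sum-aggregated
blocks, switch probabilities underflow double precision altogether and
`stationary_distribution_exact()` refuses with an explicit error.

## Outcome statistics

`group_summary()` and the individual functions compute the standard
outcome variables from a deterministic trace, a simulation, or round-level
records: group relative contribution $\sum c_i / \sum e_i$; group overall
surplus (GOS) $(\sum \pi_i - \sum e_i)/\sum e_i$ (zero under full
defection, and in linear games identically
$\sum_i (p_i - 1)\,\bar c_i / \sum_i e_i$); threshold success rate; Gini
coefficients of endowments and payoffs; per-role absolute and relative
contributions; the fraction of full-contribution rounds; lag-1 reciprocity
correlations $\mathrm{cor}(c_i(t), c_j(t-1))$; and first-five/last-five
round trends.

Choices worth flagging: the Gini uses the population pairwise
mean-difference form $\sum_{ij}|x_i - x_j| / (2 n^2 \bar x)$ without
small-sample correction, applied to per-player session-mean payoffs
(round-level Gini is available by applying `gini()` per round). Statistics
over round records average over rounds within each group first, then
across groups, so each group is one observation. Correlations of constant
series are *undefined* and reported as `NA`, never coerced to zero.

## Synthetic behavioral data

`synth_behavior()` generates round records so the statistics and fitting
pipelines run without any external data: each player mixes a fairness
target (half-endowment, equal-relative, or equal-absolute) with in-kind
reciprocation of the coplayer's last contribution rescaled to their own
endowment, plus Gaussian noise, rounded and clamped to the action set.
Defaults (`reciprocity = 0.5`, `noise_sd = 1`, half-endowment target)
reproduce the two structures that matter downstream: positive lag-1
reciprocity in linear play and coordination near $(e_1/2, e_2/2)$ — which
meets the default threshold exactly — in threshold play. It is a test
fixture, deliberately simple: it has no learning, no treatment-specific
motives, no end-game effects, and no participant heterogeneity beyond
noise, so passing tests against it validate the *pipelines*, not any
behavioral claim about real participants.

## Fitting

`delta_gos()` is the squared-error objective
$\Delta_{\mathrm{GOS}} = \sum_k (\mathrm{GOS}^k_{\mathrm{exp}} -
\mathrm{GOS}^k_{\mathrm{sim}})^2$ over treatments
$k \in \{\mathrm{FE, EI, PI, AI, MI}\}$. `fit_gos_grid()` sweeps a grid of
$(s, \beta, \gamma)$ — the full published grid is
$s \in \{1, 10, 100\}$, $\beta \in \{0..30\}$, $\gamma \in \{0..100\}$;
desk-scale fits coarsen the grid and use $10^5$–$10^6$ steps — simulating
every treatment at every grid point, with per-run seeds derived
deterministically from one master seed, and GOS computed across *all*
recorded rounds (no burn-in). Ties in the argmin break lexicographically
in $(s, \beta, \gamma)$; the grid is traversed in that order and the first
minimum wins. Parameter-recovery experiments (synthetic "observed" GOS
generated by the simulator itself at known $(s, \beta, \gamma)$) recover
the generating parameters' low-objective plateau on a coarse grid; this is
the package's acceptance oracle for the fitter.

## Problem sizes and known limitations

Tests and the acceptance script use $10^5$–$10^6$ introspection steps,
$16$–$30$-point fitting grids, and tiny games ($e = (1,1)$, 64 strategy
profiles) for exact-chain comparisons; these sizes give stable estimates
for every quantity we assert. Known limitations: learning dynamics are
two-player only (reactive response tables over four-player histories grow
exponentially, and the underlying study design simulates pairs);
mixed-strategy equilibria and discount-factor-dependent equilibrium
characterizations are out of scope; minimax is pure-action; the metastable
regimes described above mean simulated occupancies at very strong
selection depend on initialization for any feasible run length; and the
reconstructed productivity pair $(1.9, 1.3)$ is one representative of the
constraint set described earlier, so quantities that depend on its exact
value (e.g. treatment-level surplus magnitudes) should be read as
model-family results rather than point predictions.
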