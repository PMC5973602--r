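---
title: "Clonal competition, niche construction and the ecology of metastasis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal competition, niche construction and the ecology of metastasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorniche)
```

## The model

A primary tumor is modelled as four clonal phenotypes competing under
Lotka--Volterra dynamics. Each clone is indexed `(x, y)`: `x = 1` means the
clone pays a growth-rate cost to construct the *local* niche — it secretes
a shared resource `R` (recruited vasculature, growth factors) that raises
the carrying capacity of every tumor cell — and `y = 1` means it pays a
cost to construct the distant *pre-metastatic* niche, secreting factors
into the bloodstream that prepare a remote site for colonization but give
no local benefit. That yields cheaters (`00`), secondary producers (`01`),
local producers (`10`) and global producers (`11`), in the canonical
ordering used everywhere in this package.

Each clone `i` follows

$$\frac{dn_i}{dt} = r_i n_i\left(1 - \frac{(Cn)_i}{K_i(R)}\right)
  - m_i(N, R)\, n_i, \qquad
  \frac{dR}{dt} = g\,(n_{10} + n_{11}) - l\,R,$$

with carrying capacity $K_i = k + \beta_0 R$ for non-constructors of the
local niche and $k + \beta_1 R$ for constructors. The ratio
$\beta_1/\beta_0$ is the *specificity* of niche construction: above 1 the
constructed resource preferentially benefits its producers, limiting
free-riding. Intravasation removes cells at the crowding-driven rate
$m = \alpha N / (k + \beta_x R)$, with $\alpha$ several orders of magnitude
below every other rate. Because pre-metastatic niche construction is the
gatekeeper of metastasis, a tumor counts as *metastasis-competent* exactly
when a secondary- or global-producer lineage has established.

The interclonal competition matrix `C` (diagonal 1; off-diagonal entries
at most 1, since neighbours tend to be clonemates and unlike clones draw
on partly different resources) comes in three structures:

* **I** — general symmetric: six free coefficients
  $\theta, \phi, \psi, \omega, \mu, \nu$;
* **II** — producers share one metabolic niche: structure I with
  $\omega = \nu = \mu = 1$;
* **III** — two niches defined by local production (`{00, 01}` vs
  `{10, 11}`): intra-niche competition 1, non-constructors experience
  $\theta$ from constructors and exert $\phi$ on them (asymmetric).

### The dispersal denominator

The crowding rate divides by "the" carrying capacity, which is ambiguous
for a four-clone tumor with two capacities. This package uses the focal
clone's own capacity ($\beta_0$ for `x = 0`, $\beta_1$ for `x = 1`): under
that reading, dividing a rare invader's growth equation by $r n$ produces
invasion inequalities whose intravasation terms appear as $\alpha/r$, and
the exact inequalities in `analytic_invasion_exact()` become algebraically
identical to the sign of the invasion eigenvalue. A `dispersal_beta =
"shared"` variant (all clones divided by $k + \beta_0 R$) is provided for
sensitivity checks.

## Default parameters

`param_registry("fig3_defaults")` is the reference set used throughout:
growth rates $r_{00} = 0.07$, $r_{10} = 0.05$, $r_{01} = 0.045$,
$r_{11} = 0.02$ per day (one cell cycle $\approx$ one day; producers pay a
construction cost, global producers pay both), $k = 10^5$ cells,
$\beta_0 = 1$, $\beta_1 = 1.2$, $\theta = \phi = 0.9$, $g = 0.004$ and
$l = 0.001$ per day, $\alpha = 10^{-6}$. The remaining coefficients are not
pinned down by that set; this package fixes $\psi = \omega = \nu = 0.9$
and $\mu = 1$. The $\mu$ choice is deliberate: $\mu$ is the competition
between global and local producers, which construct the same local niche,
draw on the same resource and differ only in the extra secretory burden of
the global producer — ecological equivalence ($\mu = 1$) is the natural
default, and it makes the producer-only community marginally closed to
global producers, so that established producer tumors resist *all*
pre-metastatic niche constructors rather than being trivially invadable
through the $\mu < 1$ channel. Structures II and III make the same
identification.

## Fast/slow reduction

With these rates the cell dynamics relax on a timescale $1/r \sim$ two to
three weeks while the resource accumulates over years, so the package
analyzes the cell subsystem at frozen `R` ("quasi-equilibria") and then
the resource flow along the resulting manifold. At any fixed `R` the
interior fixed point on a resident support solves a *linear* system
(`r_i (Cn)_i + \alpha N K_i/D_i` against `r_i K_i`), which gives closed
forms for the three nontrivial local communities — cheaters only, local
producers only (`n* = K r/(r+\alpha)`), and cheater/producer coexistence —
via `single_type_equilibrium()` and `coexistence_equilibrium()`.
`find_quasi_equilibria()` cross-checks these with a multi-start damped
Newton iteration on the nonlinear right-hand side (starts at the vertices
and centroid of `[0, Kmax]^s`, duplicates merged at `1e-6` relative,
residual bound `1e-8` of the rate scale `max(r K)`). Feasibility of
coexistence requires strictly positive components (threshold
`1e-12 * max(K)` to reject sign noise).

On the producer manifold the slow flow is `g(k + beta1 R) - l R`: whenever
`g*beta1 > l` (0.0038/day at the defaults) the resource grows without
bound on clinical timescales — producer tumors never equilibrate, they
keep expanding exponentially. Two consequences run through everything
below:

* a population slaved to a capacity growing at rate `s = g*beta1 - l`
  trails it by a relative lag `s/r` (about 7.6% for local producers at the
  defaults) and keeps changing at `s` per day — "equilibration" of the
  fast variables is only ever equilibration *up to the slow drift*, which
  is why `detect_fast_equilibration()` takes a tolerance argument and why
  tracking of `k + beta1 R` by the total population is accurate to the
  lag, not to arbitrary precision;
* the lag also softens competitive exclusion: a cheater remnant inside a
  growing producer tumor declines extremely slowly (the producers never
  quite reach the capacity that would exclude it at full strength), so
  within a decade it persists as a shrinking minority rather than going
  extinct.

## Invasion analysis

A rare mutant's fate at a resident quasi-equilibrium is decided by its
per-capita growth rate (`invasion_growth_rate()`, the boundary eigenvalue
of `jacobian_fast()`). `analytic_invasion_exact()` evaluates the same
condition as an inequality `(Cn^*)_{inv} + (\alpha/r_{inv}) N < K_{inv}`;
the two routes are algebraically identical and the test suite checks the
sign equivalence over thousands of random draws. `is_stable()` combines
internal attractivity (resident-block eigenvalues) with external stability
against the founding clones — "producer-only stability" means resistance
to cheater re-invasion, not mere internal attractivity. Coexistence
stability is decided numerically only; its closed form is intractable.

In the limit regime (`alpha ~ 0`; `R >> k` for producer-containing
residents, `R ~ 0` for cheater-only), every verdict reduces to a closed
form in the parameters (`analytic_condition_limit()`, `table3_grid()`).
The salient cells: producer-only communities are stable against cheaters
iff $\theta > \beta_0/\beta_1$ in every structure; secondary producers
invade them iff $\omega < \beta_0/\beta_1$ (I), $\beta_0 > \beta_1$ (II)
or $\theta < \beta_0/\beta_1$ (III); cheater-only communities are never
stable and admit any producer whose cross-coefficient is below 1. Under
structure I, $\omega < \beta_0/\beta_1 < \theta$ opens a *window of
specificity* in which a producer-only tumor is simultaneously stable
against cheaters and open to secondary producers. Under structure III,
stability and invasibility by secondary producers are mutually exclusive.

Several structure-III cells are degenerate at order $\alpha^0$: the
invader's competition row coincides with a resident's own isocline, every
competition term cancels, and the verdict is decided by the
order-$\alpha$ tie-break, which reduces to a growth-rate comparison
(`r01 > r00` for secondary producers against cheater-only and coexistence
residents; `r11 > r10` for global producers against coexistence). All of
these fail whenever producers pay their costs, so those communities are
closed to the respective invaders. The `consistency_report()` harness
validates every cell of the grid against the numeric eigenvalues over
randomized draws, excluding draws within a margin of `1e-3` of a
condition boundary (sign tests carry no information at the knife edge; a
relative zero-tolerance of `1e-10` likewise guards eigenvalue signs
against floating-point noise in the exactly-marginal cells).

## Deterministic integration

`integrate_tumor()` wraps a stiff-capable solver (deSolve's `lsoda`,
relative tolerance `1e-8`, absolute `1e-6` cells) with daily dense output.
Tiny negative undershoots are clipped, and a pseudo-extinction rule zeroes
a clone that falls below one cell *while declining* — without it,
competitively excluded clones decay only asymptotically and "extinction"
never happens in finite time. Both the threshold and the tolerances are
arguments.

## The mutation-arrival ensemble

`simulate_tumor()` couples the deterministic dynamics to daily Poisson
mutation draws: each allowed phenotype transition fires with mean
`n_source * rate * p(transition)` per day, at the defaults a mutation rate
of `2e-7` per cell per day with conditional probabilities 1/500 for each
single-flag transition (`00→01`, `00→10`, `10→11`, `10→00`) and 1/1000 for
each double-flag transition (`00→11`, `01→10`), read per transition;
residual mutations are phenotypically silent and untracked. Each event
moves one cell (the minimal "small but nonzero" perturbation) from source
to target at a day boundary. Integration proceeds in multi-day chunks with
daily dense output purely for speed; since each day's draw uses that day's
starting populations and events apply at day boundaries, the scheme is
distributionally identical to strict daily alternation. Demographic noise
is otherwise neglected — at $10^5$--$10^7$ cells it matters only for the
seeded lineages, whose fate the scoring rule handles explicitly.

**Establishment scoring** (`invasion_success()`): a lineage is established
once it reaches `max(100 * seeded, 0.1% of N)` while not declining, failed
once it hits zero, and a lineage still pending at the horizon is resolved
by its growth *advantage* — per-capita growth minus the tumor's mean
per-capita growth. The relative form matters precisely because producer
tumors grow exponentially: the slow-manifold lag hands every rare clone a
small positive absolute growth rate (about `r_inv * s/r_resident`) even
when its frequency is shrinking, and the advantage criterion correctly
scores such diluted lineages as failures. At a settled resident the two
rules coincide.

**Resident community at arrival** is defined by dominance: a founding
clone (`00` or `10`) counts as a resident when it is established and makes
up at least 10% of the tumor. A freshly seeded lineage racing to
establish, or a remnant undergoing competitive exclusion, is an invader or
a leftover — not a resident — which keeps the community label aligned with
the quasi-equilibrium the tumor is actually tracking. Tumor fates are
labelled the same way (`classify_fate()`), with metastasis-competence
dominating.

`run_ensemble()` runs independent tumors from per-tumor substreams of a
master seed (bit-reproducible) and tabulates arrivals and establishments
of pre-metastatic constructors by resident community. Under the default
conditions — 200 tumors founded with $10^3$ cheaters and `R(0) = 1`
(founding conditions are an assumption of this package, recorded in the
configuration), horizon 3650 days — the ensemble exhibits the
arrival-versus-invasion trade-off: cheater-only tumors see few mutants
(they sit at $10^5$ cells) but those mutants establish; tumors taken over
by local producers grow far beyond `k`, accumulate mutant arrivals in
proportion, and every one of those arrivals fails against the accumulated
specific resource.

## What the randomized draws do and do not show

`sample_params()` is the package's synthetic parameter generator: rates
bracket the registry values, competition coefficients span their
admissible ranges, $\alpha$ is log-uniform about $10^{-6}$, and the
producer cost ordering is enforced by construction. Feasibility-restricted
draws (for coexistence residents) condition on the equilibrium existing,
which is the only regime where the invasion question is posed. Passing the
randomized cross-checks therefore shows that the analytic conditions,
closed forms and numeric routes agree *within this model*, over a broad
admissible parameter region. It says nothing about real tumors: the model
has no space, no immune compartment, a single abstract resource, constant
per-cell rates, and a deterministic core with mutation as the only noise
source.

## Problem sizes and numerical choices

The test suite validates the sign equivalence on 200 draws per structure
across four resource levels, the limit grid on 240 draws per structure per
cell, closed forms against Newton on 100 draws, and the ensemble at its
full 200-tumor, 3650-day setting (the ensemble completes in well under a
minute). Boundary margin `1e-3`; duplicate-root merge `1e-6` relative;
equilibrium residual bound `1e-8` of the rate scale; solver tolerances as
above; establishment thresholds as above. All randomness flows from
explicit seeds.

## Known limitations

* No spatial structure, bloodstream or secondary-site compartments; the
  endpoint is the establishment of a pre-metastatic constructor lineage in
  the primary tumor, not completed metastasis.
* The unbounded exponential growth of `R` at the default rates means
  producer tumors have no finite attractor; several classical equilibrium
  notions apply only in the frozen-`R` sense, and finite-horizon summaries
  (fate labels, arrival counts into producer communities) depend on the
  horizon.
* Within a decade, full cheater extinction inside a growing producer tumor
  is the exception rather than the rule (the slow-manifold lag nearly
  neutralizes exclusion); dominance-based community labels are used
  instead of waiting for extinction.
* Mutation counts into small communities are Poisson with means of order
  one per decade, so any single ensemble realization can lack arrivals
  into a given community; claims about such counts are seed-dependent by
  nature.
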