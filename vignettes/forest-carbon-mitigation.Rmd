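---
title: "Methods: factorial assessment of forest carbon mitigation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: factorial assessment of forest carbon mitigation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestmit)
```

## The question

Managed temperate forests mitigate climate change through three channels:
the in-situ carbon sink (live biomass, dead biomass, soil), the carbon
stored in harvested wood products, and substitution — emissions avoided
when wood replaces carbon-intensive materials and fossil fuels. How much
each channel contributes depends on many interacting factors: forest age
and type, the climate pathway and its disturbance regime, harvest
intensity, salvage logging practice, wood usage patterns, and how quickly
the substituted economy decarbonizes. `forestmit` quantifies the impact of
each factor with a full factorial simulation experiment (3456 scenario
combinations) and attributes effects with pairwise differences between
"partner" simulations that differ in exactly one factor.

## The stand emulator

A process-based vegetation model is deliberately replaced here by a
reduced-form emulator that produces the *statistical structure* the
downstream accounting needs — per-patch pools, harvest fluxes, stochastic
stand-replacing kills — at desk scale. Each stand is `n_patches` (default
100) independent replicate patches. Per patch and year:

1. **Growth.** Stand woody NPP is logistic in the standing stock $B$,

   $$\mathrm{NPP} = N_{\max}\,\max\!\left(0, 1 - B/K\right)\,
     \max\!\left(0, 1 + a\,\Delta T - b\,\Delta T^2\right),$$

   with $N_{\max} = 0.714$ kgC/m²/yr (the regional NPP calibration
   anchor), carrying capacity $K = 18$ kgC/m², and a climate modifier
   ($a = 0.05$, $b = 0.01$ per °C) that is mildly positive at moderate
   warming (CO₂ fertilization, longer growing seasons) and penalizes
   strong warming (drought, heat); it passes back through 1 at
   $\Delta T = 5$ °C. NPP is allocated to cohorts with weights
   $\max(B_i, w_0)$, $w_0 = 0.05$ kgC/m² (`seedling_mass`). A strictly
   biomass-proportional rule would starve zero-biomass regeneration
   cohorts forever; the floor weight is the minimal device that lets
   continuous establishment work while remaining proportional for grown
   cohorts. Note the allocation does not change stand-level $B$ dynamics —
   only the age distribution, which matters solely for the under-20-yr
   firewood rule.
2. **Background mortality** moves 1%/yr of live biomass to deadwood.
3. **Disturbance.** A shared uniform draw $u_{t,\mathrm{patch}}$ triggers a
   stand-replacing event iff $u < p(t)$, killing all cohorts. The baseline
   $p_0$ is the reciprocal disturbance return interval (1/300 yr for
   needle-leaved, 1/1000 yr for broad-leaved stands) and responds to the
   warming anomaly as `constant`, `linear` ($p_0(1 + \Delta T)$) or
   `exponential` ($p_0 2^{\Delta T}$, a doubling per +1 °C, the analysis
   default). The exact response curves are not published; doubling per
   degree is consistent with the steep observed increase of
   central-European disturbance rates and is configurable. Negative
   anomalies never reduce $p$ below $p_0$.
4. **Harvest.** Partial harvests fire every 20 (NE) / 25 (BD) years per
   patch — phases staggered uniformly across patches — removing 24% of
   every cohort, scaled after 2020 by the scenario's intensity level
   (0/50/100/150%).
5. **Dead pools.** Deadwood decays at 4%/yr and soil at 1%/yr, both scaled
   by $Q_{10}^{\Delta T / 10}$ with $Q_{10} = 2$; 30% of deadwood decay is
   humified into the soil pool (a parallel update: soil respiration acts
   on the pre-existing stock). Pools start empty in 1920 — there is no
   spin-up — but all metrics are changes relative to the 2020 stock, so
   only post-2020 dynamics enter the results.

With harvesting and disturbance off, the stand converges to the analytic
fixed point $B^\* = K N_{\max}/(N_{\max} + mK) \approx 14.4$ kgC/m² — note
*below* $K$, because background mortality persists; the tests check
convergence to $B^\*$, not to $K$. Managed stands equilibrate near 10–13
kgC/m², a realistic central-European growing stock.

## Harvest allocation

Cut or killed carbon is partitioned with fixed fractions: 65% of woody
biomass is stem material, of which 90% (fresh cut) or 75% (salvage) is
removed; 13% is branches, of which 40% are removed and burned; everything
else (unremoved stem, remaining branches, coarse roots) is residue routed
to deadwood. Trees younger than 20 years are used entirely as firewood.
Salvage logging (enabled scenarios, events after 2020) processes only 80%
of the killed trees. Residue is computed by difference, so every event
closes exactly. The branch-burn rule is applied to the salvaged share too,
since salvaged wood follows the same usage patterns as fresh wood — the
source material does not state this case explicitly; it is a package
choice.

## Wood products and substitution

Removed stem carbon is allocated to long/medium/short-lived product pools
(NE 37/17/36%, BD 6/34/25%, remainder fuel wood burned in the harvest
year). Each vintage decays along a Gamma survival curve
$S(t) = 1 - F(t;k,\theta)$ calibrated so the median lifetime is 3/18/93
years; the Gamma form produces the empirically observed lag before decay
losses peak. The shape parameter is not published; the default $k = 2$
(per pool, configurable) gives a pronounced lag without an implausibly
heavy tail — the medians are the binding constraint. Cascade usage (+50%)
raises the shape, at fixed scale, until the median is 1.5× larger, for
vintages after 2020 only. Increased material usage scales the long and
medium shares by up to +50% along a linear 2020–2050 ramp, at the expense
of the short and fuel shares, which are reduced in proportion to their
baseline sizes (the source states only "at the expense of" both; the
proportional split is a package choice, and an all-from-short variant
would be a one-line change in `usage_fractions()`).

Substitution credits use displacement factors of 1.5 tC/tC (material,
booked at product creation) and 0.67 tC/tC (fuel, booked at combustion —
stand firewood, the stem fuel share, and end-of-life energy recovery of
every decayed product; wood is assumed never landfilled). Booking times
are a package choice; the source does not state them. All DFs decline as
$m(y) = d^{(y-2020)/30}$ where $d$ is the pace label (25/50/75% of today's
value remaining in 2050), continuing at the same exponential rate past
2050. By construction the pace rescales credits only and cannot touch any
carbon pool — the ensemble invariant "decarbonization pace has zero effect
on the combined sink" is exact, not approximate.

## Metrics and attribution

The **combined carbon sink** at horizon $h$ (2050, 2100) is the change of
the single summed stock (vegetation + deadwood + soil + products) from end
of 2020 to end of $h$; the **total mitigation potential** adds the
cumulative substitution credits over 2021..$h$. An independent flux-side
identity (NPP − heterotrophic respiration − combustion − product decay)
must reproduce the stock-side sink to 1e−9 relative and is enforced in the
tests.

`run_experiment()` simulates each of the 288 distinct stand
configurations once (wood usage, cascade and decarbonization do not feed
back on the stand) and layers the 12 product/substitution variants on
top — an exact factorization that keeps the full factorial at desk scale.
All stochastic draws (climate noise, disturbance uniforms, harvest phases)
derive from `(site, base seed)` only, never from scenario factors:
partner simulations share their random numbers, so pairwise differences
are free of Monte-Carlo noise and the event set of a low-probability
disturbance schedule is a subset of a high-probability one.
`pairwise_differences()` joins partner rows exactly on all non-target
factors (in the exponential-response subset by default): two-level factors
give 576 pairs, one harvest contrast 288, one decarbonization contrast
384.

## What the synthetic world does and does not establish

The generator emulates the *structure* of the original experiment — the
factor design, the accounting arithmetic, the coupling of disturbances to
warming — not the physiology of a process-based model or real forcing
data. Green tests establish: the design and pairing arithmetic; exact
carbon conservation on both the stand and product sides; the printed
parameter arithmetic (decay medians, usage shares, displacement-factor
paths); the binomial statistics of disturbance events; and the structural
invariants (pace-sink independence, salvage nonnegativity at 2050). They
do **not** establish the magnitudes of the original study's pool or flux
trajectories, which depend on process detail deliberately out of scope.

## Numerical choices

* Gamma calibration: `scale = median / qgamma(0.5, shape)`; cascading
  solves the shape with `uniroot` at `tol = 1e-12` and verifies the new
  median to 1e−6. Annual decay uses survival differences at integer ages;
  age-0 vintages do not decay in their creation year.
* Closure residuals are reported relative to the maximum stock scale;
  observed values are ~1e−16, asserted at 1e−9.
* Probabilities are clamped to [0, 1]; growth and decay modifiers floor at
  0; fraction closure (`fuel = 1 − long − medium − short`, residue by
  difference) is exact by construction.
* Seeds are derived by a deterministic string hash below $2^{31}$;
  identical inputs give bit-identical trajectories.

## Known limitations

* **Density-dependent regrowth.** Logistic growth makes thinned stands
  regrow at a rate proportional to $1 - B/K$; with $K$ binding at managed
  stocks, harvest removals are partially compensated within decades. In
  combination with the 93-yr-median long-lived pool (37% of NE stem wood),
  *increased* harvest can increase the combined sink in many NE scenario
  cells, and the strictly-negative harvest→sink finding of the original
  full-physiology study is reproduced only in sign-majority, not in all
  pairs (at the default calibration: ~78% of 150%-vs-100% pairs at 2050,
  ~45% at 2100). The corresponding directional acceptance tests are left
  failing rather than weakened; they document exactly where the emulator's
  simplification bites.
* **Exact ties.** Scenario cells with harvest intensity 0 and salvage off
  produce no products after 2020, so material-usage pairs there differ by
  exactly zero — capping the strictly-positive share at 87.5% (504/576),
  below the 95% the corresponding test demands. Counting ties as
  non-negative would satisfy it; the test keeps the strict reading.
* One site is simulated by default: emulator sites are exchangeable
  replicates distinguished only by their noise seed (`n_sites` raises
  this).
* No species competition, mixed stands, fire, clearcuts, market dynamics,
  landfilling, or additionality/leakage corrections for substitution —
  credits are theoretical maxima.
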