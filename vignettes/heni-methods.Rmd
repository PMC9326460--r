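---
title: "Dietary health-impact characterization: model, assumptions and design choices"
author: "heni package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dietary health-impact characterization: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heni)
```

## The problem

Life cycle assessment (LCA) of foods routinely quantifies environmental
damage to human health — fine particulate, toxicity, climate — in
disability-adjusted life years (DALYs), but leaves the health effect of
*eating the food* unquantified. Yet epidemiology attaches well-characterized
risks and benefits to dietary components: sodium and trans fat are
detrimental, fruit, fiber, calcium, nuts, seafood omega-3 and
polyunsaturated fats beneficial. This package treats those components as
inventory flows and characterizes them into the same damage-level unit as
the environmental impacts, so that both can be compared and summed.

## The model

For a food or recipe delivering $d_r$ grams of dietary risk component $r$
per functional unit (a serving, 100 g, or a kcal), with Dietary Risk
Factors $\mathrm{DRF}_r$ in $\mu$DALY per gram (negative = beneficial), the
dietary impact and its Health Nutrient Index (HENI) expression are

$$
I \;=\; \sum_r d_r \,\mathrm{DRF}_r \quad [\mu\mathrm{DALY/FU}],
\qquad
\mathrm{HENI} \;=\; -0.526 \times I \quad [\text{min healthy life gained/FU}].
$$

The conversion constant is minutes per $\mu$DALY: one DALY is a year of
healthy life and a year holds $525{,}960 \approx 0.526$ million *minutes*,
so $1\,\mu\mathrm{DALY} = 0.526$ min. (Source texts sometimes state this
constant in "seconds", which is dimensionally inconsistent with the minute
results they print; we document the minutes reading and use it throughout.)

Two sign conventions coexist in practice and the package reports both
explicitly: the canonical internal quantity is $\mu$DALY (positive =
damage); HENI minutes are positive-is-gained through the leading minus; and
published component tables often print *minute-scaled values in the
$\mu$DALY sign convention* (negative = beneficial), which reports expose as
`minutes_udaly_sign`.

### Inventory resolution

`resolveComponents()` sums mass $\times$ mass-fraction content over
ingredients, on the serving basis. Double counting is handled by
declarative exclusion rules — (ingredient category, component) pairs whose
contribution is zeroed. The packaged rule set excludes calcium for the
`fluid_milk` category, because fluid milk is itself a risk component whose
dose-response already reflects its calcium; fermented dairy (yogurt) is not
milk, so its calcium counts. Fiber is split by source (`fiber_fruit` vs
`fiber_other`) as separate registry components with their own factors.
Sugar-sweetened beverages are accounted in beverage grams, a provisional
convention recorded in the registry; DRFs supplied for `ssb` must use the
same basis.

### Functional units

Conversions rescale through the serving basis: per 100 g multiplies
amounts by $100/\text{serving mass}$, per kcal by
$1/\text{serving energy}$. Zero mass or energy in the requested
denominator is rejected rather than yielding infinities. Round trips
reproduce inputs to machine precision, and characterization is
scale-equivariant, so the functional-unit choice never changes a ranking
between foods on the same basis.

## Deriving Dietary Risk Factors

Published DRF tables come from full burden-of-disease source data; the
package also derives factors from the epidemiological primitives when the
user supplies them. The construction is the standard comparative risk
assessment:

* **Relative-risk curves** are piecewise log-linear between knots
  (ratio-scale quantities interpolate linearly in log space, the convention
  for monotone dose-response segments), constant beyond the outermost
  knots, and clamped to $RR = 1$ inside the theoretical minimum-risk
  exposure level (TMREL) range, where marginal changes carry no benefit or
  harm.
* **Population attributable fraction**:
  $\mathrm{PAF} = (\mathbb{E}[RR] - 1)/\mathbb{E}[RR]$, with the
  expectation over the population intake distribution and the TMREL
  counterfactual at $RR = 1$.
* **Attributable burden**: $AB = \mathrm{PAF} \times \sum_o B_o$ with
  $B_o$ the associated outcomes' DALY rates per person-year.
* **Marginal DRF**: the central finite difference under a rigid
  $\pm\delta$ g/day shift of the intake distribution,
  $\mathrm{DRF} = \dfrac{AB(+\delta) - AB(-\delta)}{2\,\delta \times 365}
  \times 10^{6}$ $\mu$DALY/g. The $1/365$ converts the sensitivity of an
  annual burden to a per-(g/day) change into a per-gram-consumed factor
  (annualized convention, declared rather than inferred), and $10^6$
  converts DALY to $\mu$DALY.

Default $\delta = 1$ g/day with a convergence check at $\delta/2$; the
finite difference converges at $O(\delta^2)$ for smooth curves. Shifts that
would push intakes below zero clamp mass at zero intake and flag the result.

### Numerical choices

Histogram intake distributions are uniform-density bins, and
$\mathbb{E}[RR]$ over a bin is integrated **in closed form**: the clamped
curve is piecewise $e^{a + bx}$ (or constant), so each piece contributes
$(e^{a+bu} - e^{a+bl})/b$. This makes the PAF exactly invariant under bin
refinement, instead of depending on midpoint quadrature. Lognormal
distributions use adaptive quadrature (`stats::integrate`,
relative tolerance $10^{-10}$) plus an analytic point mass at zero when a
negative shift truncates support. Point masses are evaluated directly.

### Stratification

DRFs may be stratified by age group and sex. The aggregate factor is the
population-weighted mean with caller-supplied weights — the source
framework stratifies but publishes no aggregation rule, so the rule is
explicit here and weights are never assumed.

## Substantial diet changes

Marginal factors apply only to small changes within an overall diet, and
only for the population share in the *active range* (outside the TMREL);
`activeRangeFraction()` reports that share alongside any marginal score.
For substantial changes, attributable fractions of several risk components
acting on the **same outcome** combine multiplicatively,
$1 - \prod_i (1 - \mathrm{PAF}_i)$, while components with disjoint outcomes
add — the granularity follows the risk–outcome pair structure of
burden-of-disease accounting; the exact distribution of overlapping
outcomes across risk factors in whole-diet applications is not published,
so the shared/disjoint rule is a declared convention of this package.
`dietDelta()` shifts each component's distribution rigidly (translation of
the mean, preserving shape — chosen for transparency over re-estimating
distribution shape), recombines, and differences against baseline. As the
shift shrinks, the result approaches the marginal DRF limit
$\mathrm{DRF} \times \delta \times 365 / 10^{6}$, which the tests verify at
$\delta = 1, 0.1, 0.01$ g/day.

Substitution effects (eating more of one food means eating less of another)
are a known confounder in the underlying epidemiology and are out of scope:
scenarios state intake shifts explicitly.

## Damage-level integration

Because dietary impacts are in DALYs, `combineWithEnvironmental()` simply
sums them with environmental damage-level results per functional unit,
keeping each labeled contribution and its share of total absolute damage
(absolute values, so beneficial and detrimental contributions both count in
the denominator). Mixed functional units and duplicate labels are rejected.
Computing the environmental factors themselves is out of scope; they are
consumed as numbers.

## The packaged worked example

`yogurtFixture()` ships a three-ingredient strawberry yogurt (170 g,
127.4 kcal per serving) with six characterized components and their
factors. Scoring it:

```{r yogurt}
fx <- yogurtFixture()
vec <- resolveComponents(fx$recipe)
res <- dietaryImpact(vec, fx$drf)
totalUDALY(res)
heniMinutes(res)
contributionSplit(res)[c("beneficial_minutes", "detrimental_minutes")]
```

about $-0.93\,\mu$DALY per serving, i.e. $+0.49$ minutes of healthy life
gained (0.5 at one decimal): the balance of $\approx 1.39$ minutes gained
(mostly calcium and fruit) against $\approx 0.90$ lost (mostly sodium).
Published versions of this table carry small internal rounding
inconsistencies (a calcium minute cell of $-0.77$ that back-computes to
$-0.76$ from the rounded 0.28 g input; a quoted "1.5 min gained" whose
cells sum to $\approx 1.39$); the package always recomputes from first
principles and documents the discrepancy rather than matching rounded
cells. Per-ingredient contents in the fixture are back-computed from the
published per-serving amounts, so resolution reproduces those amounts to
machine precision.

## The synthetic generator

`generateSynthetic()` makes every module testable without external data. It
emulates recipe-scale composition data: ingredient masses uniform on
5–200 g (typical recipe ingredients), energy densities 0–4 kcal/g (water to
pure fat), sparse component contents uniform on 0–0.2 g/g with ~50%
structural zeros, and DRFs uniform on $-6$ to $+14$ $\mu$DALY/g (the span
of published beneficial to detrimental factors). The expected result is
computed by an independent plain-loop summation kept separate from the
package's matrix code path, so the two act as cross-checks. What it does
*not* emulate: correlated nutrient profiles of real foods, measurement
error in composition databases, or realistic co-occurrence of components —
passing tests demonstrate arithmetic and contract correctness, not
nutritional realism.

## What the derivation module can and cannot reproduce

The packaged worked-example DRFs originate from full national
burden-of-disease source data (hundreds of risk–outcome associations,
stratified intake distributions). Re-deriving them is not possible at desk
scale, and the package does not pretend to: `marginalDRF()` is validated
against closed-form oracles (analytic derivative of the point-mass
attributable burden, $O(\delta^2)$ convergence, Monte-Carlo checks of
$\mathbb{E}[RR]$) and the worked-example factors ship as a static table
consumed by the characterization module.

## Problem sizes and limitations

The test suite exercises recipes of up to a handful of ingredients, 1,000
random generator draws for the independent-summation and
linearity/permutation properties, $10^6$-sample Monte-Carlo oracles for
$\mathbb{E}[RR]$, and finite-difference convergence over two decades of
$\delta$ — sizes at which every oracle is exact or statistically tight
while the whole suite runs in well under a minute.

Known limitations: epidemiological resolution is coarse (all fruits equally
beneficial per gram); risk estimates are revised substantially between
source data versions; morbidity/mortality splits and uncertainty intervals
on the primitives are not modeled; nutrient estimation, cooking losses,
waste and serving-size databases are out of scope — serving size is
caller-supplied data.
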