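# heni — dietary human-health impacts for food LCA

Life cycle assessment of foods quantifies environmental damage to human
health in DALYs (disability-adjusted life years) but traditionally ignores
the health consequences of *eating the food itself*. `heni` closes that gap
for R users working on food LCA, nutrition-sensitive product design, or
diet-level burden modeling: it quantifies the grams of each dietary risk
component a food delivers per functional unit, characterizes them into
µDALY, and expresses the result as the Health Nutrient Index (HENI) —
minutes of healthy life gained or lost per serving, per 100 g, or per kcal —
directly summable with environmental damage-level impacts.

## The model

For amounts *d<sub>r</sub>* (g of risk component *r* per functional unit)
and Dietary Risk Factors *DRF<sub>r</sub>* (µDALY/g; negative = beneficial):

```
impact  =  Σ_r  d_r × DRF_r                     [µDALY/FU]
HENI    =  −0.526 × impact                      [min healthy life gained/FU]
```

(0.526 minutes per µDALY: a year holds ≈ 0.526 million minutes and one DALY
is one year of healthy life.)

When the epidemiological primitives are available, DRFs are derived by
comparative risk assessment: piecewise log-linear relative-risk curves
clamped to RR = 1 inside the TMREL (theoretical minimum-risk exposure
level), population attributable fraction `PAF = (E[RR] − 1)/E[RR]`,
attributable burden `AB = PAF × Σ burden rates`, and a marginal factor as
the central finite difference `DRF = [AB(+δ) − AB(−δ)]/(2δ·365)·10⁶`.
Substantial diet changes combine attributable fractions multiplicatively
(`1 − Π(1 − PAF_i)`) across risk components sharing an outcome.

## Worked example

The packaged three-ingredient strawberry yogurt (corn syrup, strawberries,
plain low-fat yogurt; 170 g and 127.4 kcal per serving):

```r
library(heni)
fx  <- yogurtFixture()
vec <- resolveComponents(fx$recipe)   # d_r per serving
res <- dietaryImpact(vec, fx$drf)     # characterize with DRFs
heniCLI("demo-yogurt")                # or the side-by-side report:
```

```
Strawberry-yogurt worked example (computed vs published):
   component amount_g published_g   drf min_udaly_sign published_min
 fiber_fruit    0.120       0.120 -0.18          -0.01         -0.01
     calcium    0.280       0.280 -5.15          -0.76         -0.77
        pufa    0.080       0.080 -0.61          -0.03         -0.02
      fruits    5.950       5.950 -0.19          -0.59         -0.59
      sodium    0.114       0.114 13.90           0.83          0.83
         tfa    0.030       0.030  4.44           0.07          0.07
total: -0.9251 uDALY/serving (published -0.92)
HENI: +0.49 min healthy life gained/serving (published +0.5)
beneficial 1.39 min vs detrimental 0.90 min
```

Reading it: each component's per-serving amount times its factor gives a
µDALY contribution; the serving nets −0.93 µDALY, i.e. about half a minute
of healthy life gained — roughly 1.4 minutes gained via calcium and fruit
minus 0.9 minutes lost mainly to sodium. The `min_udaly_sign` column is the
minute-scaled µDALY-sign convention that composition tables print (negative
= beneficial); the published calcium/PUFA cells differ by 0.01 because they
were rounded from unrounded inputs. Yogurt's calcium counts because
fermented dairy is not fluid milk; for fluid milk itself the packaged
exclusion rule zeroes calcium to avoid double counting.

Further entry points: `convertFunctionalUnit()` (serving / 100 g / kcal),
`combineWithEnvironmental()` (sum with e.g. fine-particulate µDALY while
keeping contributions), `marginalDRF()` / `paf()` / `rrEvaluate()`
(derivation from epidemiological primitives), `dietDelta()` and
`activeRangeFraction()` (substantial diet changes), `readRecipe()` /
`readDRF()` / `writeReport()` (CSV/JSON interfaces), and the command line
(`inst/cli/heni.R`) with subcommands `score`, `derive-drf`, `diet-delta`,
`demo-yogurt`, `synth`. The methods vignette
(`vignettes/heni-methods.Rmd`) documents the model, conventions and design
choices.

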