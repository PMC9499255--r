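# metabtwin

A whole-body **digital twin** of human glucose, insulin, glycogen and
protein metabolism, for simulating meals, diet schemes and multi-day
fasts — and for asking the questions single clinical studies cannot:
how does the *same* person respond to an oral protein load before
versus after a 48 h fast, or to isocaloric diets that differ only in
meal frequency or macronutrient split?

The package is aimed at quantitative physiologists and systems
biologists who need a mechanistic meal-response model that goes beyond
glucose–insulin dynamics: it tracks hepatic and renal glycogen as finite
stores, routes dietary and muscle-derived amino acids between anabolic
and gluconeogenic fates under energy-status control, and decomposes
endogenous glucose production (EGP) into its four mechanistic sources.

## The model in brief

A stiff ODE system $\dot X = f(X,t,q,u)$, $\hat y = g(X,t,q,u)$ over 15
physiological states (gut, circulation, liver, kidney, muscle), driven
by meal inputs $u(t)$ as square ingestion pulses. Key regulations:
glucose-driven insulin secretion with incretin amplification; hepatic
first-pass plus peripheral insulin clearance; insulin-dependent uptake
in muscle and liver; Hill-type insulin inhibition of gluconeogenesis
(GNG) and glycogenolysis; muscle proteolysis rising as the glycogen
store empties. Two identities hold exactly at every time point:

```
EGP = HGP + RGP = GNG + glycogenolysis
```

Parameters: 57 general (two variants, healthy and T2D, each within
declared optimisation bounds) plus 5 person-specific (basal glucose,
basal insulin, production/clearance/resistance modifiers). Estimation
uses a weighted least-squares cost (weights = SEM), eight qualitative
physiological penalty constraints active only during optimisation, a
χ²(dof = number of data points, α = 0.05) acceptance test, particle-swarm
global search, and ensemble min/max uncertainty bands.

See `vignettes/metabtwin-methods.Rmd` for the full model description,
design choices and limitations.

## Worked example

A healthy 80 kg, 1.80 m adult eats a mixed meal (87 g carbohydrate,
23 g protein) one hour into the simulation:

```r
library(metabtwin)

meal <- diet_schedule(meal_event(1, carb_g = 87, protein_g = 23))
sim  <- simulate_twin(meal, t_span_h = c(0, 10))
sim
#> <twin simulation> 0.0-10.0 h, 601 grid points, 1 meals
#>   plasma glucose 5.00-8.98 mmol/L; hepatic glycogen 263-315 mmol/L

fx <- flux_breakdown(sim)
round(organ_uptake_fractions(fx, window_h = c(0, 1)), 2)
#> brain muscle  liver kidney  other
#>  0.44   0.17   0.12   0.09   0.17
round(insulin_clearance_split(fx), 2)
#> [1] 0.6
```

Plasma glucose peaks at 9.0 mmol/L about 1.4 h after the meal starts
and returns toward the 5 mmol/L basal; hepatic glycogen rises from 275
to a peak of 315 mmol/L on a slower timescale. In the pre-meal hour the
brain takes ~44% of glucose disposal, muscle ~17%, liver ~12%, kidneys
~9%, and the liver accounts for ~60% of insulin clearance — inside the
reported physiological bands.

The headline fasting behaviour:

```r
twin <- digital_twin(anthropometry("male", 80, 1.80))
res  <- run_optt_fast_optt(twin, fast_h = 48)
str(res$summary[c("fed_rise_mM", "post_fast_rise_mM", "sustained_h")])
#> List of 3
#>  $ fed_rise_mM      : num 0
#>  $ post_fast_rise_mM: num 1.64
#>  $ sustained_h      : num 6
```

The identical protein bolus (132.5 kcal, 25.55 g protein) produces no
measurable glucose response in the fed state, but after a 48 h fast it
raises plasma glucose by 1.6 mmol/L, sustained for hours — because the
emptied glycogen store has rerouted amino acids into gluconeogenesis.

Diet schemes are built by name and compared over a three-week protocol:

```r
schemes <- lapply(c(IF = "IF", SFM = "SFM", HCLF = "HCLF", LCHF = "LCHF"),
                  build_diet, daily_kcal = 2000, days = 14)
run_diet_comparison(twin, schemes)
```

which reports the week-3 means of glucose, insulin, glycogen, GNG and
EGP per diet (higher meal frequency lowers mean insulin at nearly equal
mean glucose; the high-carbohydrate split raises glycogen, insulin and
glucose relative to low-carbohydrate).

A command-line interface wraps these workflows:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","metabtwin.R",package="metabtwin"))')" \
    simulate --subject inst/extdata/subject_example.yaml --hours 24 --out out/
```

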