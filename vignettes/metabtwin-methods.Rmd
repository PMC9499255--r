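---
title: "Model and methods behind metabtwin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind metabtwin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabtwin)
```

# The model

`metabtwin` implements a whole-body, multi-timescale ODE model of glucose,
insulin, glycogen and protein metabolism, of the general form

$$\dot X = f(X, t, q, u), \qquad X(t_0) = X_0(q), \qquad \hat y = g(X, t, q, u),$$

where $X$ collects 15 physiological states plus two bookkeeping
integrals, $q$ the parameters, and $u(t)$ the meal input (square pulses
of carbohydrate, protein and fat ingestion in g/min). The states span
four compartment groups:

* **gut** — stomach carbohydrate and protein, intestinal glucose and
  amino acids; first-order gastric emptying and absorption, with protein
  released markedly more slowly than carbohydrate;
* **circulation** — plasma and interstitial glucose (mmol/L), plasma and
  liver-compartment insulin (pmol/L), exchanged by a hepatic plasma
  flow so that portal insulin exceeds peripheral insulin whenever the
  beta cell secretes;
* **liver** — glycogen (mmol/L of liver volume), a fast
  glucose-6-phosphate pool fed by hepatic glucose uptake, and amino-acid,
  pyruvate and TCA-intermediate pools;
* **kidney and muscle** — renal glycogen and a labile muscle protein
  reserve.

The regulation structure is: glucose-dependent insulin secretion (Hill
function of plasma glucose with a glucose-independent floor, amplified
by intestinal glucose content — the incretin effect); hepatic first-pass
plus peripheral insulin degradation; insulin-activated glucose uptake in
muscle and liver alongside insulin-independent uptake in brain, kidney
and other tissues; Hill-type insulin *inhibition* of gluconeogenesis and
glycogenolysis in both liver and kidney; and energy-status control of
protein fate. Endogenous glucose production (EGP) is the sum of four
mechanistic fluxes — hepatic and renal glycogenolysis from their finite
stores, and hepatic and renal gluconeogenesis from a common substrate
pool — so the two accounting identities

$$\mathrm{EGP} = \mathrm{HGP} + \mathrm{RGP}
             = \mathrm{GNG} + \mathrm{glycogenolysis}$$

hold *exactly* at every instant, by construction rather than by
approximate balance.

Protein handling is the part that differentiates fed from fasted
physiology. Ingested protein is tracked in glucose-equivalents (0.60 g
of glucose potential per g protein, the classic gluconeogenic yield) and
arrives in a hepatic amino-acid pool. A routing function of hepatic
glycogen — the model's energy-status signal — splits that pool between
an anabolic fate (return to the muscle protein reserve) and a catabolic
fate (conversion to pyruvate, the gluconeogenic precursor). With full
glycogen stores almost all amino acids go the anabolic way and a protein
bolus barely perturbs plasma glucose; with stores depleted the split
reverses and the same bolus drives a sustained gluconeogenic glucose
rise. Muscle proteolysis, the endogenous substrate source during
fasting, is likewise governed by the glycogen store: it rises smoothly
as the store empties. Driving proteolysis by energy status rather than
by instantaneous insulin is a deliberate design choice: insulin-driven
suppression would make the insulin response to a post-fast protein bolus
shut off the bolus's own substrate supply on a minutes timescale,
whereas muscle protein turnover responds on the hour scale and tracks
the depletion state of the organism. A fixed fraction of peripheral
glucose uptake returns to the substrate pool as pyruvate
(Cori-cycle recycling); without it the basal gluconeogenic flux would
demand an unphysiological proteolysis rate. Ingested fat contributes
energy bookkeeping only and is metabolically inert — a stated model
limitation, shared with the data the model class is built on: conclusions
about low-carbohydrate/high-fat diets therefore rest only on their
carbohydrate and protein content.

## Rate-law forms

All transport and production fluxes are saturating
(Michaelis–Menten-type) in their substrate; insulin activation and
inhibition use Hill functions. Glycogenolysis saturates in the glycogen
store itself with a squared store dependence, so release collapses as
the store approaches exhaustion rather than linearly. Glycogen synthesis
draws on the glucose-6-phosphate pool and is capped by a storage
capacity term $1 - (\mathrm{gly}/\mathrm{gly_{max}})^4$. These forms
were chosen so that the eight qualitative constraints (next section) and
the reported flux proportions can all be satisfied simultaneously; they
are this package's own formulations of the published regulation
topology.

## Units

Glucose mmol/L; insulin pmol/L; hepatic glycogen mmol/L of liver
volume; fluxes umol/kg/min; meal masses g and energies kcal (Atwater: 4
kcal/g carbohydrate and protein, 9 kcal/g fat); time in hours at every
interface, minutes internally.

# Parameters and basal anchoring

There are 57 general parameters in two variants (healthy, T2D) with
per-parameter optimisation bounds (a factor-three window around the
defaults for capacities and rates, narrower for exponents, yields and
volumes), plus 5 person-specific parameters: basal glucose, basal
insulin, and multiplicative production/clearance/resistance modifiers.

Two derived constants close the basal state exactly instead of leaving
it to a transient:

* a **secretion anchor** chosen so the two-compartment insulin subsystem
  is stationary at the person's basal glucose/insulin pair (the
  production modifier then scales only the dynamic increment above that
  basal rate, keeping it identifiable);
* a **production anchor** scaling the four EGP capacities jointly so
  production balances total uptake at the anchored basal state, with the
  gluconeogenic substrate pool solved for self-consistency by root
  finding.

`steady_state()` therefore returns a state whose fast subsystems are
exact fixed points; glycogen and muscle protein are *slow stores* and
drift on their physiological timescales (basal hepatic glycogen drains
at roughly 10 mmol/L/h post-absorptively, which is what sustains EGP).

The T2D variant differs in reduced secretory capacity and incretin
amplification, right-shifted insulin-action and insulin-inhibition
midpoints (resistance), a higher gluconeogenic and lower
glycogenolytic/storage capacity, and a reduced hepatic uptake affinity;
its person defaults are basal glucose 9 mmol/L and insulin 60 pmol/L.

# Estimation and acceptance

The cost is the standard weighted least-squares sum
$V(q) = \sum_{i,j} \left((y_i(t_j) - \hat y_i(t_j, q)) / \mathrm{SEM}_i(t_j)\right)^2$
with $\mathrm{SEM} = \sigma/\sqrt{n}$, the simulated counterpart
linearly interpolated from the dense output grid. Records whose SEM
falls below 5% of the observable's dynamic range are floored to that
value so single ultra-precise points cannot dominate a fit. A parameter
vector is accepted when its *unpenalised* cost does not exceed the
$\chi^2$ quantile at significance 0.05 with degrees of freedom equal to
the number of data points — no subtraction of parameter count.

Eight qualitative constraints guard optimisation against
non-physiological vectors: non-negativity everywhere; plasma insulin
below 3000 pmol/L; renal production at most 40% of EGP; hepatic insulin
clearance at least 40% of the total; proportionate organ uptake shares
(post-absorptive brain 0.35–0.55, muscle 0.10–0.28, liver 0.05–0.22,
kidney 0.02–0.14 — the measured bands with margin for the undefined
"reasonably proportionate"); gluconeogenesis at most 100% of EGP; fed
hepatic glycogen in 200–350 mmol/L; unfed (about 48 h fasted) glycogen
below 100 mmol/L. Each violation adds a constant penalty of $10^5$ —
large enough to dominate any plausible data cost — during optimisation
only; the $\chi^2$ verdict always uses the raw cost.

`fit_global()` is a standard global-best particle swarm (inertia 0.729,
cognitive and social weights 1.49, reflecting bounds), written in the
package because no swarm optimiser is otherwise available to it; the
full-scale preset uses a swarm of 2000 with a $10^{-6}$ stall tolerance
over 20 iterations, and a smoke preset (swarm 24, 40 iterations) keeps
test runs in minutes. Every vector whose cost passes the $\chi^2$ test
is archived; pointwise min/max over the archived ensemble's simulations
gives the prediction-uncertainty bands.

# Personalisation

Three calibration categories, strictly separated from the 57 general
parameters:

1. **anthropometry** — sex/height/weight set total blood volume by the
   sex-specific height-cubed/weight regression equations, with a free
   factor bounded to ±30%; liver blood is fixed at 13% of the total; the
   diabetes flag selects the parameter variant;
2. **basal values** — observed basal glucose/insulin become the
   anchoring targets (exact by construction), and a five-day lead-in
   diet (3 meals/day, 200–1000 kcal per meal) is searched over daily
   energy so the endpoint glycogen matches the observed baseline;
3. **data** — the production/clearance/resistance modifiers are fitted
   to the designated calibration points by Nelder–Mead on the
   weighted-least-squares cost, bounded to [0.3, 3].

A note on identifiability: because the basal state is anchored, the
clearance modifier expresses itself only through insulin kinetics and
the portal/peripheral gradient; with sparse sampling and realistic noise
it is the weakest-identified of the three. Round-trip tests therefore
check the median recovery error across subjects (below 10%) rather than
demanding every subject's clearance estimate individually.

# Numerical choices

Integration uses `deSolve::ode` (lsoda, stiff-capable) with relative
tolerance $10^{-6}$ and absolute tolerance $10^{-8}$, integrating
piecewise between meal start/end boundaries so input discontinuities
never straddle a solver step; dense output defaults to a 1-minute grid.
A classic fixed-step RK4 integrator over the same boundaries serves as
the integrator-independent reference; the two agree within 0.5% relative
on all observables for the fixture protocols (typically within 0.1% on
plasma glucose). During fitting, simulations run at a relaxed tolerance
($10^{-5}$) and a coarser grid, which is far below the data noise.
Negative-state protection is by construction (all outflows are
proportional to their source pool) plus a soft clamp inside the flux
evaluator; trajectories are checked against a $-10^{-9}$ tolerance.
Meals above 1000 kcal are simulated but warned about: they lie outside
the regime the parameter defaults were designed for, and oscillatory
artefacts are possible there.

# The synthetic-study generator

`generate_study()` emulates the statistical structure the estimation
assumes and nothing more: additive, independent, normally distributed
noise around a truth simulation, values stored as replicate means with
$\mathrm{SEM} = \sigma/\sqrt{n}$. Under that construction the truth
parameters' weighted residuals are standard normal, so their cost is
$\chi^2$-distributed with one degree of freedom per record — the
generator and the acceptance test are two halves of the same null
hypothesis, which is what makes end-to-end self-consistency checks
(truth cost near the dof, about 95% acceptance) meaningful. Fixtures
default to at most 30 points per study so the full fit/validate stack
runs in minutes. What the generator does *not* emulate: digitisation
error of figure-extracted data, between-subject variance structure,
CGM sensor drift, or any model discrepancy — passing recovery tests on
these fixtures shows the estimator works when the model is true, not
that the model is true of any real cohort.

# Protocols and diet schemes

`run_optt_fast_optt()` reproduces the fasting-study design: three
standard 2000 kcal days, a dinner at 19:00 on day 3, a 132.5 kcal
protein bolus (25.55 g protein, 2.6 g carbohydrate) at 23:00, a 48 h
fast, and the same bolus again. A fed-state response below 0.5 mmol/L
counts as negligible — the threshold is a documented, configurable
interpretation of "no noticeable response". With the shipped healthy
defaults the fed rise is ~0 while the post-fast rise exceeds 1 mmol/L
and stays above the pre-bolus level for more than 2 h.

`build_diet()` provides the five named schemes at a daily energy target
(default 2000 kcal/day as the isocaloric comparison point): IF (two
meals, 12:00/20:00), SFM (three smaller meals, 08:00/13:00/19:00), 5:2
(five normal days at 1.28x the target = 2560 kcal and two restricted
days at 0.30x = 600 kcal, weekly mean exactly the target), HCLF
(60/25/15 carbohydrate/protein/fat energy split) and LCHF. The printed
45/27/27 split sums to 99 and is normalised before use. Clock times are
the package's own defaults; the source designs show meal bars without
times. For LCHF the carbohydrate energy is half of HCLF's; where the
freed energy goes is not specified anywhere, and this package assigns
it to fat while keeping the protein share (30/25/45) — documented here
because it is a genuine free choice. The three-week comparison protocol
runs a standard week, switches diet, and analyses the third week;
summaries are insensitive to the output grid within 1%.

# Problem sizes used in the shipped checks

The test-suite and acceptance computations run deliberately small
configurations: fixtures of 20–36 records, recovery harnesses of 20
seeds with three free parameters, smoke-preset swarms, and three-week
diet simulations at a 4-minute output grid. These sizes were chosen as
the smallest at which each statistical statement (acceptance rates,
recovery tolerances, Monte-Carlo means) is stable; the full-scale
presets (swarm 2000, multi-study pooling at 273 data points) use the
same code paths.

# Known limitations

* No lipid metabolism or glucose–fat crosstalk; LCHF-type conclusions
  rest on carbohydrate/protein content only.
* No body-weight dynamics and no weight-dependent insulin resistance.
* The gluconeogenic fraction of EGP with the shipped defaults reaches
  about 0.74 late in a healthy day-long fast and about 0.75 (window
  average) in the diabetic variant — the healthy value sits in the
  reported range, while the diabetic share stays below the highest
  literature estimates; pushing it higher flattens the fasting glucose
  decline, and the decline was prioritised.
* Meals beyond 1000 kcal and fasts beyond 72 h are outside the designed
  regime (warned, not blocked).
* Person-specific calibration has been exercised on synthetic subjects;
  real-cohort heterogeneity (adherence, sensor error, unmodelled
  physiology) is out of scope.
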