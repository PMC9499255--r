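Package: metabtwin
Title: Whole-Body Glucose-Insulin-Glycogen Digital Twin for Diet and
    Fasting Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-timescale ordinary-differential-equation model of
    whole-body glucose, insulin, hepatic and renal glycogen, and protein
    metabolism, with meal and fasting inputs. Provides stiff integration
    of diet protocols with discrete meal events, physiological flux
    accounting (endogenous glucose production split into hepatic and
    renal gluconeogenesis and glycogenolysis, organ-specific glucose
    uptake, hepatic versus peripheral insulin clearance),
    weighted-least-squares parameter estimation with qualitative
    physiological constraints and chi-squared model acceptance, ensemble
    uncertainty bands, three-category personalisation into
    subject-specific digital twins, named diet-scheme builders
    (intermittent fasting, 5:2, small frequent meals, high-carb and
    low-carb diets), protocol runners for tolerance tests and multi-day
    fasts, and a synthetic-study generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
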