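Package: pedpdcua
Title: Cost-Utility and Budget-Impact Modelling of Pediatric Peritoneal Dialysis
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Lifetime Markov cohort model comparing automated peritoneal
    dialysis (APD) with continuous ambulatory peritoneal dialysis (CAPD)
    in children with end-stage kidney disease. Implements the
    survival-to-transition-probability conversion chain, a four-state
    cohort engine with discounting and background-mortality merging,
    incremental cost-effectiveness analysis (ICER, net monetary benefit,
    dominance), one-way deterministic sensitivity analysis (tornado),
    probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves, and a ten-year budget-impact projection.
    Includes a synthetic parameter generator and an individual-level
    microsimulation oracle for engine verification.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
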