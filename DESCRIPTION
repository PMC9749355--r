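Package: cvdmicrosim
Title: Markov Microsimulation for Cost-Effectiveness of Cardiovascular
    Primary Prevention in Premenopausal Women
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-level (Markov microsimulation) cost-effectiveness
    model of a lifestyle modification program offered to premenopausal women
    (30-54 years) as primary prevention of cardiovascular disease, from an
    Australian healthcare system perspective. A synthetic cohort drawn from
    survey-style marginal distributions experiences first-ever and recurrent
    cardiovascular events under Cox-form risk equations, accruing discounted
    costs and quality-adjusted life years over a lifetime horizon with
    half-cycle correction and common random numbers across arms. Includes
    base-case, subgroup, deterministic and probabilistic sensitivity,
    threshold, extreme-value adherence, and budget-impact analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    yaml,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
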