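Package: abmprobe
Title: Dot-Probe Attentional Bias Modification Trial Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for designing and analysing dot-probe attentional bias
    modification (ABM) trials. Generates counterbalanced measurement and
    training schedules, simulates full synthetic cohorts with ex-Gaussian
    reaction times and longitudinal questionnaire trajectories, applies
    standard reaction-time cleaning rules, computes the attentional bias
    index, estimates split-half reliability with Spearman-Brown correction
    and Cronbach's alpha, performs Jacobson-Truax reliable and clinically
    significant change classification, and fits the dummy-coded linear
    mixed-effects model ladder compared by AIC and likelihood-ratio tests.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nlme,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
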