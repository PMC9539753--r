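Package: fivechoice
Title: Simulation and Analysis of the Five-Choice Serial Reaction Time Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing rodent five-choice serial reaction time task
    (5CSRTT) data and for simulating the full multi-stage protocol with a
    stochastic agent model. Implements trial classification from timestamped
    operant event logs, session summaries, conditional-omission statistics
    (omissions after correct, OAC, and omissions after incorrect/omission,
    OAIO) that dissociate attentional lapses from reward-eating motor
    confounds, perseveration rank-transfer analysis, and the group-level
    statistics battery (Student t, two-way repeated-measures ANOVA with
    Bonferroni post-hoc tests, linear regression, age-covariate adjustment).
    The generative agent mechanistically embeds the eating-delay confound:
    the intertrial interval starts at reward retrieval while eating continues,
    so long eating times spill into subsequent stimulus windows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
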