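Package: ehusage
Title: Usage Evaluation of Fully Automated Web-Based Interventions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for technical usage evaluation of unguided, fully automated
    web-based self-management interventions from server request logs.
    Reconstructs sessions with an inactivity timeout, computes per-user
    frequency, duration and activity statistics, derives intervention
    adherence (continuous usage) and nonusage attrition (intermittent usage)
    from phase coverage, classifies users against developer-intended minimal
    usage thresholds, and summarises cohorts with Wilson score intervals and
    standard group-comparison tests. Includes a calibrated synthetic
    event-log generator emulating a 70-participant, 16-week intervention
    cohort so the whole pipeline can be exercised without access to trial
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, tools, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
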