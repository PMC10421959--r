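Package: proctailor
Title: Tailoring the PRO-CTCAE Symptom Library for Phase I Oncology Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for condensing the 80-term PRO-CTCAE symptomatic
    adverse-event library into a tailored core survey for phase I oncology
    trials. Implements per-term prevalence and attribute proportion scores
    over pooled survey administrations, threshold elimination with
    carry-forward rules for terms lacking an attribute question,
    leave-one-term-out Cronbach's-alpha domain-reliability pruning, and a
    physician impact-rating refinement step with term reintroduction, all
    recorded in an auditable elimination ledger. A seeded latent-factor
    generator simulates ordinal survey responses with within-domain
    correlation, timepoint attrition, and closed-form marginals so the whole
    pipeline can be exercised and validated without access to raw trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
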