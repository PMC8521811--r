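Package: cvhrx
Title: Pediatric Cardiovascular Health Scoring and Lifestyle Prescriptions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An offline clinical decision-support toolkit for adolescent
    preventive cardiology. Scores the seven Life's Simple 7 cardiovascular
    health factors with interactive what-if recalculation, computes
    BMI-for-age z-scores by the LMS method, generates tailored progressive
    physical-activity plans and Stoplight-Diet recommendations, matches
    geolocated community resources, schedules automated follow-up check-ins
    with Likert-driven goal progression, renders the patient-facing
    behaviour-change prescription, and generates seedable synthetic
    adolescent cohorts for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    geosphere,
    lubridate,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
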