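Package: msfit
Title: Kinect-Based Pilates Exergame Analytics for Multiple Sclerosis Rehabilitation
Version: 1.0.0
Authors@R:
    person("MS-FIT", "Developers", email = "msfit@example.org", role = c("aut", "cre"))
Description: Computational core of a markerless (Kinect V2 style) Pilates
    exergame for people with multiple sclerosis: 25-joint skeleton stream
    input/output and validation, low-pass Butterworth filtering of joint
    trajectories, joint-angle kinematics, gesture-correctness scoring against
    reference templates, a gamification engine (coins, city itinerary,
    missions, calibration gating), session-use and adherence metrics, Likert
    questionnaire descriptive statistics, and a synthetic articulated-motion
    generator so that every stage is testable without sensor hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
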