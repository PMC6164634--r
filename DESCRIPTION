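Package: araquant
Title: Quantification of Upper-Limb Movement from Wearable IMU and EMG Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for instrumented assessment of upper-limb motor function
    during standardized reach-grasp-transfer tasks (Action Research Arm Test
    style protocols) recorded with a seven-sensor wearable inertial
    measurement unit (IMU) system and an eight-channel surface EMG armband.
    Joint angles of a seven degree-of-freedom arm model are estimated from
    gyroscope streams through a Jacobian pseudo-inverse with optional drift
    correction, hand trajectories are re-parameterized by normalized arc
    length and segmented into movement phases from direction-change and
    speed profiles, onsets are refined with a cubic minimum-acceleration
    model, and each phase is quantified with five metrics: movement time,
    rotational jerk index, trajectory similarity against a healthy-median
    reference, trunk stability, and normalized EMG activity. A synthetic
    motion generator emulates task executions across impairment profiles so
    the full pipeline is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    signal,
    pracma,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
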