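Package: circleslines
Title: Bimanual Circles-Lines Coupling Analysis with Single-Case Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the bimanual Circles-Lines drawing paradigm: a synthetic
    trajectory generator with the paradigm's block design (conditions L, C, LL,
    CL in 15 s blocks, six repetitions each), trajectory kinematics (cycle
    segmentation, per-cycle Ovalization Index, drawing frequency), single-case
    inferential tests against a small normative sample (revised standardized
    difference test, unstandardized difference test, two-case comparison,
    single-score deficit test), and a study pipeline that turns trajectories
    and region-of-interest activation estimates into report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
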