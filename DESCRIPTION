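Package: vertpsm
Title: Population State Model for Fluorescence-Tracked Evolution Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects adaptive-mutant expansions in evolving microbial
    populations tracked by fluorescence-activated cell sorting (FACS).
    Implements a population state model: a t-test based statistical
    classifier converts per-subpopulation proportion slopes into
    significance symbols (P/N/Z), and a two-state hidden Markov model
    with a run-length transition penalty decodes those symbols into
    adaptive (A) versus non-adaptive (N) states. Includes supervised
    parameter training from annotated population histories, optimal
    sampling-point suggestions for mutant isolation, error-rate and
    population-dynamics summaries, a synthetic chemostat data
    generator, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
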