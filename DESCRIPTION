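Package: pulsedyn
Type: Package
Title: Two-Species Population Dynamics Under Pulsed Antibiotic Stress
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Deterministic birth-death model of a wild-type and a more
    resistant bacterial species competing through logistic growth while a
    bacteriostatic drug switches the environment between stress levels
    (free, low, high). Builds pulse schedules from duration, high-stress
    width and skewness, integrates the dynamics through single pulses or
    periodic pulse sequences, and extracts the observables used to compare
    treatment regimens: the minimal total population size, the pulse in
    which it is attained, the resistant-to-wild-type composition at pulse
    end, and the optimal low-stress onset timescales. Includes full
    (t_r, s, N) configuration-space sweeps, constant-drug-load variants,
    CSV/JSON writers and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
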