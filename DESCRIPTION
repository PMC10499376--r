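Package: headfixr
Title: Simulation and Analysis of Head-Fixed Operant and Consummatory Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hardware-free discrete-event simulator and analysis toolkit for
    head-fixed rodent behavioral tasks run on a wheel-and-spout platform:
    free-access lick training, retractable-spout training, fixed- and
    progressive-ratio operant conditioning, optogenetic positive and negative
    reinforcement, wheel-based real-time place preference, and brief-access
    multi-spout consumption. Task state machines consume actions from a
    parametric virtual mouse and emit timestamped event logs in a stable CSV
    interchange format; the analysis layer computes lick microstructure,
    trial metrics, operant and place-preference readouts, and a fiber
    photometry processing chain (polynomial detrend, session z-scores,
    peri-event time histograms, and behavior correlations) from those logs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
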