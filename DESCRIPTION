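Package: rmmeff
Title: Emission-Reduction Effectiveness of Risk Management Measures from
    Concentration Decay Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the emission-reduction effectiveness of workplace
    risk management measures (enclosure, local exhaust ventilation, drum
    pumps, drain-and-flush procedures) from continuously monitored solvent
    concentration traces. The descending limb of each trace is fitted by a
    log-linear exponential-decay model whose decay constant is constrained
    to the known room air-exchange rate; the intercept is the extrapolated
    concentration at the moment the transfer ended, a robust proxy for the
    mean room concentration built up by the activity. Replicate summaries
    are compared against baseline scenarios to give minimum, optimal and
    mean emission-reduction percentages. A well-mixed-room simulator
    generates IR-probe-like synthetic traces (first-order ventilation loss,
    transfer-phase source, lognormal noise, movement spikes) so the whole
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    tibble,
    withr,
    yaml
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
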