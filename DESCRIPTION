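Package: lhsched
Title: Dynamic Scheduling of Liquid-Handling Operations for Parallel
    Bioreactor Cultivations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Priority-based dynamic scheduling of liquid-handling-station (LHS)
    operations for parallel mL-scale stirred-tank bioreactor systems. Provides
    the priority calculus (step, step-specific, dynamic-volume and dynamic-time
    algorithms with a critical-priority cap), hard/soft constraint evaluation
    per reactor position, schedulable task definitions (intermittent feeding,
    one-sided pH control, multi-stage sampling, induction, scheduled abort), a
    greedy non-preemptive scheduler with malfunction-based reactor exclusion
    and a safety termination sequence, a digital twin of an eight-channel
    pipetting robot that validates commands and emulates execution times, a
    synthetic fed-batch plant model (overflow metabolism, acetate/pH coupling,
    dissolved-oxygen balance) so complete experiments run in silico, and a
    file-backed tagged time-series store with filtered query and export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
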