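Package: lobulefib
Title: Agent-Based Simulation of Toxicant-Induced Liver Fibrosis in a 2-D Lobule
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-lattice agent-based model of liver fibrosis driven by
    repeated injections of a metabolically activated hepatotoxin (CCl4).
    Hepatocytes on a two-dimensional lobule grid die by pericentral necrosis or
    TNF-alpha-induced apoptosis; Kupffer cells phagocytose dead cells, are
    activated by HMGB1, and switch from a TNF-alpha-secreting M1 phenotype to a
    TGF-beta-secreting M2 phenotype; hepatic stellate cells transform into
    non-migrating myofibroblasts; myofibroblasts and portal fibroblasts deposit
    origin-tagged collagen. Four diffusible mediators (CCl4, HMGB1, TNF-alpha,
    TGF-beta) spread by an eight-neighbour share kernel with first-order decay.
    Includes injection-schedule dosing, time-course metrics (onset, peak,
    periodicity, blank area), scripted sensitivity experiments (injection
    interval, injection count, Kupffer-cell and stellate-cell ratios), and
    snapshot rendering.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
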