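Package: smartscan
Title: Event-Driven Intelligent Microscopy with a Virtual Microscope
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An event-driven acquisition engine for intelligent (feedback)
    fluorescence microscopy: fast low-resolution primary scans are analyzed
    on the fly to detect targets of interest, which trigger high-resolution
    secondary scans at the detected stage positions. Implements four target
    detection workflows (condensed-chromatin mitotic cells, FISH spot-count
    phenotypes, single cells on micropatterned surfaces, and live
    nuclear-envelope-breakdown onset), the tiled-map and block acquisition
    state machines for fixed and live samples, a text message dialect and
    exchange-folder image transport for driving acquisition software, offline
    replay of recorded primary scans, and a virtual microscope simulator that
    renders multi-channel z-stack tiles of parameterized synthetic samples
    with exportable ground truth so the whole system runs without hardware.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    tiff,
    jsonlite,
    yaml,
    EBImage
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
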