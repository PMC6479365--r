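Package: edenp
Title: Enzymatic Numerical P System Simulation and Membrane-Computing Edge Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A general-purpose execution engine for enzymatic numerical P systems
    (ENPS), a class of cell-like membrane systems whose objects are numerical
    variables evolved by programs made of a production function and a repartition
    protocol, with enzyme variables gating rule applicability. On top of the engine,
    the package compiles a grayscale image and an edge threshold into a four-membrane
    system (EDENP) that performs gradient-based edge detection in five parallel
    macro-steps, and verifies it against an independent serial Sobel/Prewitt/Roberts
    edge detector. Includes PGM (P2/P5) and delimited-text image input/output, a
    seeded synthetic image generator with known edge loci, resource accounting for
    the membrane system, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
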