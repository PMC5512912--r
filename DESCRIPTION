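Package: iolens
Title: Aspheric Intraocular Lens Design by Ray Tracing and a Real-Coded
    Genetic Algorithm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Sequential real and paraxial ray tracing through conic
    (aspheric) surfaces of a schematic human eye, third-order Seidel
    aberration sums, RMS spot size and geometric modulation transfer
    function metrics, and a real-coded genetic algorithm with
    roulette-wheel selection, blend crossover, bounded mutation and an
    optional damped-least-squares polish for optimizing intraocular lens
    curvatures, conic constants and thicknesses against myopia and
    astigmatism.  Ships schematic-eye and lens prescriptions as
    plain-text fixtures, a prescription/config file format, and a small
    command-line front end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
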