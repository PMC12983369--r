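Package: aquadmc
Title: Dynamic Monte Carlo Track Structure for Liquid-Water Radiolysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Event-by-event dynamic Monte Carlo simulation of the physical
    and physicochemical stage of liquid-water radiolysis. Primary electrons
    (20 eV to 30 keV) generate tracks from channel-resolved cross sections;
    every secondary electron is propagated for about one picosecond in the
    time-dependent, dielectrically screened Coulomb field of its parent
    cation, down to thermalisation. Final electron-cation separations are
    classified against a charge-separation radius to predict initial
    hydrated-electron yields G(1 ps), W values, and the energy and spatial
    distributions of subexcitation electrons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
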