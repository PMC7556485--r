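Package: rodspr
Title: Space-Resolved Simulation of Rod Single-Photon Response Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully space-resolved biophysical model of vertebrate rod
    phototransduction on a homogenized cylindrical outer segment. Activated
    phosphodiesterase spreads by surface diffusion on the photoisomerized disk
    (with incisures as reflecting barriers), cGMP and calcium obey
    reaction-diffusion over coupled interior, outer-shell and special-disk
    domains, and membrane currents follow from cooperative channel and
    exchanger kinetics. Monte-Carlo ensemble drivers quantify single-photon
    response variability arising from the random transverse location of the
    photoisomerization and from stochastic stepwise rhodopsin shutoff, as
    functions of disk radius, incisure pattern and cGMP diffusivity, with
    mouse and salamander parameter presets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
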