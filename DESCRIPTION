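Package: follidose
Title: Alpha-Particle Microdosimetry for Thyroid Follicle Models
Version: 0.1.0
Authors@R:
    person("follidose", "maintainers", email = "follidose@example.org",
           role = c("aut", "cre"))
Description: Monte Carlo microdosimetry of the alpha emitter astatine-211 in
    spherical thyroid-follicle models for mouse, rat and human.  Implements
    continuous-slowing-down-approximation (CSDA) transport of the two 211At
    alpha lines through nested single- and multi-follicle geometries, with
    source compartments in the follicle lumen, follicle cells, cell nuclei
    and surrounding follicles.  Computes specific-energy and lineal-energy
    statistics for the follicle-cell nucleus (mean specific energy per decay,
    single-hit mean specific energy, frequency-mean lineal energy, single-hit
    spectra, fraction of alphas fully stopped in the lumen) together with a
    MIRD mean-dose comparison, parameter sweeps and table regeneration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
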