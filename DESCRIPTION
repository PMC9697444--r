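Package: pbrsurf
Title: Surface Energy, Wettability and Biofouling Propensity of
    Photobioreactor Materials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Characterizes candidate photobioreactor construction
    materials from sessile-drop contact angles and related surface
    measurements. Inverts the three-liquid van Oss-Chaudhury-Good
    acid-base Young-Dupre system to recover Lifshitz-van der Waals and
    electron-acceptor/donor surface-energy components, computes the free
    energy of cohesion in water, water adhesion tension and Zisman
    critical surface tension, and classifies surfaces under the Vogler
    and Baier biocompatibility criteria. Also provides surface
    zeta-potential extrapolation from displacement-resolved tracer
    measurements, average shear-rate estimation for orbitally shaken
    dishes, control-normalized exopolymeric-substance adhesion with
    one-way ANOVA and Fisher LSD compact-letter grouping, and synthetic
    data generators with the replicate structure of goniometer,
    zetasizer and adhesion assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    minpack.lm,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
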