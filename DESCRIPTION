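Package: photocoag
Title: Simulation of Laser Photocoagulation of Large Blood Vessels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for planning and simulating near-infrared (1.07 um) laser
    coagulation of large (0.05-1 mm) blood vessels. Provides the closed-form
    selective-photothermolysis dosimetry calculator (thermal relaxation time,
    adiabatic temperature rise, pulse-train arithmetic) together with a
    stacked-pulse irradiation protocol generator, and a deterministic 2D
    thermofluid simulator coupling pulsed-light heat deposition (flat-top beam,
    Beer-Lambert attenuation), advective-conductive heat transfer in flowing
    blood with temperature-dependent viscosity, wall shear stress extraction,
    and Arrhenius thermal damage accumulation. A sweep driver compares vessel
    lumen diameters under a shared irradiation schedule.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
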