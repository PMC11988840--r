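Package: lamellar
Title: Lamellar Neutron Diffraction Analysis of Oriented Lipid Multilayers
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to analyse lamellar neutron diffraction from oriented
    lipid multilayer films: reduction of omega-scan reciprocal-space maps to
    one-dimensional diffractograms, Bragg peak detection and fitting,
    d-spacing estimation with propagated uncertainty, absorption / Lorentz /
    flux intensity corrections, centrosymmetric phase (sign) assignment,
    Fourier synthesis of neutron scattering length density profiles, and
    extraction of membrane metrics (Gibbs-Luzzati bilayer thickness, water
    layer, midplane trough, hydrocarbon hump). Includes a forward simulator
    that renders noisy diffraction patterns from parametric membrane density
    models of archaeal diether / tetraether lipid films, so the whole chain
    is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
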