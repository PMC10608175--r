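Package: memelastic
Title: Continuum Elasticity of Lipid Membranes with Liquid-Ordered Domains
    and Adsorbed Amphipathic Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A one-dimensional continuum-elasticity solver for lipid bilayers
    with coexisting liquid-ordered (Lo) and liquid-disordered (Ld) phases and
    rigid adsorbed amphipathic peptides. Minimizes a quadratic tilt-splay
    energy functional over piecewise-analytic director and surface-shape
    fields, using an exponential Euler-Lagrange solution basis per membrane
    region with continuity, decay and peptide boundary conditions. Computes
    the elastic contribution to the line tension of the domain boundary,
    membrane-mediated peptide-domain interaction profiles, and domain-domain
    fusion energy barriers as a function of inter-domain distance and peptide
    occupancy. An independent finite-difference variational discretization of
    the same functional is included as a cross-check.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
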