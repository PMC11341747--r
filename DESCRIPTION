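Package: aneutreat
Title: In Silico Treatment Comparison for Bifurcation Aneurysms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for desk-scale in silico comparison of endovascular
    treatments for intracranial bifurcation aneurysms. Generates
    parametric middle-cerebral-artery bifurcation-aneurysm lumens,
    encodes the Contour intrasaccular device selection table and braided
    flow-diverter (e.g. Silk Vista Baby) specifications, performs fast
    virtual deployment of strut-level device wireframes by damped
    relaxation with rigid-wall contact, solves steady incompressible
    Newtonian flow on an immersed-boundary Cartesian grid with the
    deployed device coupled as a homogenized porous screen or resolved
    struts, and reports aneurysm neck inflow, daughter-vessel flow and
    wall shear stress together with treated-versus-untreated comparison
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
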