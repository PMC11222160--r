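Package: cryomem
Title: Membrane Signal Modelling and Geometry Analysis for In Situ Cryo-EM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for handling lipid-bilayer membrane signals in cryo-EM
    images of membrane-protein complexes in their native environment.
    Simulates curvature-indexed banks of 2D bilayer projections, detects
    membrane side views by normalized cross-correlation template matching,
    estimates membrane orientation, centre and local curvature from class
    averages (Radon transform plus template correlation), and weakens the
    dominant membrane signal by subtracting a locally averaged estimate
    within a soft mask. Fits smooth bilayer surfaces to binarized 3D
    density, maps altitude contours and mean/Gaussian curvature, and
    deforms planar phospholipid lattices onto fitted surfaces. Includes
    coordinate-model measurements (membrane height from lipid headgroups,
    ligand height above the membrane, inter-group distances) and seeded
    synthetic-data generators with exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
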