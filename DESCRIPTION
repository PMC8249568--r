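Package: sws4d
Title: Four-Dimensional Superficial Wall Strain and Stress of Coronary Arteries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Inverse estimation of the dynamic strain and stress of the
    superficial (luminal) coronary arterial wall from a sequence of 3D lumen
    geometries over the cardiac cycle. Vessel frames are discretized into
    structured tubular surface meshes with identical node dimensions, a
    one-to-one node correspondence between consecutive cardiac phases is found
    by minimizing a potential-energy functional, element stretch ratios yield
    principal strains, and an incompressible Mooney-Rivlin membrane model with
    lesion-aware material assignment yields Cauchy and von Mises stresses,
    including systolic-diastolic pulse stress. Ships a synthetic generator of
    idealized stenotic vessels and cardiac-cycle motion with known ground
    truth, a force-based cylindrical membrane equilibrium comparator, and
    Procrustes centerline-prediction validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml
Config/testthat/edition: 3
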