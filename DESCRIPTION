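Package: memcurv
Title: Curvature-Restrained Membrane Builders and Curved-Membrane Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building asymmetric bicelle membrane systems held at a
    prescribed global curvature by repulsive dummy-particle walls, and for
    analysing curved membrane configurations. Generates anchor/shell wall
    grids with GROMACS-compatible coordinate (GRO) and topology (ITP)
    fragments, plans gradual bending schedules, assembles lipid bilayers from
    a leaflet composition table with selective inter-monolayer repulsion, and
    provides curvature-aware analyses: signed-depth density profiles,
    deuterium order parameters against the local membrane normal,
    tangent-plane Voronoi areas per lipid, and cholesterol inclination, depth
    and interleaflet (minor) fraction statistics. A synthetic-configuration
    generator with known ground truth makes every operation testable without
    simulation output.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deldir,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
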