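Package: cochleoplan
Title: Landmark-Based Cochleostomy Target and Insertion Trajectory Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes scala tympani centerlines, ideal electrode insertion
    trajectories and cochleostomy targets from a segmented inner-ear surface
    mesh and four anatomical landmarks. Builds a local cochlear coordinate
    system, truncates the labyrinth surface to the basal scala tympani,
    extracts radial cross sections and fits a smoothed cubic spline
    centerline, then locates cochleostomy targets by ray/triangle
    intersection along centerline tangents. Also provides planning and
    evaluation metrics (out-of-plane and in-plane alignment angles,
    point-based rigid fiducial registration, drilled-trajectory target
    error, basilar-membrane plane-approximation error, angular insertion
    depth) and a synthetic helico-spiral phantom generator with analytic
    ground truth so that every pipeline stage is testable without clinical
    data. Reads and writes STL, PLY and OBJ surface meshes and JSON
    landmark/plan files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
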