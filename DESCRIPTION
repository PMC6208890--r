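Package: neurofield
Title: Neural Field Models on Flat and Curved Triangulated Domains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Solves two-variable nonlocal neural field equations (activity plus
    a slow recovery variable, mexican-hat connectivity, sigmoidal firing rate)
    on flat periodic squares and closed triangulated surfaces. Spatial
    discretisation uses piecewise-linear collocation with a three-point vertex
    quadrature rule on triangles; reference discretisations (trapezoidal rule
    and FFT convolution on regular periodic grids, parametric trapezoidal rule
    on the torus) are included for cross-validation. Connectivity is a function
    of geodesic distance, computed analytically on the periodic plane and by
    fast marching (or edge-graph Dijkstra) on triangulated surfaces. Includes
    mesh generators (periodic Cartesian grid, torus grid, seeded irregular
    Delaunay meshes), quadrisection refinement, OFF/PLY input and output,
    discrete Gaussian curvature, mesh-convergence studies, travelling-bump
    tracking, and a reproducible configuration-driven pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    deldir,
    stats,
    utils,
    graphics,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
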