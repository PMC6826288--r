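Package: wingmorph
Title: Geometric and Topological Morphometrics of Insect Wings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying insect-wing size, shape and structure from
    images of wing venation. Wing images (veins dark on a bright membrane) are
    segmented into vein-bounded membrane domains by intensity-dependent front
    propagation, the resulting label map is polygonized into a tessellation
    plus a planar venation graph, and a set of dimensionless morphospace
    statistics is computed: contour curvature profiles from least-squares
    circle fits, the isoperimetrically anchored normalized perimeter, scaled
    internal vein length, per-domain circularity and fractional area, binned
    proximal-distal trait profiles, and maximum-modularity community structure
    of the venation network under unweighted, inverse-length and
    vein-resistance edge weightings. A seeded synthetic-wing generator
    (clipped centroidal Voronoi tessellations with controllable domain count
    and density gradients) provides ground-truthed fixtures spanning
    sparse fly-like to dense dragonfly-like venation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, Rcpp, igraph, png, tiff
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
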