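Package: craniomorph
Title: Atlas-Based 3D Craniofacial Morphometrics with Pseudo-Landmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dense 3D phenotyping of craniofacial shape from surface
    meshes and label volumes: symmetric pseudo-landmark generation on a template
    mesh, landmark transfer to specimens by rigid (ICP) then deformable
    (coherent point drift) point-cloud registration, generalized Procrustes
    analysis with sliding surface semilandmarks, bilateral object-symmetry
    decomposition into symmetric and fluctuating-asymmetric shape components,
    residual-randomization Procrustes ANOVA, morphological disparity and shape
    PCA with per-axis permutation tests, and atlas-based propagation of label
    volumes through displacement fields for segmentation validation. Includes a
    fully parameterized synthetic-study generator (template mesh, deformed
    specimens, replicate manual landmarks, otolith label volumes) with recorded
    ground truth, plus readers and writers for FCSV fiducials, PLY/OBJ meshes,
    and NRRD volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
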