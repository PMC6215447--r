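Package: fabpose
Title: Inverse Posture Estimation from Cancellous Bone Fabric
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A quasi-static biomechanical pipeline that estimates the
    characteristic limb posture of a biped from the architectural fabric of
    its cancellous bone. Given a parameterized musculoskeletal hindlimb
    model, each candidate posture is evaluated by static optimization of
    muscle activations, linear-elastic tetrahedral finite-element solves of
    the femur and tibiotarsus, and eigenanalysis of the resulting stress
    fields; the posture whose minimum-principal-stress trajectories best
    align with the observed trabecular fabric directions is returned by a
    deterministic coordinate-descent search. Includes a synthetic
    bird-like hindlimb generator and synthetic fabric-field generators so
    the whole pipeline is testable without imaging data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
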