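Package: predgait
Title: Predictive Simulation of Prosthetic and Stiff-Knee Gait by Direct Collocation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Optimal-control prediction of walking with a reduced sagittal-plane
    musculoskeletal model, including variants for a knee-disarticulation amputee
    fitted with a variable-damping microprocessor-controlled prosthetic knee
    (MPK) and for induced stiff-knee gait (SKG). Provides Hill-type muscle-tendon
    dynamics with implicit tendon compliance, Raasch activation dynamics, exponential
    passive joint moments, Hunt-Crossley foot-ground contact, a bilinear MPK damper
    model, and a metabolic energy model; transcribes parameter-estimation and gait
    prediction optimal-control problems with third-order Radau collocation and solves
    the resulting sparse nonlinear programs with a built-in augmented-Lagrangian
    solver. Also implements the accompanying statistics: one-dimensional
    nonparametric (permutation) statistical parametric mapping paired tests on gait
    cycles, banded dynamic time warping similarity scores, gait-cycle normalization,
    and synthetic gait-trial generation with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: Matrix, methods, stats, utils, yaml, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr, deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
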