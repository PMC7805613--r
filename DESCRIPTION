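Package: neuromc
Title: Morphological Computation Across a Neuro-Muscular Control Hierarchy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates planar human arm movements with a layered
    neuro-musculoskeletal model (two-link dynamics, six Hill-type
    muscle-tendon units, Hatze-type activation, delayed proprioceptive
    feedback, equilibrium-point control, and a central pattern generator
    driving a hand-held vibrating rod), and quantifies morphological
    computation at every level of the control hierarchy with a discrete
    Kullback-Leibler estimator equivalent to conditional mutual
    information I(W'; W | A). Includes discrete Markov benchmarks with
    analytically known values for estimator validation and
    repeated-measures statistics for comparing hierarchy levels.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
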