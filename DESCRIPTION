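Package: qhsboa
Title: Quantum-Enhanced Secretary Bird Optimization and Kernel Extreme
    Learning Machines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the Secretary Bird Optimization Algorithm (SBOA) and
    its quantum-enhanced variant QHSBOA, which augments the base swarm with a
    particle-swarm velocity search mechanism, dynamic boundary repair anchored
    on the best individual, and a quantum-rotation mutation scaled by Student-t
    draws.  Couples the optimizer to a Kernel Extreme Learning Machine (KELM)
    binary classifier whose penalty and kernel-width hyperparameters are tuned
    by nested stratified cross-validation.  Includes an analytic benchmark
    function suite with seeded shift/rotation, a multi-run benchmarking harness
    with rank-sum and Friedman comparisons, and a generator of synthetic
    diabetes-like tabular data with controllable class separation and
    missingness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
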