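Package: cgmelt
Title: Conformational Restraints and Membrane-Binding Melting Analysis for
    Coarse-Grained Peptide Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gaussian conformational restraints on backbone bend and dihedral
    angles for coarse-grained peptide models, with analytic Cartesian forces,
    tabulated-potential export, and minimal Metropolis and Brownian-dynamics
    samplers for statistical validation. Implements a peptide-membrane binding
    analysis pipeline built on residue-phosphate contact indices: per-residue
    and global contact indices, temperature melting curves, logistic
    melting-temperature fits, the temperature-averaged global contact index
    (TAGCI) for deletion constructs, and segment-based convergence estimates.
    Includes a synthetic multi-temperature trajectory generator with known
    two-state binding ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
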