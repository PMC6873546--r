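Package: pripot
Title: Principal Interactions of Knowledge-Based Pair Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trains distance-dependent knowledge-based pair potentials over
    the 210 amino-acid pair types, computes per-structure pair-type energy
    vectors, and extracts the principal interactions -- the subset of pair
    types that captures most of the variance of native-structure energies --
    by covariance eigendecomposition with an eigenvalue-weighted contribution
    threshold. Includes reduced (principal-only) scoring, six decoy-set
    performance criteria (Top1, native and best-decoy Z-scores, RMSD of the
    energy minimum, energy-RMSD correlation, 20 percent fraction enrichment),
    and seeded synthetic generators for polymer chains, decoy ladders and
    planted energy matrices.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
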