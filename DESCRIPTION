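Package: maxasa
Title: Maximum Allowed Solvent Accessibility Scales for Protein Residues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving maximum-ASA normalization scales for relative
    solvent accessibility (RSA). Builds Gly-X-Gly tripeptides from internal
    coordinates, exhaustively scans backbone (phi/psi) and side-chain (chi)
    conformations, computes Lee-Richards solvent-accessible surface area by
    Shrake-Rupley quadrature with DSSP-compatible radii, and records the
    maximum ASA per amino acid and per Ramachandran bin. A companion survey
    pipeline mines PDB-format structures for per-residue ASA with quality
    filters, defines CORE/ALLOWED/GENEROUS/ALL Ramachandran regions, and
    reports RSA exceedance frequencies. Published normalization constants and
    hydrophobicity-scale machinery (mean RSA, fraction buried, correlations
    with experimental transfer-energy scales) are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
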