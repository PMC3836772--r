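#' Standard backbone geometry parameters
#'
#' Bond lengths (Angstrom) and bond angles (degrees) used when constructing
#' peptides from internal coordinates. Defaults follow the Engh & Huber
#' standard values used throughout crystallographic refinement; all values
#' can be overridden, and a survey of any structure corpus can supply
#' replacement means.
#'
#' @param ... Named overrides of the default values.
#' @return Named list of geometry parameters.
#' @export
geometry_params <- function(...) {
  p <- list(
    n_ca = 1.458, ca_c = 1.525, c_o = 1.231, c_n = 1.329,
    ang_n_ca_c = 111.2, ang_n_ca_c_gly = 112.5,
    ang_ca_c_n = 116.2, ang_c_n_ca = 121.7, ang_ca_c_o = 120.5
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) abort(paste("unknown geometry parameter:", paste(bad, collapse = ", ")))
    p[names(dots)] <- dots
  }
  p
}

# Side-chain build entries: one row per heavy atom beyond the backbone.
# ref_a/ref_b/ref_c name previously placed atoms of the same residue;
# the new atom bonds to ref_c. `chi` gives the free torsion index driving
# the dihedral (NA = fixed), `offset` is added to it (or is the dihedral
# itself when chi is NA). Lengths/angles are standard heavy-atom values.
sc_row <- function(atom, element, a, b, c, len, ang, chi = NA_integer_, offset = 0) {
  tibble(atom = atom, element = element, ref_a = a, ref_b = b, ref_c = c,
         length = len, angle = ang, chi = as.integer(chi), offset = offset)
}

# CB is common to all non-Gly residues: improper torsion N-C-CA-CB fixes
# the L-configuration at CA.
cb_row <- function(len = 1.530, ang = 110.4, improper = 122.68) {
  sc_row("CB", "C", "N", "C", "CA", len, ang, NA, improper)
}

sidechain_templates <- function() {
  list(
    G = sc_row(character(), character(), character(), character(), character(),
               numeric(), numeric(), integer(), numeric()),
    A = cb_row(1.521, 110.4),
    S = dplyr::bind_rows(
      cb_row(),
      sc_row("OG", "O", "N", "CA", "CB", 1.417, 110.8, 1L)
    ),
    C = dplyr::bind_rows(
      cb_row(),
      sc_row("SG", "S", "N", "CA", "CB", 1.808, 113.8, 1L)
    ),
    T = dplyr::bind_rows(
      cb_row(1.540, 111.5),
      sc_row("OG1", "O", "N", "CA", "CB", 1.433, 109.5, 1L),
      sc_row("CG2", "C", "N", "CA", "CB", 1.521, 110.5, 1L, -120)
    ),
    V = dplyr::bind_rows(
      cb_row(1.540, 111.5),
      sc_row("CG1", "C", "N", "CA", "CB", 1.527, 110.7, 1L),
      sc_row("CG2", "C", "N", "CA", "CB", 1.527, 110.4, 1L, 122.3)
    ),
    I = dplyr::bind_rows(
      cb_row(1.540, 111.5),
      sc_row("CG1", "C", "N", "CA", "CB", 1.530, 110.4, 1L),
      sc_row("CG2", "C", "N", "CA", "CB", 1.521, 110.5, 1L, -122.0),
      sc_row("CD1", "C", "CA", "CB", "CG1", 1.513, 113.8, 2L)
    ),
    L = dplyr::bind_rows(
      cb_row(),
      sc_row("CG",  "C", "N", "CA", "CB", 1.530, 116.3, 1L),
      sc_row("CD1", "C", "CA", "CB", "CG", 1.521, 110.7, 2L),
      sc_row("CD2", "C", "CA", "CB", "CG", 1.521, 110.7, 2L, 122.6)
    ),
    P = dplyr::bind_rows(
      # endocyclic geometry fixed; ring closed by the N-CD bond (see bonds)
      sc_row("CB", "C", "N", "C", "CA", 1.530, 103.0, NA, 115.3),
      sc_row("CG", "C", "N", "CA", "CB", 1.492, 104.5, NA, 22.0),
      sc_row("CD", "C", "CA", "CB", "CG", 1.503, 105.5, NA, -25.0)
    ),
    M = dplyr::bind_rows(
      cb_row(),
      sc_row("CG", "C", "N", "CA", "CB", 1.520, 113.3, 1L),
      sc_row("SD", "S", "CA", "CB", "CG", 1.803, 112.7, 2L),
      sc_row("CE", "C", "CB", "CG", "SD", 1.791, 100.6, 3L)
    ),
    K = dplyr::bind_rows(
      cb_row(),
      sc_row("CG", "C", "N", "CA", "CB", 1.520, 114.1, 1L),
      sc_row("CD", "C", "CA", "CB", "CG", 1.520, 111.3, 2L),
      sc_row("CE", "C", "CB", "CG", "CD", 1.520, 111.3, 3L),
      sc_row("NZ", "N", "CG", "CD", "CE", 1.489, 111.9, 4L)
    ),
    R = dplyr::bind_rows(
      cb_row(),
      sc_row("CG", "C", "N", "CA", "CB", 1.520, 114.1, 1L),
      sc_row("CD", "C", "CA", "CB", "CG", 1.520, 111.3, 2L),
      sc_row("NE", "N", "CB", "CG", "CD", 1.460, 112.0, 3L),
      sc_row("CZ", "C", "CG", "CD", "NE", 1.329, 124.2, 4L),
      # planar guanidinium
      sc_row("NH1", "N", "CD", "NE", "CZ", 1.326, 120.0, NA, 0),
      sc_row("NH2", "N", "CD", "NE", "CZ", 1.326, 120.0, NA, 180)
    ),
    D = dplyr::bind_rows(
      cb_row(),
      sc_row("CG",  "C", "N", "CA", "CB", 1.516, 112.6, 1L),
      sc_row("OD1", "O", "CA", "CB", "CG", 1.249, 118.4, 2L),
      sc_row("OD2", "O", "CA", "CB", "CG", 1.249, 118.4, 2L, 180)
    ),
    N = dplyr::bind_rows(
      cb_row(),
      sc_row("CG",  "C", "N", "CA", "CB", 1.516, 112.6, 1L),
      sc_row("OD1", "O", "CA", "CB", "CG", 1.231, 120.8, 2L),
      sc_row("ND2", "N", "CA", "CB", "CG", 1.328, 116.4, 2L, 180)
    ),
    E = dplyr::bind_rows(
      cb_row(),
      sc_row("CG",  "C", "N", "CA", "CB", 1.520, 114.1, 1L),
      sc_row("CD",  "C", "CA", "CB", "CG", 1.516, 112.6, 2L),
      sc_row("OE1", "O", "CB", "CG", "CD", 1.249, 118.4, 3L),
      sc_row("OE2", "O", "CB", "CG", "CD", 1.249, 118.4, 3L, 180)
    ),
    Q = dplyr::bind_rows(
      cb_row(),
      sc_row("CG",  "C", "N", "CA", "CB", 1.520, 114.1, 1L),
      sc_row("CD",  "C", "CA", "CB", "CG", 1.516, 112.6, 2L),
      sc_row("OE1", "O", "CB", "CG", "CD", 1.231, 120.8, 3L),
      sc_row("NE2", "N", "CB", "CG", "CD", 1.328, 116.4, 3L, 180)
    ),
    H = dplyr::bind_rows(
      cb_row(),
      sc_row("CG",  "C", "N", "CA", "CB", 1.497, 113.8, 1L),
      sc_row("ND1", "N", "CA", "CB", "CG", 1.378, 122.7, 2L),
      sc_row("CD2", "C", "CA", "CB", "CG", 1.354, 131.0, 2L, 180),
      sc_row("CE1", "C", "CB", "CG", "ND1", 1.321, 109.0, NA, 180),
      sc_row("NE2", "N", "CG", "ND1", "CE1", 1.321, 108.5, NA, 0)
    ),
    F = dplyr::bind_rows(
      cb_row(),
      sc_row("CG",  "C", "N", "CA", "CB", 1.502, 113.8, 1L),
      sc_row("CD1", "C", "CA", "CB", "CG", 1.389, 120.8, 2L),
      sc_row("CD2", "C", "CA", "CB", "CG", 1.389, 120.8, 2L, 180),
      sc_row("CE1", "C", "CB", "CG", "CD1", 1.382, 120.8, NA, 180),
      sc_row("CE2", "C", "CB", "CG", "CD2", 1.382, 120.8, NA, 180),
      sc_row("CZ",  "C", "CG", "CD1", "CE1", 1.378, 120.0, NA, 0)
    ),
    Y = dplyr::bind_rows(
      cb_row(),
      sc_row("CG",  "C", "N", "CA", "CB", 1.502, 113.8, 1L),
      sc_row("CD1", "C", "CA", "CB", "CG", 1.389, 120.8, 2L),
      sc_row("CD2", "C", "CA", "CB", "CG", 1.389, 120.8, 2L, 180),
      sc_row("CE1", "C", "CB", "CG", "CD1", 1.382, 121.1, NA, 180),
      sc_row("CE2", "C", "CB", "CG", "CD2", 1.382, 121.1, NA, 180),
      sc_row("CZ",  "C", "CG", "CD1", "CE1", 1.378, 119.5, NA, 0),
      sc_row("OH",  "O", "CD1", "CE1", "CZ", 1.376, 119.9, NA, 180)
    ),
    W = dplyr::bind_rows(
      cb_row(),
      sc_row("CG",  "C", "N", "CA", "CB", 1.498, 113.6, 1L),
      sc_row("CD1", "C", "CA", "CB", "CG", 1.365, 126.9, 2L),
      sc_row("CD2", "C", "CA", "CB", "CG", 1.433, 126.8, 2L, 180),
      sc_row("NE1", "N", "CB", "CG", "CD1", 1.374, 110.2, NA, 180),
      sc_row("CE2", "C", "CG", "CD1", "NE1", 1.370, 109.0, NA, 0),
      sc_row("CE3", "C", "CD1", "CG", "CD2", 1.398, 133.9, NA, 180),
      sc_row("CZ2", "C", "CD1", "NE1", "CE2", 1.394, 130.1, NA, 180),
      sc_row("CZ3", "C", "CG", "CD2", "CE3", 1.392, 118.7, NA, 180),
      sc_row("CH2", "C", "NE1", "CE2", "CZ2", 1.368, 117.5, NA, 180)
    )
  )
}

# ring-closure bonds: present in the bonded graph (clash exclusion) but
# removed from the rotation graph so torsion propagation stays acyclic
ring_closure_bonds <- function(aa) {
  switch(aa,
    P = list(c("N", "CD")),
    H = list(c("CD2", "NE2")),
    F = list(c("CE2", "CZ")),
    Y = list(c("CE2", "CZ")),
    W = list(c("CD2", "CE2"), c("CZ3", "CH2")),
    list()
  )
}

# four-atom definitions of the free chi torsions, per amino acid
chi_definitions <- function(aa) {
  defs <- list(
    S = list(c("N", "CA", "CB", "OG")),
    C = list(c("N", "CA", "CB", "SG")),
    T = list(c("N", "CA", "CB", "OG1")),
    V = list(c("N", "CA", "CB", "CG1")),
    I = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
    L = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
    M = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
             c("CB", "CG", "SD", "CE")),
    K = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
    R = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ")),
    D = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
    N = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
    E = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
    Q = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
    H = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
    F = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
    Y = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
    W = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1"))
  )
  defs[[aa]] %||% list()
}

#' Number of free side-chain torsions per amino acid
#'
#' Glycine and alanine have none; proline's ring is held in a fixed
#' endocyclic template so it contributes none either.
#'
#' @param aa One-letter amino-acid code(s).
#' @return Integer vector of chi counts.
#' @export
n_chi <- function(aa) {
  vapply(aa, function(a) {
    check_aa(a)
    length(chi_definitions(a))
  }, integer(1), USE.NAMES = FALSE)
}

# full heavy-atom complement of a residue (used by quality filters)
residue_heavy_atoms <- function(aa) {
  check_aa(aa)
  c("N", "CA", "C", "O", sidechain_templates()[[aa]]$atom)
}
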