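#' Quasi-uniform points on the unit sphere
#'
#' Deterministic golden-spiral (Fibonacci) construction used as the
#' quadrature rule for Shrake-Rupley surface integration.
#'
#' @param n Number of points (at least 12).
#' @return An `n` x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  if (n < 12) abort("need at least 12 sphere points")
  i <- seq_len(n) - 1
  z <- 1 - 2 * (i + 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- i * pi * (3 - sqrt(5))
  cbind(x = r * cos(th), y = r * sin(th), z = z)
}

#' Van der Waals radius table
#'
#' DSSP-compatible radii: backbone N 1.65, carbonyl O 1.40, carbonyl C
#' 1.76, C-alpha (and other non-carbonyl carbons) 1.87, and — under the
#' default `"dssp"` convention — a single 1.80 radius for every side-chain
#' atom, matching the constants DSSP itself uses. The `"element"`
#' convention instead assigns every atom by element (side-chain O 1.40,
#' C 1.87, S 1.85). The probe defaults to the 1.4 Angstrom water sphere of
#' the Lee-Richards definition.
#'
#' @param probe Probe radius in Angstrom.
#' @param N,O,C_carbonyl,C_other,S,SIDE Class radii in Angstrom; `SIDE` is
#'   the common side-chain radius used by the `"dssp"` convention.
#' @param convention How atoms map to classes, see [radius_class()].
#' @return A tibble with columns `radius_class`, `radius`, carrying the
#'   probe radius and convention as attributes.
#' @export
radius_table <- function(probe = 1.4, N = 1.65, O = 1.40,
                         C_carbonyl = 1.76, C_other = 1.87, S = 1.85,
                         SIDE = 1.80, convention = c("dssp", "element")) {
  convention <- match.arg(convention)
  vals <- c(N = N, O = O, C_carbonyl = C_carbonyl, C_other = C_other,
            S = S, SIDE = SIDE)
  if (any(vals <= 0) || probe < 0) abort("radii must be positive")
  out <- tibble(radius_class = names(vals), radius = unname(vals))
  attr(out, "probe") <- probe
  attr(out, "convention") <- convention
  out
}

#' Assign radius classes from atom name and element
#'
#' The class is a fixed lookup on atom name and element. Under the
#' `"dssp"` convention the four backbone atoms map to their own classes
#' (`N`, `O` — including `OXT` —, `C_carbonyl` for the carbonyl carbon,
#' `C_other` for C-alpha) and every side-chain atom maps to the common
#' `SIDE` class. Under the `"element"` convention atoms map by element,
#' with carbon split into `C_carbonyl` (backbone `"C"`) and `C_other`.
#'
#' @param atom PDB atom names.
#' @param element Element symbols.
#' @param convention `"dssp"` or `"element"`.
#' @return Character vector of radius classes.
#' @export
radius_class <- function(atom, element, convention = c("dssp", "element")) {
  convention <- match.arg(convention)
  out <- character(length(atom))
  if (convention == "dssp") {
    out[atom == "N" & element == "N"] <- "N"
    out[atom %in% c("O", "OXT") & element == "O"] <- "O"
    out[atom == "C" & element == "C"] <- "C_carbonyl"
    out[atom == "CA" & element == "C"] <- "C_other"
    side <- out == "" & element %in% c("C", "N", "O", "S")
    out[side] <- "SIDE"
  } else {
    out[element == "N"] <- "N"
    out[element == "O"] <- "O"
    out[element == "S"] <- "S"
    is_c <- element == "C"
    out[is_c] <- ifelse(atom[is_c] == "C", "C_carbonyl", "C_other")
  }
  if (any(out == "")) {
    abort(paste("no radius class for element:",
                paste(unique(element[out == ""]), collapse = ", ")))
  }
  out
}

radii_for_atoms <- function(atoms, radii) {
  conv <- attr(radii, "convention") %||% "dssp"
  cls <- radius_class(atoms$atom, atoms$element, conv)
  r <- radii$radius[match(cls, radii$radius_class)]
  if (anyNA(r)) abort("radius table does not cover all radius classes")
  r
}

#' Per-atom solvent-accessible surface area
#'
#' Shrake-Rupley quadrature of the Lee-Richards surface: each atom's
#' solvent-expanded sphere is sampled with a deterministic golden-spiral
#' point set and points inside any other expanded sphere are discarded.
#'
#' @param atoms A tibble with columns `atom`, `element`, `x`, `y`, `z`
#'   (e.g. a `peptide` or the output of [read_pdb_atoms()]).
#' @param radii Radius table, see [radius_table()].
#' @param n_points Quadrature points per atom.
#' @return The input with an added `asa` column (Angstrom^2).
#' @export
atom_asa <- function(atoms, radii = radius_table(), n_points = 960) {
  if (nrow(atoms) < 1) abort("empty structure")
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  if (any(!is.finite(xyz))) abort("non-finite coordinates")
  r <- radii_for_atoms(atoms, radii)
  asa <- cpp_atom_asa(xyz, r, attr(radii, "probe"), sphere_points(n_points),
                      seq_len(nrow(atoms)))
  out <- as_tibble(atoms)
  out$asa <- asa
  out
}

#' Per-residue solvent-accessible surface area
#'
#' Residue ASA is the sum of its atoms' ASA, computed with every atom of
#' the structure as potential occluder.
#'
#' @inheritParams atom_asa
#' @param subset Optional integer vector of residue ids (`res_id`) to
#'   report; occlusion still uses the full structure.
#' @return A tibble with one row per residue: `res_id`, `res_name`, `asa`
#'   (plus `chain` if present in the input).
#' @export
residue_asa <- function(atoms, radii = radius_table(), n_points = 960,
                        subset = NULL) {
  if (nrow(atoms) < 1) abort("empty structure")
  keep <- if (is.null(subset)) seq_len(nrow(atoms)) else which(atoms$res_id %in% subset)
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  r <- radii_for_atoms(atoms, radii)
  asa <- cpp_atom_asa(xyz, r, attr(radii, "probe"), sphere_points(n_points), keep)
  sub <- as_tibble(atoms[keep, ])
  sub$asa <- asa
  grp <- c(intersect("chain", names(sub)), "res_id", "res_name")
  dplyr::summarise(dplyr::group_by(sub, dplyr::across(dplyr::all_of(grp))),
                   asa = sum(.data$asa), .groups = "drop")
}

# fast path used by the conformational scan: ASA summed over the atoms of
# one residue, full-structure occlusion, preallocated point set
central_asa <- function(xyz, r, probe, pts, rows) {
  sum(cpp_atom_asa(xyz, r, probe, pts, rows))
}
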