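cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

unit3 <- function(v) v / sqrt(sum(v * v))

# torsion angle a-b-c-d in degrees, IUPAC sign (clockwise positive looking
# from b towards c), range [-180, 180)
torsion_angle <- function(a, b, c, d) {
  u1 <- b - a; u2 <- c - b; u3 <- d - c
  n1 <- cross3(u1, u2)
  n2 <- cross3(u2, u3)
  y <- sum(cross3(n1, n2) * unit3(u2))
  x <- sum(n1 * n2)
  wrap180(atan2(y, x) * 180 / pi)
}

bond_angle_deg <- function(a, b, c) {
  u <- unit3(a - b); v <- unit3(c - b)
  acos(pmin(1, pmax(-1, sum(u * v)))) * 180 / pi
}

#' Place an atom from an internal coordinate
#'
#' Given three previously placed reference atoms `a`, `b`, `c`, places a new
#' atom bonded to `c` at the requested bond length, bond angle (b-c-new) and
#' torsion angle (a-b-c-new, IUPAC sign convention).
#'
#' @param a,b,c Numeric 3-vectors: coordinates of the reference atoms.
#' @param length Bond length c-new in Angstrom (> 0).
#' @param angle Bond angle b-c-new in degrees, in (0, 180).
#' @param dihedral Torsion a-b-c-new in degrees.
#' @return Numeric 3-vector: coordinates of the new atom.
#' @export
place_atom <- function(a, b, c, length, angle, dihedral) {
  if (length <= 0) abort("bond length must be positive")
  if (angle <= 0 || angle >= 180) abort("bond angle must lie in (0, 180)")
  ab <- b - a
  bc <- c - b
  n <- cross3(ab, bc)
  nn <- sqrt(sum(n * n))
  if (nn < 1e-10 * sqrt(sum(ab^2) * sum(bc^2)) || nn == 0) {
    abort("degenerate frame: reference atoms are collinear")
  }
  n <- n / nn
  bch <- unit3(bc)
  m <- cross3(n, bch)
  ar <- angle * pi / 180
  dr <- dihedral * pi / 180
  d <- length * c(-cos(ar), sin(ar) * cos(dr), sin(ar) * sin(dr))
  c + d[1] * bch + d[2] * m + d[3] * n
}

new_peptide <- function(atoms, dihedrals, bonds, seq, central = NA_integer_) {
  attr(atoms, "dihedrals") <- dihedrals
  attr(atoms, "bonds") <- bonds
  attr(atoms, "seq") <- seq
  attr(atoms, "central") <- central
  class(atoms) <- c("peptide", class(tibble()))
  atoms
}

peptide_coords <- function(pep) {
  cbind(pep$x, pep$y, pep$z)
}

#' Build a peptide chain from internal coordinates
#'
#' Constructs an all-heavy-atom peptide in an arbitrary conformation by
#' sequential atom placement. Backbone torsions are set via `phi`, `psi`,
#' `omega`; side-chain torsions via `chi`. `phi[1]` does not exist (the
#' first residue is seeded directly) and `psi[n]` only orients the terminal
#' carbonyl oxygen.
#'
#' @param seq Character vector of one-letter amino-acid codes.
#' @param phi,psi Numeric vectors of backbone torsions in degrees (length
#'   equal to `length(seq)`; recycled if length 1).
#' @param omega Peptide-bond torsions in degrees, length `length(seq) - 1`
#'   (recycled if length 1). Default 180 (trans).
#' @param chi List of numeric chi vectors, one per residue; each must match
#'   that residue's chi count (see [n_chi()]). Default: all chis at 180.
#' @param params Geometry parameters, see [geometry_params()].
#' @return A `peptide` tibble with one row per atom (columns `res_id`,
#'   `res_name`, `atom`, `element`, `x`, `y`, `z`) carrying the torsion
#'   index and bonded graph as attributes.
#' @export
build_peptide <- function(seq, phi = -120, psi = 140, omega = 180,
                          chi = NULL, params = geometry_params()) {
  n <- length(seq)
  if (n < 1) abort("empty sequence")
  for (aa in seq) check_aa(aa)
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  omega <- rep_len(omega, max(n - 1L, 1L))
  if (is.null(chi)) chi <- lapply(seq, function(a) rep(180, n_chi(a)))
  if (length(chi) != n) abort("chi must have one entry per residue")
  for (i in seq_len(n)) {
    if (length(chi[[i]]) != n_chi(seq[i])) {
      abort(paste0("chi count mismatch for residue ", i, " (", seq[i], "): expected ",
                   n_chi(seq[i]), ", got ", length(chi[[i]])))
    }
  }

  templates <- sidechain_templates()
  n_atoms_est <- sum(4L + vapply(seq, function(a) nrow(templates[[a]]), integer(1)))
  xyz <- matrix(NA_real_, n_atoms_est, 3)
  atom_name <- character(n_atoms_est)
  element <- character(n_atoms_est)
  res_id <- integer(n_atoms_est)
  res_name <- character(n_atoms_est)
  bonds <- matrix(0L, 0, 2)
  k <- 0L
  idx_of <- vector("list", n)  # per-residue name -> row index

  add_atom <- function(i, name, elem, pos, bond_to) {
    k <<- k + 1L
    xyz[k, ] <<- pos
    atom_name[k] <<- name
    element[k] <<- elem
    res_id[k] <<- i
    res_name[k] <<- aa_three(seq[i])
    idx_of[[i]][[name]] <<- k
    if (!is.na(bond_to)) bonds <<- rbind(bonds, c(bond_to, k))
    k
  }
  at <- function(i, name) xyz[idx_of[[i]][[name]], ]

  for (i in seq_len(n)) {
    idx_of[[i]] <- list()
    aa <- seq[i]
    ang_nca <- if (aa == "G") params$ang_n_ca_c_gly else params$ang_n_ca_c
    if (i == 1L) {
      add_atom(1L, "N", "N", c(0, 0, 0), NA)
      add_atom(1L, "CA", "C", c(params$n_ca, 0, 0), idx_of[[1]][["N"]])
      th <- (180 - ang_nca) * pi / 180
      cpos <- at(1, "CA") + params$ca_c * c(cos(th), sin(th), 0)
      add_atom(1L, "C", "C", cpos, idx_of[[1]][["CA"]])
    } else {
      npos <- place_atom(at(i - 1, "N"), at(i - 1, "CA"), at(i - 1, "C"),
                         params$c_n, params$ang_ca_c_n, psi[i - 1])
      add_atom(i, "N", "N", npos, idx_of[[i - 1]][["C"]])
      capos <- place_atom(at(i - 1, "CA"), at(i - 1, "C"), at(i, "N"),
                          params$n_ca, params$ang_c_n_ca, omega[i - 1])
      add_atom(i, "CA", "C", capos, idx_of[[i]][["N"]])
      cpos <- place_atom(at(i - 1, "C"), at(i, "N"), at(i, "CA"),
                         params$ca_c, ang_nca, phi[i])
      add_atom(i, "C", "C", cpos, idx_of[[i]][["CA"]])
    }
    opos <- place_atom(at(i, "N"), at(i, "CA"), at(i, "C"),
                       params$c_o, params$ang_ca_c_o, wrap180(psi[i] + 180))
    add_atom(i, "O", "O", opos, idx_of[[i]][["C"]])

    tmpl <- templates[[aa]]
    if (nrow(tmpl)) {
      for (r in seq_len(nrow(tmpl))) {
        dih <- tmpl$offset[r]
        if (!is.na(tmpl$chi[r])) dih <- wrap180(chi[[i]][tmpl$chi[r]] + dih)
        pos <- place_atom(at(i, tmpl$ref_a[r]), at(i, tmpl$ref_b[r]),
                          at(i, tmpl$ref_c[r]), tmpl$length[r], tmpl$angle[r], dih)
        add_atom(i, tmpl$atom[r], tmpl$element[r], pos,
                 idx_of[[i]][[tmpl$ref_c[r]]])
      }
    }
    for (rc in ring_closure_bonds(aa)) {
      bonds <- rbind(bonds, c(idx_of[[i]][[rc[1]]], idx_of[[i]][[rc[2]]]))
    }
  }

  # ring-closure bonds are bonded (for clash exclusion) but not rotatable
  n_ring <- sum(vapply(seq, function(a) length(ring_closure_bonds(a)), integer(1)))
  rot_bonds <- bonds
  if (n_ring > 0) {
    ring_rows <- logical(nrow(bonds))
    for (i in seq_len(n)) {
      for (rc in ring_closure_bonds(seq[i])) {
        p <- c(idx_of[[i]][[rc[1]]], idx_of[[i]][[rc[2]]])
        ring_rows <- ring_rows | (bonds[, 1] == p[1] & bonds[, 2] == p[2])
      }
    }
    rot_bonds <- bonds[!ring_rows, , drop = FALSE]
  }

  dihedrals <- build_dihedral_index(seq, idx_of)
  atoms <- tibble(
    res_id = res_id[1:k], res_name = res_name[1:k],
    atom = atom_name[1:k], element = element[1:k],
    x = xyz[1:k, 1], y = xyz[1:k, 2], z = xyz[1:k, 3]
  )
  pep <- new_peptide(atoms, dihedrals, bonds, seq)
  attr(pep, "rot_bonds") <- rot_bonds
  attr(pep, "movers") <- precompute_movers(pep)
  pep
}

build_dihedral_index <- function(seq, idx_of) {
  n <- length(seq)
  rows <- list()
  add <- function(name, a, b, c, d) {
    rows[[length(rows) + 1L]] <<- tibble(name = name, a = a, b = b, c = c, d = d)
  }
  for (i in seq_len(n)) {
    if (i > 1) {
      add(paste0("phi_", i), idx_of[[i - 1]][["C"]], idx_of[[i]][["N"]],
          idx_of[[i]][["CA"]], idx_of[[i]][["C"]])
      add(paste0("omega_", i - 1), idx_of[[i - 1]][["CA"]], idx_of[[i - 1]][["C"]],
          idx_of[[i]][["N"]], idx_of[[i]][["CA"]])
    }
    if (i < n) {
      add(paste0("psi_", i), idx_of[[i]][["N"]], idx_of[[i]][["CA"]],
          idx_of[[i]][["C"]], idx_of[[i + 1]][["N"]])
    }
    defs <- chi_definitions(seq[i])
    for (j in seq_along(defs)) {
      q <- defs[[j]]
      add(paste0("chi", j, "_", i), idx_of[[i]][[q[1]]], idx_of[[i]][[q[2]]],
          idx_of[[i]][[q[3]]], idx_of[[i]][[q[4]]])
    }
  }
  dplyr::bind_rows(rows)
}

# for every named torsion, the set of atoms that move when it is rotated:
# the connected component containing atom c after deleting rotatable bond b-c
precompute_movers <- function(pep) {
  bonds <- attr(pep, "rot_bonds")
  dih <- attr(pep, "dihedrals")
  n <- nrow(pep)
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  movers <- vector("list", nrow(dih))
  for (r in seq_len(nrow(dih))) {
    b <- dih$b[r]; cc <- dih$c[r]
    seen <- logical(n)
    seen[b] <- TRUE  # wall off the b side
    stack <- cc
    seen[cc] <- TRUE
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      for (w in adj[[v]]) {
        if (!seen[w]) {
          seen[w] <- TRUE
          stack <- c(stack, w)
        }
      }
    }
    seen[b] <- FALSE
    seen[cc] <- FALSE  # on the rotation axis; rotating it is a no-op
    movers[[r]] <- which(seen)
  }
  names(movers) <- dih$name
  movers
}

#' Build a Gly-X-Gly tripeptide
#'
#' The reference construct for maximum-ASA normalization: the residue of
#' interest `aa` flanked by glycines (which occlude least). Flanking
#' residues default to the extended conformation; the peptide bonds are
#' trans (omega = 180) unless overridden.
#'
#' @param aa One-letter code of the central residue.
#' @param phi,psi Central-residue backbone torsions in degrees.
#' @param omega Peptide-bond torsion (applied to both peptide bonds).
#' @param chi Numeric vector of central-residue chi torsions; length must
#'   equal `n_chi(aa)`.
#' @param params Geometry parameters, see [geometry_params()].
#' @return A `peptide` tibble (see [build_peptide()]) whose attribute
#'   `central` is 2; torsion names `"phi"`, `"psi"`, `"chi1"`, ... resolve
#'   to the central residue.
#' @export
build_tripeptide <- function(aa, phi = -120, psi = 140, omega = 180,
                             chi = rep(180, n_chi(aa)),
                             params = geometry_params()) {
  check_aa(aa)
  pep <- build_peptide(c("G", aa, "G"),
                       phi = c(180, phi, 180), psi = c(180, psi, 180),
                       omega = omega, chi = list(numeric(), chi, numeric()),
                       params = params)
  attr(pep, "central") <- 2L
  pep
}

resolve_dihedral_name <- function(pep, name) {
  dih <- attr(pep, "dihedrals")
  if (name %in% dih$name) return(name)
  central <- attr(pep, "central")
  if (!is.na(central)) {
    alias <- paste0(name, "_", central)
    if (alias %in% dih$name) return(alias)
  }
  abort(paste0("unknown dihedral: ", name))
}

#' Torsion names defined on a peptide
#'
#' @param pep A `peptide` object.
#' @return Character vector of torsion names (`phi_i`, `psi_i`, `omega_i`,
#'   `chi<j>_i`).
#' @export
dihedral_names <- function(pep) attr(pep, "dihedrals")$name

#' Measure a named torsion angle
#'
#' @param pep A `peptide` object.
#' @param name Torsion name (see [dihedral_names()]); on a tripeptide,
#'   `"phi"`, `"psi"`, `"chi1"`, ... refer to the central residue.
#' @return Angle in degrees in \[-180, 180).
#' @export
measure_dihedral <- function(pep, name) {
  name <- resolve_dihedral_name(pep, name)
  dih <- attr(pep, "dihedrals")
  r <- match(name, dih$name)
  xyz <- peptide_coords(pep)
  torsion_angle(xyz[dih$a[r], ], xyz[dih$b[r], ], xyz[dih$c[r], ], xyz[dih$d[r], ])
}

#' Set a named torsion angle
#'
#' Rigid-body rotation of all atoms downstream of the torsion's central
#' bond; bond lengths and angles are untouched, atoms on the non-rotating
#' side do not move.
#'
#' @inheritParams measure_dihedral
#' @param value Target angle in degrees.
#' @return The modified `peptide`.
#' @export
set_dihedral <- function(pep, name, value) {
  name <- resolve_dihedral_name(pep, name)
  dih <- attr(pep, "dihedrals")
  r <- match(name, dih$name)
  xyz <- peptide_coords(pep)
  current <- torsion_angle(xyz[dih$a[r], ], xyz[dih$b[r], ], xyz[dih$c[r], ], xyz[dih$d[r], ])
  delta <- wrap180(value - current)
  if (delta == 0) return(pep)
  movers <- attr(pep, "movers")[[name]]
  axis_from <- xyz[dih$b[r], ]
  u <- unit3(xyz[dih$c[r], ] - axis_from)
  th <- delta * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  pts <- xyz[movers, , drop = FALSE]
  pts <- sweep(pts, 2, axis_from)
  pts <- pts %*% t(R)
  pts <- sweep(pts, 2, axis_from, FUN = "+")
  pep$x[movers] <- pts[, 1]
  pep$y[movers] <- pts[, 2]
  pep$z[movers] <- pts[, 3]
  pep
}
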