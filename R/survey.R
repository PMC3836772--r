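#' Flag chain-terminating residues
#'
#' The first and last residues of every chain are always flagged. In
#' addition, a residue is flagged when the peptide bond to either neighbor
#' deviates from the structure's mean peptide-bond length by more than six
#' standard deviations (with zero spread meaning no additional flags).
#' Chains shorter than three residues are flagged entirely.
#'
#' @param residues A tibble with one row per residue in chain order:
#'   columns `chain` and `bond_next` (the C(i)-N(i+1) peptide-bond length
#'   in Angstrom, `NA` for the last residue of a chain). The mean and SD
#'   are taken over all peptide bonds of the structure.
#' @param n_sd Outlier cutoff in standard deviations (default 6).
#' @return The input with an added logical column `flag_terminal`.
#' @export
flag_chain_terminators <- function(residues, n_sd = 6) {
  bonds <- residues$bond_next[!is.na(residues$bond_next)]
  mu <- mean(bonds)
  sdev <- if (length(bonds) > 1) sd(bonds) else 0
  out <- dplyr::group_modify(
    dplyr::group_by(residues, .data$chain),
    function(df, key) {
      n <- nrow(df)
      flag <- rep(FALSE, n)
      if (n < 3) {
        flag[] <- TRUE
      } else {
        flag[c(1, n)] <- TRUE
        if (sdev > 0) {
          bad <- which(!is.na(df$bond_next) &
                         abs(df$bond_next - mu) > n_sd * sdev)
          flag[bad] <- TRUE
          flag[pmin(bad + 1L, n)] <- TRUE
        }
      }
      df$flag_terminal <- flag
      df
    }
  )
  dplyr::ungroup(out)
}

#' Flag residues with missing atoms or ambiguous occupancy
#'
#' A residue is flagged when any of its atoms has occupancy different from
#' 1.0 or when any heavy atom of its template is absent; both sequence
#' neighbors of a flagged residue are flagged as well.
#'
#' @param atoms Atom table as from [read_pdb_atoms()] (columns `chain`,
#'   `res_id`, `aa`, `atom`, `occupancy`).
#' @return A tibble `chain`, `res_id`, `flag_quality` (one row per residue,
#'   in chain order).
#' @export
flag_quality <- function(atoms) {
  res <- dplyr::summarise(
    dplyr::group_by(atoms, .data$chain, .data$res_id, .data$aa),
    bad_occ = any(.data$occupancy != 1.0),
    atoms = list(.data$atom),
    .groups = "drop"
  )
  res <- dplyr::arrange(res, .data$chain, .data$res_id)
  res$incomplete <- vapply(seq_len(nrow(res)), function(i) {
    aa <- res$aa[i]
    if (is.na(aa)) return(TRUE)
    !all(residue_heavy_atoms(aa) %in% res$atoms[[i]])
  }, logical(1))
  res$self <- res$bad_occ | res$incomplete
  out <- dplyr::group_modify(
    dplyr::group_by(res, .data$chain),
    function(df, key) {
      n <- nrow(df)
      flag <- df$self
      bad <- which(df$self)
      flag[pmax(bad - 1L, 1L)] <- TRUE
      flag[pmin(bad + 1L, n)] <- TRUE
      df$flag_quality <- flag
      df
    }
  )
  dplyr::select(dplyr::ungroup(out), "chain", "res_id", "flag_quality")
}

# phi/psi and peptide-bond lengths for every residue of one structure
backbone_geometry <- function(atoms) {
  bb <- atoms[atoms$atom %in% c("N", "CA", "C"), ]
  res <- dplyr::arrange(
    dplyr::distinct(atoms, .data$chain, .data$res_id, .data$aa),
    .data$chain, .data$res_id
  )
  get_xyz <- function(chain, res_id, name) {
    i <- which(bb$chain == chain & bb$res_id == res_id & bb$atom == name)
    if (length(i) != 1) return(c(NA_real_, NA_real_, NA_real_))
    c(bb$x[i], bb$y[i], bb$z[i])
  }
  n <- nrow(res)
  phi <- psi <- bond_next <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ch <- res$chain[i]
    prev_ok <- i > 1 && res$chain[i - 1] == ch
    next_ok <- i < n && res$chain[i + 1] == ch
    Ni <- get_xyz(ch, res$res_id[i], "N")
    CAi <- get_xyz(ch, res$res_id[i], "CA")
    Ci <- get_xyz(ch, res$res_id[i], "C")
    if (prev_ok) {
      Cp <- get_xyz(ch, res$res_id[i - 1], "C")
      if (!anyNA(c(Cp, Ni, CAi, Ci))) phi[i] <- torsion_angle(Cp, Ni, CAi, Ci)
    }
    if (next_ok) {
      Nn <- get_xyz(ch, res$res_id[i + 1], "N")
      if (!anyNA(c(Ni, CAi, Ci, Nn))) {
        psi[i] <- torsion_angle(Ni, CAi, Ci, Nn)
        bond_next[i] <- sqrt(sum((Nn - Ci)^2))
      }
    }
  }
  res$phi <- phi
  res$psi <- psi
  res$bond_next <- bond_next
  res
}

#' Per-residue observations for one structure
#'
#' Runs the survey pipeline on a parsed structure: backbone torsions and
#' peptide-bond lengths, per-residue ASA (full-structure occlusion),
#' terminal and quality flags.
#'
#' @param atoms Atom table as from [read_pdb_atoms()].
#' @param structure_id Identifier recorded in the output.
#' @param radii Radius table ([radius_table()]).
#' @param n_points SASA quadrature points per atom.
#' @return An observation tibble: `structure_id`, `chain`, `res_id`, `aa`,
#'   `phi`, `psi`, `asa`, `ss` (secondary structure, `"unknown"`),
#'   `flag_terminal`, `flag_quality`, `flagged`.
#' @export
structure_observations <- function(atoms, structure_id = "structure",
                                   radii = radius_table(), n_points = 960) {
  if (!nrow(atoms)) abort("empty structure")
  geo <- backbone_geometry(atoms)
  geo <- flag_chain_terminators(geo)
  qual <- flag_quality(atoms)
  asa <- residue_asa(atoms, radii = radii, n_points = n_points)
  out <- dplyr::left_join(geo, qual, by = c("chain", "res_id"))
  out <- dplyr::left_join(out, dplyr::select(asa, "chain", "res_id", "asa"),
                          by = c("chain", "res_id"))
  tibble(
    structure_id = structure_id,
    chain = out$chain, res_id = out$res_id, aa = out$aa,
    phi = out$phi, psi = out$psi, asa = out$asa, ss = "unknown",
    flag_terminal = out$flag_terminal, flag_quality = out$flag_quality,
    flagged = out$flag_terminal | out$flag_quality
  )
}

#' Survey a directory of PDB files
#'
#' @param dir Directory containing `.pdb` files.
#' @param radii Radius table ([radius_table()]).
#' @param n_points SASA quadrature points per atom.
#' @return Row-bound observation tibble (see [structure_observations()]),
#'   one `structure_id` per file (basename without extension).
#' @export
survey_pdb_dir <- function(dir, radii = radius_table(), n_points = 960) {
  files <- sort(list.files(dir, pattern = "\\.pdb$", full.names = TRUE))
  if (!length(files)) abort(paste("no .pdb files in", dir))
  purrr::map_dfr(files, function(f) {
    structure_observations(read_pdb_atoms(f),
                           structure_id = sub("\\.pdb$", "", basename(f)),
                           radii = radii, n_points = n_points)
  })
}

#' Empirical maximum-ASA grid
#'
#' Bins unflagged observations of one amino acid by (phi, psi) and records
#' the maximum observed ASA per bin; bins without observations are absent.
#'
#' @param obs Observation tibble (see [structure_observations()]); rows
#'   with `flagged = TRUE` or missing angles are dropped. Must contain a
#'   single amino acid.
#' @param bin_width Bin width in degrees.
#' @return A `max_asa_grid` tibble: `phi`, `psi` (bin lower edges),
#'   `max_asa`, `n_obs`.
#' @export
empirical_max_grid <- function(obs, bin_width = 20) {
  obs <- obs[!obs$flagged & !is.na(obs$phi) & !is.na(obs$psi) & !is.na(obs$asa), ]
  if (!nrow(obs)) abort("no usable observations")
  if (length(unique(obs$aa)) != 1) abort("observations must be a single amino acid")
  out <- dplyr::summarise(
    dplyr::group_by(tibble(phi = bin_of(obs$phi, bin_width),
                           psi = bin_of(obs$psi, bin_width),
                           asa = obs$asa),
                    .data$phi, .data$psi),
    max_asa = max(.data$asa), n_obs = dplyr::n(), .groups = "drop"
  )
  attr(out, "aa") <- obs$aa[1]
  attr(out, "bin_width") <- bin_width
  attr(out, "step") <- bin_width
  class(out) <- c("max_asa_grid", class(tibble()))
  out
}

scale_lookup <- function(scale) {
  if (is.numeric(scale) && !is.null(names(scale))) return(scale)
  setNames(scale$max_asa, scale$aa)
}

#' Relative solvent accessibility
#'
#' `RSA = ASA / MaxASA(aa)` under a normalization scale; values above 1
#' indicate accessibilities in excess of the scale's reference maximum.
#'
#' @param asa ASA values (Angstrom^2, non-negative).
#' @param aa One-letter amino-acid code(s), recycled against `asa`.
#' @param scale A normalization scale: tibble with columns `aa`, `max_asa`
#'   (see [get_scale()]) or a named numeric vector.
#' @return Numeric vector of RSA values.
#' @export
rsa <- function(asa, aa, scale = get_scale("theoretical")) {
  lut <- scale_lookup(scale)
  aa <- rep_len(aa, length(asa))
  if (any(!aa %in% names(lut))) {
    abort(paste("amino acid missing from scale:",
                paste(setdiff(aa, names(lut)), collapse = ", ")))
  }
  if (any(asa < 0, na.rm = TRUE)) abort("asa must be non-negative")
  asa / unname(lut[aa])
}

#' Frequency of RSA values exceeding 1
#'
#' Tabulates, per amino acid and per normalization scale, the fraction of
#' unflagged observations whose RSA exceeds 1.
#'
#' @param obs Observation tibble (see [structure_observations()]).
#' @param scales Named list of normalization scales (see [rsa()]).
#' @return A tibble `scale`, `aa`, `n`, `n_gt1`, `frac_gt1`.
#' @export
rsa_exceedance <- function(obs, scales = list(
                             miller1987 = get_scale("miller1987"),
                             rose1985 = get_scale("rose1985"))) {
  obs <- obs[!obs$flagged & !is.na(obs$asa) & !is.na(obs$aa), ]
  purrr::map_dfr(names(scales), function(nm) {
    r <- rsa(obs$asa, obs$aa, scales[[nm]])
    dplyr::summarise(
      dplyr::group_by(tibble(aa = obs$aa, r = r), .data$aa),
      n = dplyr::n(), n_gt1 = sum(.data$r > 1),
      frac_gt1 = mean(.data$r > 1), .groups = "drop"
    ) |>
      dplyr::mutate(scale = nm, .before = 1)
  })
}
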