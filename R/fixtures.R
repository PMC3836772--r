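#' Simulate a synthetic PDB corpus
#'
#' Writes small single-chain PDB files with planted conformations and,
#' optionally, planted defects: an atom with ambiguous occupancy, or a
#' stretched peptide bond (the chain tail is translated away, producing a
#' bond-length outlier). A ground-truth sidecar (`truth.tsv`) records the
#' planted torsions, the per-residue ASA recomputed from the written file,
#' and which residues a correct filter must flag.
#'
#' Backbone angles are drawn per residue from the synthetic Ramachandran
#' mixture ([simulate_rama_angles()]); side-chain chis from the rotamer
#' sectors.
#'
#' @param dir Output directory (created if needed).
#' @param n_structures Number of structures to write.
#' @param n_res Residues per chain (single value or range to sample from).
#' @param seed Integer seed; the corpus is fully reproducible.
#' @param occ_defect Number of structures receiving one 0.5-occupancy atom.
#' @param bond_outlier Number of structures receiving one stretched bond.
#' @param n_points SASA quadrature points used for the ground-truth ASA.
#' @return Invisibly, the ground-truth tibble (also written to
#'   `file.path(dir, "truth.tsv")`): `structure_id`, `chain`, `res_id`,
#'   `aa`, `phi`, `psi`, `asa`, `planted_occ_defect`,
#'   `planted_bond_outlier`, `expect_flag_terminal`, `expect_flag_quality`.
#' @export
simulate_pdb_corpus <- function(dir, n_structures = 3, n_res = 10, seed = 1L,
                                occ_defect = 0, bond_outlier = 0,
                                n_points = 960) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- vector("list", n_structures)
  for (s in seq_len(n_structures)) {
    sid <- sprintf("synth%03d", s)
    st_seed <- (seed * 1009L + s) %% 2147483647L
    len <- if (length(n_res) > 1) {
      with_local_seed(st_seed, sample(min(n_res):max(n_res), 1))
    } else n_res
    gets_outlier <- s > occ_defect && s <= occ_defect + bond_outlier
    # a single outlier among n bonds has z at most ~sqrt(n); the 6-SD rule
    # can only trigger on chains with enough bonds
    if (gets_outlier) len <- max(len, 50L)
    draws <- with_local_seed(st_seed + 1L, {
      seq_aa <- sample(AA1, len, replace = TRUE)
      chis <- lapply(seq_aa, function(a) sample(chi_sectors(), n_chi(a), replace = TRUE))
      list(seq_aa = seq_aa, chis = chis)
    })
    seq_aa <- draws$seq_aa
    ang <- purrr::map_dfr(seq_along(seq_aa), function(i) {
      simulate_rama_angles(seq_aa[i], n = 1, seed = st_seed + 10L + i)
    })
    pep <- build_peptide(seq_aa, phi = ang$phi, psi = ang$psi,
                         chi = draws$chis)

    occ <- rep(1, nrow(pep))
    occ_res <- NA_integer_
    if (s <= occ_defect && len >= 4) {
      occ_res <- 2L + (s %% (len - 3L))  # interior residue
      occ[which(pep$res_id == occ_res)[1]] <- 0.5
    }
    outlier_after <- NA_integer_
    if (gets_outlier) {
      outlier_after <- 3L  # stretch bond between residues 3 and 4
      tail_rows <- pep$res_id > outlier_after
      ci <- which(pep$res_id == outlier_after & pep$atom == "C")
      ni <- which(pep$res_id == outlier_after + 1L & pep$atom == "N")
      shift <- 5 * unit3(c(pep$x[ni] - pep$x[ci], pep$y[ni] - pep$y[ci],
                           pep$z[ni] - pep$z[ci]))
      pep$x[tail_rows] <- pep$x[tail_rows] + shift[1]
      pep$y[tail_rows] <- pep$y[tail_rows] + shift[2]
      pep$z[tail_rows] <- pep$z[tail_rows] + shift[3]
    }

    path <- file.path(dir, paste0(sid, ".pdb"))
    write_pdb(pep, path, occupancy = occ)

    # ground truth from the written (coordinate-rounded) file
    atoms <- read_pdb_atoms(path)
    asa <- residue_asa(atoms, n_points = n_points)
    exp_term <- seq_len(len) %in% c(1L, len) |
      (!is.na(outlier_after) &
         seq_len(len) %in% c(outlier_after, outlier_after + 1L))
    exp_qual <- if (is.na(occ_res)) rep(FALSE, len) else
      abs(seq_len(len) - occ_res) <= 1L
    truth[[s]] <- tibble(
      structure_id = sid, chain = "A", res_id = seq_len(len), aa = seq_aa,
      phi = c(NA, ang$phi[-1]), psi = c(ang$psi[-len], NA),
      asa = asa$asa[match(seq_len(len), asa$res_id)],
      planted_occ_defect = seq_len(len) %in% occ_res,
      planted_bond_outlier = !is.na(outlier_after) &
        seq_len(len) %in% c(outlier_after, outlier_after + 1L),
      expect_flag_terminal = exp_term,
      expect_flag_quality = exp_qual
    )
  }
  truth <- dplyr::bind_rows(truth)
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(truth)
}
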