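#' Write a structure as a single-model PDB file
#'
#' Emits `ATOM` records with the fixed-column PDB v3.3 layout (occupancy
#' and B-factor columns included), followed by `TER` and `END`.
#'
#' @param atoms A tibble with columns `res_id`, `res_name`, `atom`,
#'   `element`, `x`, `y`, `z` (e.g. a `peptide`).
#' @param path Output file path.
#' @param chain Chain identifier (single character), recycled or one per atom.
#' @param occupancy Occupancy value(s), recycled over atoms.
#' @param b B-factor value(s), recycled over atoms.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(atoms, path, chain = "A", occupancy = 1, b = 0) {
  n <- nrow(atoms)
  chain <- rep_len(chain, n)
  occupancy <- rep_len(occupancy, n)
  b <- rep_len(b, n)
  name_field <- ifelse(nchar(atoms$atom) >= 4, substr(atoms$atom, 1, 4),
                       sprintf(" %-3s", atoms$atom))
  rec <- sprintf("ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 seq_len(n), name_field, atoms$res_name, chain, atoms$res_id,
                 atoms$x, atoms$y, atoms$z, occupancy, b, atoms$element)
  last <- n
  ter <- sprintf("TER   %5d      %3s %1s%4d", n + 1L, atoms$res_name[last],
                 chain[last], atoms$res_id[last])
  writeLines(c(rec, ter, "END"), path)
  invisible(path)
}

#' Read atoms from a PDB file
#'
#' Parses `ATOM` records (via bio3d); `HETATM` records and alternate
#' locations other than blank or `'A'` are skipped.
#'
#' @param path PDB file path.
#' @return A tibble with columns `chain`, `res_id`, `res_name`, `aa`
#'   (one-letter, `NA` for non-standard residues), `atom`, `element`,
#'   `x`, `y`, `z`, `occupancy`.
#' @export
read_pdb_atoms <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & (is.na(at$alt) | at$alt %in% c("", "A")), , drop = FALSE]
  element <- at$elesy
  missing_el <- is.na(element) | element == ""
  element[missing_el] <- substr(gsub("[^A-Z]", "", at$elety[missing_el]), 1, 1)
  tibble(
    chain = at$chain,
    res_id = at$resno,
    res_name = at$resid,
    aa = aa_one(at$resid),
    atom = at$elety,
    element = element,
    x = at$x, y = at$y, z = at$z,
    occupancy = at$o
  )
}
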