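#' Sector-mean chi angles
#'
#' Rotamer chi angles are grouped into three 120-degree sectors centred on
#' +60, -60 and 180 degrees. The packaged sector means are the idealized
#' sector centres themselves (gauche+, gauche-, trans); because the scan
#' takes the maximum over rotamers and ASA varies slowly with chi, the
#' derived maxima are insensitive to the exact within-sector mean.
#'
#' @return Numeric vector of the three sector means (degrees).
#' @export
chi_sectors <- function() c(60, -60, 180)

# run `expr` under a local, restorable RNG seeded deterministically
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Enumerate side-chain rotamer conformations
#'
#' All combinations of the three chi sectors are formed; when an amino acid
#' admits more than `max_rotamers` distinct combinations, a random subset of
#' `max_rotamers` is drawn without replacement (reproducibly for a fixed
#' seed). Residues without free chis return a single empty conformation.
#'
#' @param aa One-letter amino-acid code.
#' @param seed Integer seed for the subsampling.
#' @param max_rotamers Maximum number of rotamers retained (default 10).
#' @return A tibble with columns `rotamer` (index) and `chi` (list column
#'   of numeric chi vectors).
#' @export
enumerate_rotamers <- function(aa, seed = 1L, max_rotamers = 10L) {
  check_aa(aa)
  k <- n_chi(aa)
  if (k == 0L) {
    return(tibble(rotamer = 1L, chi = list(numeric())))
  }
  grids <- rep(list(chi_sectors()), k)
  combos <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  if (nrow(combos) > max_rotamers) {
    pick <- with_local_seed(seed, sort(sample.int(nrow(combos), max_rotamers)))
    combos <- combos[pick, , drop = FALSE]
  }
  tibble(rotamer = seq_len(nrow(combos)),
         chi = lapply(seq_len(nrow(combos)), function(i) unname(combos[i, ])))
}

# non-bonded atom pairs: graph distance >= 4 bonds over the bonded graph
nonbonded_pairs <- function(pep) {
  bonds <- attr(pep, "bonds")
  n <- nrow(pep)
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  # BFS to depth 3 from each atom marks the bonded (1-2, 1-3, 1-4) exclusions
  pairs <- matrix(0L, 0, 2)
  excl <- vector("list", n)
  for (s in seq_len(n)) {
    d <- rep.int(-1L, n)
    d[s] <- 0L
    frontier <- s
    for (depth in 1:3) {
      nxt <- integer(0)
      for (v in frontier) for (w in adj[[v]]) if (d[w] < 0) {
        d[w] <- depth
        nxt <- c(nxt, w)
      }
      frontier <- nxt
      if (!length(frontier)) break
    }
    near <- which(d >= 0)
    excl[[s]] <- near
  }
  for (i in seq_len(n - 1L)) {
    far <- setdiff((i + 1L):n, excl[[i]])
    if (length(far)) pairs <- rbind(pairs, cbind(i, far))
  }
  pairs
}

#' Detect steric clashes
#'
#' A conformation clashes when any pair of atoms separated by at least four
#' bonds lies closer than `tolerance` times the sum of their van der Waals
#' radii.
#'
#' @param pep A `peptide` object.
#' @param tolerance Fraction of the summed vdW radii below which two
#'   non-bonded atoms clash (default 0.5).
#' @param radii Radius table used for the vdW radii.
#' @param pairs Optional precomputed pair matrix from repeated calls.
#' @return Logical scalar.
#' @export
steric_clash <- function(pep, tolerance = 0.5, radii = radius_table(),
                         pairs = NULL) {
  if (tolerance <= 0) return(FALSE)
  if (is.null(pairs)) pairs <- nonbonded_pairs(pep)
  if (!nrow(pairs)) return(FALSE)
  xyz <- peptide_coords(pep)
  r <- radii_for_atoms(pep, radii)
  d2 <- rowSums((xyz[pairs[, 1], , drop = FALSE] - xyz[pairs[, 2], , drop = FALSE])^2)
  lim <- tolerance * (r[pairs[, 1]] + r[pairs[, 2]])
  any(d2 < lim^2)
}

#' Scan tripeptide conformations and record maximum ASA
#'
#' Builds the Gly-X-Gly tripeptide for `aa` and exhaustively steps the
#' central phi and psi over \[-180, 180) in `step`-degree increments. At
#' each grid point all enumerated rotamers are applied (resampled per grid
#' point when subsampling is needed), sterically clashing conformations are
#' discarded, and the central residue's ASA is computed; the per-grid-point
#' maximum and its argmax conformation are recorded.
#'
#' @param aa One-letter amino-acid code of the central residue.
#' @param step Grid step in degrees; must divide 360.
#' @param params Geometry parameters ([geometry_params()]).
#' @param radii Radius table ([radius_table()]).
#' @param n_points Quadrature points per atom ([sphere_points()]).
#' @param seed Integer seed controlling rotamer subsampling.
#' @param max_rotamers Rotamer budget per grid point (default 10).
#' @param clash_tolerance Clash threshold, see [steric_clash()].
#' @param omega Peptide-bond torsion (degrees), trans by default.
#' @param phi_range Optional length-2 vector restricting the scanned phi
#'   values (e.g. `c(-110, -40)` for proline).
#' @return A `max_asa_grid` tibble: one row per (phi, psi) grid point with
#'   `max_asa` (NA when every rotamer clashed), the argmax chi vector, and
#'   counts of evaluated/clashing conformations. Attributes: `aa`, `step`,
#'   `bin_width` (= step), `seed`.
#' @export
scan_max_asa <- function(aa, step = 5, params = geometry_params(),
                         radii = radius_table(), n_points = 960,
                         seed = 1L, max_rotamers = 10L,
                         clash_tolerance = 0.5, omega = 180,
                         phi_range = NULL) {
  check_aa(aa)
  if (360 %% step != 0) abort("step must divide 360")
  grid_vals <- seq(-180, 180 - step, by = step)
  phis <- grid_vals
  if (!is.null(phi_range)) phis <- phis[phis >= phi_range[1] & phis <= phi_range[2]]

  k <- n_chi(aa)
  n_combos <- if (k == 0) 1L else 3L^k
  need_sampling <- n_combos > max_rotamers
  rot0 <- enumerate_rotamers(aa, seed = seed, max_rotamers = max_rotamers)

  pep <- build_tripeptide(aa, phi = -180, psi = -180, omega = omega,
                          chi = if (k) rep(180, k) else numeric(),
                          params = params)
  pairs <- nonbonded_pairs(pep)
  r <- radii_for_atoms(pep, radii)
  probe <- attr(radii, "probe")
  pts <- sphere_points(n_points)
  central_rows <- which(pep$res_id == 2L)
  lim2 <- (0.0 + clash_tolerance * (r[pairs[, 1]] + r[pairs[, 2]]))^2
  chi_names <- if (k) paste0("chi", seq_len(k)) else character()

  res <- vector("list", length(phis) * length(grid_vals))
  ridx <- 0L
  cell <- 0L
  for (phi in phis) {
    pep <- set_dihedral(pep, "phi", phi)
    for (psi in grid_vals) {
      cell <- cell + 1L
      pep <- set_dihedral(pep, "psi", psi)
      rot <- if (need_sampling) {
        enumerate_rotamers(aa, seed = (seed * 7919L + cell) %% 2147483647L,
                           max_rotamers = max_rotamers)
      } else rot0
      best <- NA_real_
      best_chi <- list(numeric())
      n_clash <- 0L
      for (q in seq_len(nrow(rot))) {
        chis <- rot$chi[[q]]
        for (j in seq_len(k)) pep <- set_dihedral(pep, chi_names[j], chis[j])
        xyz <- cbind(pep$x, pep$y, pep$z)
        d2 <- rowSums((xyz[pairs[, 1], , drop = FALSE] -
                       xyz[pairs[, 2], , drop = FALSE])^2)
        if (any(d2 < lim2)) {
          n_clash <- n_clash + 1L
          next
        }
        asa <- sum(cpp_atom_asa(xyz, r, probe, pts, central_rows))
        if (is.na(best) || asa > best) {
          best <- asa
          best_chi <- list(chis)
        }
      }
      ridx <- ridx + 1L
      res[[ridx]] <- tibble(phi = phi, psi = psi, max_asa = best,
                            argmax_chi = best_chi,
                            n_evaluated = nrow(rot), n_clashed = n_clash)
    }
  }
  out <- dplyr::bind_rows(res[seq_len(ridx)])
  attr(out, "aa") <- aa
  attr(out, "step") <- step
  attr(out, "bin_width") <- step
  attr(out, "seed") <- seed
  class(out) <- c("max_asa_grid", class(tibble()))
  out
}

#' Maximum ASA within a Ramachandran region
#'
#' @param grid A `max_asa_grid` (from [scan_max_asa()] or
#'   [empirical_max_grid()]).
#' @param region A `rama_region` (see [define_region()]), or `NULL` for the
#'   global maximum over all grid points.
#' @return The maximum ASA (Angstrom^2) over grid points falling in the
#'   region's bins.
#' @export
max_asa_in_region <- function(grid, region = NULL) {
  vals <- grid$max_asa
  if (!is.null(region)) {
    bw <- attr(region, "bin_width")
    key <- paste(bin_of(grid$phi, bw), bin_of(grid$psi, bw))
    keep <- key %in% paste(region$phi_bin, region$psi_bin)
    if (!any(keep)) abort("region does not intersect the grid")
    vals <- vals[keep]
  }
  if (all(is.na(vals))) abort("no non-clashing conformation in region")
  max(vals, na.rm = TRUE)
}
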