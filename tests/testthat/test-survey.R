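mk_chain <- function(n, bond = 1.33, chain = "A") {
  tibble::tibble(chain = chain, res_id = seq_len(n),
                 bond_next = c(rep(bond, n - 1), NA))
}

test_that("chain terminators are flagged from peptide-bond statistics", {
  # uniform bonds: zero spread, only the chain ends are flagged
  u <- flag_chain_terminators(mk_chain(10))
  expect_identical(which(u$flag_terminal), c(1L, 10L))

  # one 10 A bond among 100 of 1.33 A: hand-computed mean/SD flag its
  # two adjoining residues
  ch <- mk_chain(101)
  ch$bond_next[50] <- 10
  bonds <- ch$bond_next[!is.na(ch$bond_next)]
  z <- abs(10 - mean(bonds)) / sd(bonds)
  expect_gt(z, 6)  # oracle: the planted bond is a 6-sigma outlier
  f <- flag_chain_terminators(ch)
  expect_identical(which(f$flag_terminal), c(1L, 50L, 51L, 101L))

  # 3-residue chain: middle residue survives
  f3 <- flag_chain_terminators(mk_chain(3))
  expect_identical(f3$flag_terminal, c(TRUE, FALSE, TRUE))

  # too-short chain: everything flagged
  f2 <- flag_chain_terminators(mk_chain(2))
  expect_true(all(f2$flag_terminal))
})

test_that("quality flags cover defective residues and their neighbours", {
  pep <- build_peptide(c("A", "A", "A", "A", "A"), phi = -60, psi = -45)
  atoms <- tibble::as_tibble(pep)
  atoms$chain <- "A"
  atoms$aa <- "A"
  atoms$occupancy <- 1

  clean <- flag_quality(atoms)
  expect_false(any(clean$flag_quality))

  # ambiguous occupancy on residue 3 flags 2, 3, 4
  occ <- atoms
  occ$occupancy[which(occ$res_id == 3)[1]] <- 0.5
  f <- flag_quality(occ)
  expect_identical(f$res_id[f$flag_quality], c(2L, 3L, 4L))

  # missing CB on residue 4 flags 3, 4, 5
  mis <- atoms[!(atoms$res_id == 4 & atoms$atom == "CB"), ]
  f2 <- flag_quality(mis)
  expect_identical(f2$res_id[f2$flag_quality], c(3L, 4L, 5L))
})

test_that("region definitions follow the coverage thresholds", {
  one <- tibble::tibble(phi_bin = -80, psi_bin = -60, n = 50L)
  attr(one, "bin_width") <- 20
  r <- define_region(one, "CORE", coverage = 0.8)
  expect_identical(nrow(r), 1L)

  # uniform counts: any included bin forces all of them (ceiling behaviour)
  unif <- tibble::tibble(phi_bin = seq(-180, by = 20, length.out = 10),
                         psi_bin = rep(-60, 10), n = rep(7L, 10))
  attr(unif, "bin_width") <- 20
  r97 <- define_region(unif, "ALLOWED", coverage = 0.97)
  expect_identical(nrow(r97), 10L)

  # coverage 1 includes every non-empty bin
  skew <- tibble::tibble(phi_bin = c(-80, -60, 100), psi_bin = c(-60, -40, 160),
                         n = c(100L, 10L, 1L))
  attr(skew, "bin_width") <- 20
  expect_identical(nrow(define_region(skew, "ALLOWED", coverage = 1)), 3L)
  expect_identical(nrow(define_region(skew, "ALL")), 3L)
  # 80% coverage keeps only the dominant bin (100/111 > 0.8)
  expect_identical(nrow(define_region(skew, "CORE")), 1L)

  expect_error(define_region(skew, "CORE", coverage = 0), "coverage")

  # GENEROUS dilates ALLOWED by one bin in the four torus directions
  g <- define_region(one, "GENEROUS", extension = 20)
  expect_identical(nrow(g), 5L)
  expect_true(all(paste(r$phi_bin, r$psi_bin) %in% paste(g$phi_bin, g$psi_bin)))
})

test_that("region nesting holds on simulated corpora", {
  for (seed in 1:10) {
    aa <- sample(amino_acids(), 1)
    rc <- simulate_rama_counts(aa, n = 3000, seed = seed)
    core <- define_region(rc, "CORE")
    allowed <- define_region(rc, "ALLOWED")
    generous <- define_region(rc, "GENEROUS")
    all_r <- define_region(rc, "ALL")
    key <- function(r) paste(r$phi_bin, r$psi_bin)
    expect_true(all(key(core) %in% key(allowed)))
    expect_true(all(key(allowed) %in% key(generous)))
    expect_true(all(key(allowed) %in% key(all_r)))
  }
})

test_that("empirical grids recover planted per-bin maxima exactly", {
  obs1 <- tibble::tibble(aa = "A", phi = -61, psi = -42, asa = 88,
                         flagged = FALSE)
  g1 <- empirical_max_grid(obs1)
  expect_identical(nrow(g1), 1L)
  expect_identical(g1$max_asa, 88)
  expect_identical(c(g1$phi, g1$psi), c(-80, -60))  # bin lower edges

  obs2 <- dplyr::bind_rows(obs1, dplyr::mutate(obs1, asa = 120))
  g2 <- empirical_max_grid(obs2)
  expect_identical(g2$max_asa, 120)

  # synthetic corpus with ground truth
  dir <- withr::local_tempdir()
  truth <- simulate_pdb_corpus(dir, n_structures = 4, n_res = c(8, 12),
                               seed = 7, occ_defect = 1, bond_outlier = 1,
                               n_points = 240)
  obs <- survey_pdb_dir(dir, n_points = 240)
  j <- dplyr::inner_join(obs, truth, by = c("structure_id", "chain", "res_id"),
                         suffix = c("", ".t"))
  expect_identical(nrow(j), nrow(truth))
  expect_identical(j$flag_terminal, j$expect_flag_terminal)
  expect_identical(j$flag_quality, j$expect_flag_quality)
  expect_lt(max(abs(j$asa - j$asa.t)), 1e-9)
  expect_lt(max(abs(j$phi - j$phi.t), na.rm = TRUE), 0.15)  # file rounding

  aa0 <- names(which.max(table(j$aa[!j$flagged])))
  g <- empirical_max_grid(obs[obs$aa == aa0, ])
  tru <- j[!j$flagged & j$aa == aa0 & !is.na(j$phi) & !is.na(j$psi), ]
  tg <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(phi = bin_of(tru$phi, 20),
                                   psi = bin_of(tru$psi, 20), asa = tru$asa.t),
                    phi, psi),
    want = max(asa), .groups = "drop"
  )
  m <- dplyr::inner_join(tidy(g), tg, by = c("phi", "psi"))
  expect_identical(nrow(m), nrow(tg))
  expect_lt(max(abs(m$max_asa - m$want)), 1e-9)

  # pipeline determinism: identical corpus, identical report
  obs_again <- survey_pdb_dir(dir, n_points = 240)
  expect_identical(obs, obs_again)
})

test_that("RSA normalizes ASA and flags exceedance", {
  sc <- get_scale("miller1987")
  expect_identical(rsa(113, "A", sc), 1)
  expect_identical(rsa(0, "A", sc), 0)
  expect_equal(rsa(135.6, "A", sc), 1.2, tolerance = 1e-12)
  expect_error(rsa(10, "Z", sc), "missing from scale")
  expect_error(rsa(-1, "A", sc), "non-negative")

  # planted exceedance fractions recovered exactly
  obs <- tibble::tibble(
    aa = rep(c("A", "G", "V"), each = 10),
    asa = c(rep(120, 3), rep(50, 7),    # A: 3/10 above Miller's 113
            rep(90, 5), rep(10, 5),     # G: 5/10 above 85
            rep(200, 1), rep(100, 9)),  # V: 1/10 above 160
    flagged = FALSE
  )
  ex <- rsa_exceedance(obs, scales = list(miller1987 = get_scale("miller1987")))
  expect_equal(ex$frac_gt1[match(c("A", "G", "V"), ex$aa)],
               c(0.3, 0.5, 0.1))

  # all-zero ASA: no exceedance anywhere
  zero <- dplyr::mutate(obs, asa = 0)
  expect_true(all(rsa_exceedance(zero)$frac_gt1 == 0))

  # halving the scale can only increase exceedance
  half <- dplyr::mutate(get_scale("miller1987"), max_asa = max_asa / 2)
  ex2 <- rsa_exceedance(obs, scales = list(half = half))
  expect_true(all(ex2$frac_gt1 >= ex$frac_gt1))
})
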