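test_that("atom placement satisfies the requested internal coordinate", {
  a <- c(0, 0, 0); b <- c(0, 0, 1); c3 <- c(0, 1, 1)
  # orthogonal frame: cis (0 deg) puts the new atom on the same side as a
  expect_equal(place_atom(a, b, c3, 1, 90, 0), c(0, 1, 0), tolerance = 1e-12)
  expect_equal(place_atom(a, b, c3, 1, 90, 180), c(0, 1, 2), tolerance = 1e-12)

  set.seed(42)
  for (i in 1:300) {
    aa <- rnorm(3); bb <- aa + rnorm(3); cc <- bb + rnorm(3)
    L <- runif(1, 0.8, 2.5); ang <- runif(1, 15, 165); dih <- runif(1, -180, 179)
    p <- place_atom(aa, bb, cc, L, ang, dih)
    expect_lt(abs(o_dist(p, cc) - L), 1e-6)
    expect_lt(abs(o_angle(bb, cc, p) - ang), 1e-6)
    expect_lt(deg_diff(o_dihedral(aa, bb, cc, p), dih), 1e-6)
  }

  expect_error(place_atom(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2), 1, 90, 0),
               "collinear")
  expect_error(place_atom(a, b, c3, -1, 90, 0), "positive")
})

test_that("building then measuring returns the requested torsions", {
  set.seed(7)
  for (i in 1:1000) {
    aa <- sample(amino_acids(), 1)
    phi <- runif(1, -180, 179); psi <- runif(1, -180, 179)
    chi <- random_chi(aa)
    pep <- build_tripeptide(aa, phi = phi, psi = psi, chi = chi)
    expect_lt(deg_diff(measure_dihedral(pep, "phi"), phi), 1e-4)
    expect_lt(deg_diff(measure_dihedral(pep, "psi"), psi), 1e-4)
    for (j in seq_along(chi)) {
      expect_lt(deg_diff(measure_dihedral(pep, paste0("chi", j)), chi[j]), 1e-4)
    }
  }
})

test_that("tripeptide topology is correct", {
  g <- build_tripeptide("G", phi = -180, psi = -180)
  expect_identical(sum(g$res_id == 2), 4L)  # N, CA, C, O
  expect_lt(deg_diff(measure_dihedral(g, "phi"), -180), 1e-6)

  a <- build_tripeptide("A", phi = -57, psi = -47)
  expect_identical(sum(a$res_id == 2), 5L)  # + CB
  expect_setequal(a$atom[a$res_id == 2], c("N", "CA", "C", "O", "CB"))

  s <- build_tripeptide("S", chi = 60)
  og <- measure_dihedral(s, "chi1")
  expect_lt(deg_diff(og, 60), 1e-6)
  # same torsion recomputed from raw coordinates with the oracle
  expect_lt(deg_diff(o_dihedral(xyz_of(s, 2, "N"), xyz_of(s, 2, "CA"),
                                xyz_of(s, 2, "CB"), xyz_of(s, 2, "OG")), 60),
            1e-6)

  expect_error(build_tripeptide("B"), "unknown amino acid")
  expect_error(build_tripeptide("S", chi = c(60, 60)), "chi count")
  expect_error(measure_dihedral(s, "chi9"), "unknown dihedral")

  # peptide bonds at the parameterised length
  for (pr in list(c(1, 2), c(2, 3))) {
    d <- o_dist(xyz_of(s, pr[1], "C"), xyz_of(s, pr[2], "N"))
    expect_lt(abs(d - 1.329), 0.05)
  }
})

test_that("setting a torsion is a rigid rotation of one side only", {
  pep <- build_tripeptide("L", phi = -70, psi = 120, chi = c(-60, 170))

  # identity rotation leaves coordinates untouched
  same <- set_dihedral(pep, "phi", measure_dihedral(pep, "phi"))
  expect_equal(same$x, pep$x, tolerance = 1e-12)

  # inverse rotation recovers the original coordinates
  psi0 <- measure_dihedral(pep, "psi")
  back <- set_dihedral(set_dihedral(pep, "psi", 180), "psi", psi0)
  expect_lt(max(abs(back$x - pep$x), abs(back$y - pep$y), abs(back$z - pep$z)),
            1e-6)

  set.seed(11)
  bp <- bonded_pairs(pep)
  before <- sapply(seq_len(nrow(bp)), function(r) {
    o_dist(c(pep$x[bp[r, 1]], pep$y[bp[r, 1]], pep$z[bp[r, 1]]),
           c(pep$x[bp[r, 2]], pep$y[bp[r, 2]], pep$z[bp[r, 2]]))
  })
  cur <- pep
  for (i in 1:25) {
    nm <- sample(c("phi", "psi", "chi1", "chi2", "omega_1"), 1)
    cur <- set_dihedral(cur, nm, runif(1, -180, 179))
    after <- sapply(seq_len(nrow(bp)), function(r) {
      o_dist(c(cur$x[bp[r, 1]], cur$y[bp[r, 1]], cur$z[bp[r, 1]]),
             c(cur$x[bp[r, 2]], cur$y[bp[r, 2]], cur$z[bp[r, 2]]))
    })
    expect_lt(max(abs(after - before)), 1e-6)
  }

  # atoms on the non-rotating side of chi1 (whole backbone) stay put
  rot <- set_dihedral(pep, "chi1", 55)
  fixed <- which(pep$res_id != 2 | pep$atom %in% c("N", "CA", "C", "O", "CB"))
  expect_equal(rot$x[fixed], pep$x[fixed], tolerance = 1e-12)
  expect_error(set_dihedral(pep, "zeta", 0), "unknown dihedral")
})

test_that("non-glycine residues are built L-configured", {
  set.seed(3)
  for (aa in setdiff(amino_acids(), "G")) {
    pep <- build_tripeptide(aa, phi = runif(1, -180, 179),
                            psi = runif(1, -180, 179), chi = random_chi(aa))
    improper <- o_dihedral(xyz_of(pep, 2, "N"), xyz_of(pep, 2, "CA"),
                           xyz_of(pep, 2, "C"), xyz_of(pep, 2, "CB"))
    expect_true(improper > -150 && improper < -90, label = aa)
  }
})

test_that("measured backbone torsions agree with bio3d", {
  set.seed(19)
  path <- tempfile(fileext = ".pdb")
  for (i in 1:5) {
    aa <- sample(amino_acids(), 1)
    phi <- runif(1, -175, 175); psi <- runif(1, -175, 175)
    pep <- build_tripeptide(aa, phi = phi, psi = psi, chi = random_chi(aa))
    write_pdb(pep, path)
    tor <- bio3d::torsion.pdb(bio3d::read.pdb(path, verbose = FALSE))
    # central residue is the second entry
    expect_lt(deg_diff(tor$phi[2], phi), 0.1)
    expect_lt(deg_diff(tor$psi[2], psi), 0.1)
  }
})
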