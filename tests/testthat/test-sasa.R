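test_that("golden-spiral sphere points are quasi-uniform unit vectors", {
  for (n in c(12, 100, 960)) {
    p <- sphere_points(n)
    expect_equal(nrow(p), n)
    expect_lt(max(abs(sqrt(rowSums(p^2)) - 1)), 1e-12)
  }
  expect_lt(sqrt(sum(colMeans(sphere_points(100))^2)), 0.05)
  expect_error(sphere_points(11), "at least 12")

  # frozen regression: nearest-neighbour spacing CV at n = 960
  p <- sphere_points(960)
  d <- as.matrix(dist(p)); diag(d) <- Inf
  nn <- apply(d, 1, min)
  cv <- sd(nn) / mean(nn)
  expect_lt(cv, 0.2)
  expect_equal(cv, 0.0109, tolerance = 0.01)
})

test_that("isolated and pairwise sphere areas match closed forms", {
  one <- mk_atoms(matrix(0, 1, 3))
  asa1 <- atom_asa(one, n_points = 960)$asa
  expect_lt(abs(asa1 - 4 * pi * 2.8^2) / (4 * pi * 2.8^2), 0.005)

  # far apart: no occlusion
  far <- mk_atoms(rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_equal(atom_asa(far, n_points = 960)$asa, rep(asa1, 2),
               tolerance = 1e-10)

  # two spheres radius 1.8, probe 1.4, centres 2.0 apart: spherical caps
  rt <- radius_table(O = 1.8, convention = "element")
  two <- mk_atoms(rbind(c(0, 0, 0), c(2, 0, 0)))
  got <- atom_asa(two, radii = rt, n_points = 3840)$asa
  want <- o_two_sphere_exposed(3.2, 3.2, 2)
  expect_lt(max(abs(got - want)) / want, 0.005)

  # unequal radii via different elements
  rt2 <- radius_table(N = 1.65, S = 1.85, convention = "element")
  two2 <- mk_atoms(rbind(c(0, 0, 0), c(2.2, 0, 0)),
                   atom = c("N", "S"), element = c("N", "S"))
  got2 <- atom_asa(two2, radii = rt2, n_points = 3840)$asa
  expect_lt(abs(got2[1] - o_two_sphere_exposed(3.05, 3.25, 2.2)) /
              got2[1], 0.005)
  expect_lt(abs(got2[2] - o_two_sphere_exposed(3.25, 3.05, 2.2)) /
              got2[2], 0.005)

  expect_error(atom_asa(mk_atoms(rbind(c(0, 0, 0), c(0, 0, 0)))),
               "coincident")
})

test_that("adding an occluder never increases any other atom's ASA", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(3:7, 1)
    xyz <- matrix(runif(3 * n, 0, 6), n, 3)
    base <- try(atom_asa(mk_atoms(xyz), n_points = 240)$asa, silent = TRUE)
    if (inherits(base, "try-error")) next  # coincident draw
    extra <- rbind(xyz, runif(3, 0, 6))
    grown <- try(atom_asa(mk_atoms(extra), n_points = 240)$asa, silent = TRUE)
    if (inherits(grown, "try-error")) next
    expect_true(all(grown[seq_len(n)] <= base + 1e-9))
  }
})

test_that("quadrature converges and areas are rigid-motion invariant", {
  pep <- build_tripeptide("T", phi = -63, psi = -43, chi = 60)
  a960 <- residue_asa(pep, n_points = 960)$asa
  a3840 <- residue_asa(pep, n_points = 3840)$asa
  expect_lt(max(abs(a3840 - a960)), 1)

  # translation: exactly invariant
  shifted <- pep
  shifted$x <- shifted$x + 123.4
  shifted$y <- shifted$y - 98.7
  shifted$z <- shifted$z + 5.5
  expect_equal(residue_asa(shifted, n_points = 960)$asa, a960,
               tolerance = 1e-9)

  # rotation: invariant to within quadrature resolution (the point set has
  # a fixed orientation, so exactness is not expected)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- cbind(pep$x, pep$y, pep$z) %*% R
  rot <- pep
  rot$x <- xyz[, 1]; rot$y <- xyz[, 2]; rot$z <- xyz[, 3]
  expect_lt(max(abs(residue_asa(rot, n_points = 3840)$asa - a3840)), 0.5)
})

test_that("residue ASA is consistent and occlusion-monotone", {
  pep <- build_tripeptide("A", phi = -63, psi = -43)
  central_in_context <- residue_asa(pep, subset = 2)
  alone <- pep[pep$res_id == 2, ]
  isolated <- residue_asa(alone)
  expect_lt(central_in_context$asa, isolated$asa)
  expect_equal(isolated$asa, sum(atom_asa(alone)$asa), tolerance = 1e-9)
  expect_error(residue_asa(pep[0, ]), "empty")
})

test_that("central-residue ASA agrees with an independent implementation", {
  py <- Sys.which("python")
  expect_true(nzchar(py))
  set.seed(23)
  dir <- withr::local_tempdir()
  cases <- list()
  for (i in 1:20) {
    aa <- sample(amino_acids(), 1)
    pep <- build_tripeptide(aa, phi = runif(1, -170, 170),
                            psi = runif(1, -170, 170), chi = random_chi(aa))
    f <- file.path(dir, sprintf("case%02d.pdb", i))
    write_pdb(pep, f)
    cases[[i]] <- residue_asa(pep, n_points = 3840, subset = 2)$asa
  }
  script <- file.path(dir, "oracle.py")
  writeLines(c(
    "import sys, glob, numpy as np",
    "import biotite.structure as struc",
    "import biotite.structure.io.pdb as pdbio",
    "bb = {'N':1.65,'O':1.40,'C':1.76,'CA':1.87,'OXT':1.40}",
    "for f in sorted(glob.glob(sys.argv[1] + '/case*.pdb')):",
    "    arr = pdbio.PDBFile.read(f).get_structure(model=1)",
    "    vdw = np.array([bb.get(n, 1.80) for n in arr.atom_name])",
    "    s = struc.sasa(arr, probe_radius=1.4, point_number=3840, vdw_radii=vdw)",
    "    print(float(s[arr.res_id == 2].sum()))"
  ), script)
  out <- system2(py, c(script, dir), stdout = TRUE)
  ref <- as.numeric(out)
  expect_length(ref, 20)
  expect_lt(max(abs(unlist(cases) - ref)), 2)
})
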