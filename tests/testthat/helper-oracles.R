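# Independent vector-algebra oracles (deliberately different formulations
# from the package internals).

o_dist <- function(a, b) sqrt(sum((a - b)^2))

o_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  acos(sum(u * v) / (o_dist(a, b) * o_dist(c, b))) * 180 / pi
}

# torsion via projection onto the plane normal to the central bond;
# IUPAC sign: positive clockwise viewed from b towards c
o_dihedral <- function(a, b, c, d) {
  u <- (c - b) / o_dist(c, b)
  v1 <- (a - b) - sum((a - b) * u) * u
  v2 <- (d - c) - sum((d - c) * u) * u
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  s <- sum(cr * u)
  if (s < 0) -ang else ang
}

deg_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

# analytic exposed area of sphere 1 (solvent-expanded radius R1) occluded
# by an intersecting sphere 2 (R2) at centre distance d
o_two_sphere_exposed <- function(R1, R2, d) {
  stopifnot(d < R1 + R2, d > abs(R1 - R2))
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  4 * pi * R1^2 - 2 * pi * R1 * h1
}

# bare atoms for SASA tests
mk_atoms <- function(xyz, atom = "O", element = "O") {
  n <- nrow(xyz)
  tibble::tibble(res_id = seq_len(n), res_name = "XXX",
                 atom = rep_len(atom, n), element = rep_len(element, n),
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

xyz_of <- function(pep, rid, name) {
  i <- which(pep$res_id == rid & pep$atom == name)
  c(pep$x[i], pep$y[i], pep$z[i])
}

# all bonded pairs of a peptide as an index matrix
bonded_pairs <- function(pep) attr(pep, "bonds")

random_chi <- function(aa) stats::runif(n_chi(aa), -180, 179)
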