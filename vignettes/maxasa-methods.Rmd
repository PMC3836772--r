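---
title: "Deriving maximum-ASA normalization scales: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving maximum-ASA normalization scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Relative solvent accessibility (RSA) normalizes a residue's accessible
surface area (ASA, in Å²) by a per-amino-acid reference maximum:
RSA = ASA / MaxASA(aa). Classic normalization constants were derived from
Gly-X-Gly tripeptides held in a single backbone conformation (extended, or
an average conformation), and real crystal structures routinely contain
residues whose ASA exceeds those constants — RSA "greater than one". A
tight upper bound requires searching over all biophysically plausible
backbone and side-chain conformations of the tripeptide and taking the
maximum ASA.

`maxasa` implements that search end to end:

1. **geometry** — all-heavy-atom Gly-X-Gly construction from internal
   coordinates (NeRF atom placement), with exact torsion get/set;
2. **sasa** — Lee–Richards ASA by Shrake–Rupley quadrature with
   DSSP-compatible radii (Rcpp kernel);
3. **scan** — exhaustive φ/ψ grids crossed with χ-sector rotamers,
   recording per-grid-point maxima;
4. **survey** — an empirical pipeline that mines PDB files, applies
   quality filters, bins by (φ, ψ) and defines Ramachandran regions;
5. **normtables** — the published constants and comparison arithmetic;
6. **hydro** — burial-based hydrophobicity scales and their correlation
   with experimental transfer-energy scales.

## Peptide construction

Atoms are placed sequentially by the standard internal-coordinate rule:
given three placed reference atoms, a new atom is positioned at a bond
length, bond angle and torsion (IUPAC sign convention, angles stored in
[−180°, 180°)). Backbone geometry defaults to Engh & Huber-style values
(`geometry_params()`): N–CA 1.458 Å, CA–C 1.525 Å, C–O 1.231 Å, C–N
1.329 Å; τ(N–CA–C) 111.2° (112.5° for Gly). These standard values replace
corpus-averaged means for reproducibility without a private structure set;
the survey module can regenerate means from any corpus, and the derived
maxima are robust to small geometry changes. Cβ is placed through the
improper torsion N–C–CA–Cβ = 122.68°, which fixes the L-configuration
(the N–CA–C–Cβ improper measures ≈ −122.7°). Hydrogens are never placed
(heavy-atom convention); peptide bonds are trans (ω = 180°) by default and
configurable; no cis-peptide or energy refinement is attempted.

Torsion changes (`set_dihedral()`) are rigid rotations of the component on
the far side of the torsion's central bond, so bond lengths and angles are
exactly preserved. Two special cases:

* **Proline.** The pyrrolidine ring is built from a fixed endocyclic
  template (ring torsions +22°/−25°, giving an N–CD closure of 1.47 Å at
  φ = −65°). The N–CD closure bond is part of the bonded graph (so the
  clash filter treats the pair as bonded) but is removed from the rotation
  graph; rotating φ therefore distorts the closure distance away from the
  template φ — a deliberate approximation that mirrors the physical fact
  that the ring constrains φ. A `phi_range = c(-110, -40)` argument
  restricts the scan to the physically meaningful band when desired.
* **Aromatic rings** (His, Phe, Tyr, Trp) are closed approximately by
  fixed planar internal coordinates; closure bond lengths come out within
  ~0.04 Å of ideal.

## ASA computation

ASA follows the Lee–Richards definition: the area traced by the centre of
a 1.4 Å probe rolled over the heavy atoms. Numerically we use
Shrake–Rupley quadrature with a deterministic golden-spiral point set
(default 960 points per atom; no RNG), implemented in C++. Quadrature
accuracy: an isolated sphere is exact to < 0.5%, a two-sphere system
matches the analytic spherical-cap formula to < 0.5%, and 960 vs 3840
points differ by < 1 Å² on tripeptides. Because the point set has a fixed
orientation, ASA is exactly translation-invariant but rotation-invariant
only to within quadrature resolution (~0.3 Å² at 3840 points) — the
relevant comparisons (maxima over conformations built in a common frame)
are unaffected.

Radii are DSSP-compatible and configurable via `radius_table()`. The
default `"dssp"` convention matches the constants DSSP itself uses:
backbone N 1.65, carbonyl O 1.40, carbonyl C 1.76, Cα 1.87, and a single
1.80 Å radius for **every** side-chain atom. An alternative `"element"`
convention (side-chain O 1.40, C 1.87, S 1.85) is provided; note it is
*not* what DSSP does, and scales derived with it are not comparable to
DSSP-referenced constants. This choice matters: serine's Oγ at 1.40 vs
1.80 Å shifts its maximum ASA by several Å².

## The conformational scan

`scan_max_asa()` steps the central residue's φ and ψ over [−180°, 180°)
on a regular grid (default 5°; 1° available) with flanking glycines held
extended. At each grid point every rotamer from `enumerate_rotamers()` is
applied: each χ is assigned to one of three 120° sectors (gauche+,
gauche−, trans). The packaged sector values are the idealized sector
centres (+60°, −60°, 180°) — a rotamer-library snapshot was not
reproducible offline, and because the scan maximizes over rotamers and ASA
varies slowly with χ, maxima are insensitive to the within-sector mean.
When an amino acid admits more than ten sector combinations (3, 4-χ side
chains), ten are drawn without replacement, re-drawn per grid point from a
deterministic per-cell seed, so a fixed seed reproduces the scan exactly.

Conformations are generated first and filtered afterwards: a conformation
is discarded when any pair of atoms at least four bonds apart sits closer
than `tolerance × (r_i + r_j)` with tolerance 0.5 — a deliberately
permissive threshold (the source method does not define "sterically
possible") that removes only severe overlap, e.g. the forbidden core
around φ = ψ = 0 where flanking carbonyl and amide atoms interpenetrate.
Grid cells where every rotamer clashes store `NA`. Ties in the per-cell
argmax resolve by evaluation order (φ, then ψ, then rotamer index).

The default 5° step is a deliberate scale-down of the 1° protocol: the
maximum varies slowly with φ/ψ (neighbouring-cell maxima differ by well
under 15 Å², and 5° vs 2° glycine scans agree within 1.5 Å²), while the
cost drops 25-fold — a 5° scan of one amino acid takes tens of seconds.

## Ramachandran regions and the reported constants

Published constants are quoted for the ALLOWED Ramachandran region, so a
region definition is needed to turn a grid into a scalar. Regions follow
the Morris et al. convention on 20° bins: CORE = most-populated bins
covering ≥ 80% of observations, ALLOWED ≥ 97%, GENEROUS = ALLOWED dilated
by 20° in the four torus directions, ALL = every non-empty bin. The
inclusion threshold is the largest per-bin count whose bins reach the
coverage, so CORE ⊆ ALLOWED ⊆ GENEROUS by construction. (Where the source
texts disagree on whether GENEROUS extends CORE or ALLOWED, we follow the
methods-level definition: ALLOWED.)

The reference bin counts shipped with the package
(`rama_reference_counts()`,
`inst/extdata/rama_reference_counts_synthetic.tsv`) are **synthetic**: a
structure corpus is not available offline, so counts are sampled (n =
20,000 per amino acid, fixed seed) from a Gaussian-mixture Ramachandran
model — α-helix (−63°, −43°), β/extended (−120°, 135°), polyproline-II
(−65°, 145°) and a minor left-handed-α basin (60°, 45°); glycine uses the
symmetrized basin set, proline a narrow φ band with two ψ modes. Basin
locations, widths and weights were fixed a priori at textbook values.
Consequences worth being explicit about: real backbone-angle
distributions have heavier tails and amino-acid-specific structure the
mixture lacks, so region *boundaries* — and therefore the ALLOWED-region
maxima, which are typically attained at a basin fringe — inherit a few Å²
of uncertainty from this stand-in. Against the published ALLOWED-region
constants our 5° scans give Ser within 1 Å², Ala ~3 Å² high and Gly ~5 Å²
high, while the unrestricted (ALL-region) maxima sit 5–10 Å² above the
published ALLOWED values, matching the 10–15 Å² ALLOWED→ALL gap the
original analysis reports. Passing fixture tests therefore demonstrate the
machinery is correct; they do not certify the synthetic region boundaries
as substitutes for corpus-derived ones.

## Empirical survey

`survey_pdb_dir()` parses PDB v3.3 `ATOM` records (HETATM and altloc ≠
'A' skipped), computes φ/ψ with the same torsion convention as the
builder, and applies the quality filters: (i) chain terminators — first
and last residue of every chain, plus any residue whose peptide bond
deviates from the structure mean by more than six standard deviations
(zero spread ⇒ no extra flags; chains under three residues are dropped
entirely); note a single outlier bond among n bonds has z ≈ √n, so the
6-SD rule can only fire on chains with ≈ 37+ bonds; (ii) completeness and
occupancy — any missing template heavy atom or any occupancy ≠ 1.00
(exactly as printed in columns 55–60) flags the residue and both sequence
neighbours. Secondary structure is recorded as `"unknown"`; nothing
downstream uses it. Flagged residues are excluded from every statistic.
`simulate_pdb_corpus()` generates fully synthetic corpora with planted
conformations, occupancy defects and bond outliers plus a ground-truth
sidecar, and the test suite verifies exact recovery of flags, per-bin
maxima and exceedance fractions.

## Hydrophobicity scales

From unflagged observations the package derives: mean-RSA scales (score
= 1 − mean RSA; the sign/offset is immaterial because every reported
statistic is an absolute Pearson correlation, which is invariant under
affine transforms — a property the tests assert); fraction 100% buried
(ASA exactly 0 Å², the only reading consistent with "100% buried"); and
fraction 95% buried (RSA ≤ 0.05 under the theoretical ALLOWED scale).
Correlations are two-sided Pearson tests at n = 20 with a 0.05
significance flag and no multiple-testing correction. Three experimental
reference scales are packaged as citation-attributed data (Kyte &
Doolittle 1982; Fauchère & Pliška 1983; Wolfenden et al. 1981, which has
no proline value); their numbers are data inputs, not results of this
package.

## Numerical and degenerate-input conventions

* Angles wrap to [−180°, 180°); bins are lower-edge labelled.
* Atom placement refuses collinear reference frames; ASA refuses
  coincident atoms and empty structures.
* `correction_vs()` rounds 100 × (a − b)/a to the nearest integer with
  the *first* scale as denominator — the only convention that reproduces
  both printed endpoints (4% for Leu, 18% for Asp) from the printed
  constants.
* Determinism: the only RNG is rotamer subsampling and the synthetic
  generators, all driven by explicit integer seeds through R's
  Mersenne-Twister; identical inputs give byte-identical outputs.

## Known limitations

* Flanking residues are held extended; neighbour-dependent scans
  (Ala-X-Ala or arbitrary neighbours) are out of scope.
* The ALLOWED-region constants depend on the synthetic Ramachandran
  stand-in as discussed above.
* No mmCIF input, no PISCES-style culling, no chain-terminator
  normalization constants (none exist), no thermodynamic-ensemble RSA.
* DSSP's exact slice-integration scheme is matched only to within the
  stated quadrature tolerance.

## Problem sizes used in the shipped checks

Tests and the acceptance script run 5° scans (72 × 72 grid; 1–3 rotamers
for the scanned amino acids), one 2° glycine scan for grid-refinement
convergence, 960-point quadrature for headline numbers (240 points inside
fixture-heavy tests), and synthetic corpora of 3–4 structures of 8–50
residues.
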