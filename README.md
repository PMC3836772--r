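# maxasa

Maximum allowed solvent accessibility scales for protein residues.

## The problem

Relative solvent accessibility,

```
RSA = ASA / MaxASA(aa),
```

normalizes a residue's accessible surface area (ASA, Å², Lee–Richards
definition with a 1.4 Å probe) by a per-amino-acid reference maximum.
The classic normalization constants (Miller et al. 1987, extended
Gly-X-Gly tripeptides; Rose et al. 1985, average-conformation
tripeptides) are not true upper bounds: crystal structures routinely
contain residues with RSA > 1, because the conformations that maximize
ASA — in the α-helical region of the Ramachandran plot, not the extended
conformation — were never evaluated.

`maxasa` is for structural bioinformaticians who need defensible RSA
values: it derives tight per-amino-acid maximum-ASA constants by
exhaustive conformational enumeration, and provides the surrounding
machinery (empirical structure survey, normalization tables, burial-based
hydrophobicity scales).

## What it computes

For each amino acid X, the package builds a Gly-X-Gly tripeptide from
internal coordinates (all heavy atoms, Engh & Huber-style geometry, trans
peptide bonds, L-configured Cα), steps the central φ/ψ over the full
torus in discrete increments crossed with χ-sector rotamers (+60°, −60°,
180°; at most 10 sampled combinations per grid point), discards sterically
impossible conformations, and records the maximum central-residue ASA per
(φ, ψ) grid point — computed by Shrake–Rupley quadrature (golden-spiral
points, DSSP-compatible radii, C++ kernel). Restricting the grid to a
Ramachandran region (CORE / ALLOWED / GENEROUS / ALL, defined from
backbone-angle frequencies by coverage thresholds) turns the grid into a
normalization constant.

The survey module runs the complementary empirical pipeline on PDB files:
per-residue φ/ψ and ASA with chain-terminator and occupancy/completeness
filters, per-bin empirical maxima, and RSA-exceedance reports. The hydro
module derives hydrophobicity scales (1 − mean RSA, fraction 100%/95%
buried) and correlates them with packaged experimental transfer-energy
scales.

## Worked example

```r
library(maxasa)

# coarse scan of glycine (15-degree grid; use step = 5 or 1 for production)
grid <- scan_max_asa("G", step = 15)
glance(grid)
#> # A tibble: 1 × 6
#>   aa     step n_bins max_asa argmax_phi argmax_psi
#>   <chr> <dbl>  <int>   <dbl>      <dbl>      <dbl>
#> 1 G        15    576    111.        -30         15

# restrict to the ALLOWED Ramachandran region (packaged synthetic
# reference counts) to get the normalization constant
allowed <- define_region(rama_reference_counts("G"), "ALLOWED")
max_asa_in_region(grid, allowed)
#> [1] 107.4989

autoplot(grid)   # Ramachandran heat map of per-bin maxima
```

The global maximum (~111 Å²) sits in strained backbone territory; the
ALLOWED-region maximum (~107 Å² at this coarse step) is the quantity
comparable to published glycine constants (104 Å² theoretical, 97 Å²
empirical, vs 85 Å² Miller and 88.1 Å² Rose — all served by
`get_scale()`). Both comfortably exceed the older constants:

```r
correction_vs(get_scale("theoretical"), get_scale("rose1985"))
#> # A tibble: 20 × 2
#>    aa    percent
#>    <chr>   <dbl>
#>  1 A           8
#>  2 C          13
#>  3 D          18
#>  ...
```

The corrections to the Rose scale run from 4% (Leu) to 18% (Asp).

Empirical pipeline on a directory of PDB files:

```r
obs <- survey_pdb_dir("structures/")
rsa_exceedance(obs)                    # fraction of residues with RSA > 1
empirical_max_grid(obs[obs$aa == "A", ])
mean_rsa_scale(obs)                    # hydrophobicity from burial
```

A thin command-line front end lives in `inst/cli/maxasa.R`
(`scan`, `normalize`, `hydro` subcommands).

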