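#!/usr/bin/env Rscript
# Regenerates inst/extdata/rama_reference_counts_synthetic.tsv: synthetic
# per-amino-acid phi/psi bin counts from the package's Ramachandran mixture
# model (fixed seed), used to anchor CORE/ALLOWED/GENEROUS regions.
library(maxasa)
library(dplyr)

counts <- purrr::map_dfr(amino_acids(), function(aa) {
  simulate_rama_counts(aa, n = 20000, bin_width = 20, seed = 20131121) |>
    mutate(aa = aa, .before = 1)
})
write.table(counts, "inst/extdata/rama_reference_counts_synthetic.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", nrow(counts), "rows\n")
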