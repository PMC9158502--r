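#!/usr/bin/env Rscript
# Regenerates the packaged default calibration table
# (inst/extdata/lsc_synthetic_default.tsv). The table is a synthetic
# stand-in calibrated on seeded Markov-mixture genomes; run from the
# repository root after installing the package.
library(tetrasieve)

seed <- 20260912
set.seed(seed)
genomes <- lapply(1:5, function(i) {
  simulate_genome(1e6, n_components = 3, block_len_bp = 5000, alpha = 1,
                  id = sprintf("cal%02d", i))
})
table <- calibrate(
  genomes,
  bins_kb = seq(10, 200, by = 10),
  n_pairs_per_bin = 200,
  seed = seed,
  provenance = sprintf(
    paste0("synthetic: calibrate() on 5 simulated 1 Mb Markov-mixture ",
           "genomes (3 components, 5 kb blocks, alpha=1), 200 pairs/bin, ",
           "seed %d"), seed)
)
save_calibration(table, "inst/extdata/lsc_synthetic_default.tsv")
cat("wrote inst/extdata/lsc_synthetic_default.tsv\n")
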