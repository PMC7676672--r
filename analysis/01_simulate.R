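#!/usr/bin/env Rscript
# Simulate the study panel: a cotton-like genus (1 tetraploid-analog + 2
# diploid-analog congeners) and a wheat-like genus complex (8 congeners),
# using the preset plastome architectures and third-position bias profiles.
# Writes GenBank records and truth sidecars under results/records/.

suppressPackageStartupMessages(library(cpSCUB))

seed <- 1L
out_dir <- "results/records"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cotton <- generate_genus(
  emulate_paper_architecture("cotton", seed = seed, accession = "COT"),
  n_species = 3, divergence = 0.01)
wheat <- generate_genus(
  emulate_paper_architecture("wheat", seed = seed + 1L, accession = "WHT"),
  n_species = 8, divergence = 0.02)

for (gen in c(cotton, wheat)) {
  paths <- write_synthetic_record(gen, out_dir)
  message("wrote ", paths$genbank)
}

message(sprintf("simulated %d records (%d cotton-like, %d wheat-like)",
                length(cotton) + length(wheat), length(cotton), length(wheat)))
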