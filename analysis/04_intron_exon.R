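#!/usr/bin/env Rscript
# Intron- and exon-resolved SCUB: NNC/G-to-NNA/T ratios by intron class and
# by exon position, pooled per genus, with two-sample t-tests between
# classes across species.

suppressPackageStartupMessages(library(cpSCUB))

paths <- Sys.glob("results/records/*.gb")
stopifnot(length(paths) > 0)
records <- lapply(paths, read_genbank)
names(records) <- vapply(records, `[[`, character(1), "accession")

by_class <- do.call(rbind, lapply(names(records), function(acc) {
  out <- scub_by_intron_class(build_gene_models(records[[acc]]))
  cbind(accession = acc, out)
}))
write.table(by_class, "results/scub_by_intron_class.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(by_class, row.names = FALSE)

# difference between intron classes across species (ratios as replicates)
r0 <- by_class$ratio[by_class$intron_class == 0]
r1 <- by_class$ratio[by_class$intron_class == 1]
tt <- t_two_sample(r0, r1)
message(sprintf("intron class 0 vs 1 across species: t = %.2f, p = %.3g",
                tt$statistic, tt$p_value))

by_exon <- do.call(rbind, lapply(names(records), function(acc) {
  models <- build_gene_models(records[[acc]])
  do.call(rbind, lapply(1:2, function(k) {
    out <- scub_by_exon_position(models, k)
    cbind(accession = acc, intron_class = k, out)
  }))
}))
write.table(by_exon, "results/scub_by_exon_position.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("exon-position ratios written to results/scub_by_exon_position.tsv")
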