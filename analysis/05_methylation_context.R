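#!/usr/bin/env Rscript
# CpG-context proxies of methylation-mediated C-to-T conversion: NXG/NXC
# second-position ratios, NC|X / NG|X junction ratios, the NCG/NCA ratio and
# same-prefix NNG/NNC pair ratios per amino acid, pooled per genus, with the
# chi-square tests on raw counts.

suppressPackageStartupMessages(library(cpSCUB))

paths <- Sys.glob("results/records/*.gb")
stopifnot(length(paths) > 0)
records <- lapply(paths, read_genbank)
genus <- ifelse(grepl("^COT", vapply(records, `[[`, character(1), "accession")),
                "cotton", "wheat")

for (g in c("cotton", "wheat")) {
  models <- do.call(c, lapply(records[genus == g], build_gene_models))
  tab <- count_codons(models)
  ctx <- context_ratio_set(models, tab)

  message("== ", g, "-like genus (pooled) ==")
  sp <- ctx$second_pos
  print(sp, row.names = FALSE)
  # NCG/NCC vs NAG/NAC: chi-square on the raw counts
  ht <- chi2_contingency(rbind(
    C = c(sp$NXG[sp$X == "C"], sp$NXC[sp$X == "C"]),
    A = c(sp$NXG[sp$X == "A"], sp$NXC[sp$X == "A"])))
  message(sprintf("NCG/NCC vs NAG/NAC: chi2 = %.1f, p = %.3g",
                  ht$statistic, ht$p_value))
  message(sprintf("NCG/NCA = %.3f (CpG deficit at codon positions 2-3)",
                  ctx$ncg_nca$ratio))
  jr <- ctx$junction
  message(sprintf("junction NC|G/NG|G = %.3f vs NC|T/NG|T = %.3f",
                  jr$ratio[jr$X == "G"], jr$ratio[jr$X == "T"]))
  write.table(cbind(genus = g, ctx$second_pos),
              sprintf("results/context_second_position_%s.tsv", g),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cbind(genus = g, ctx$junction),
              sprintf("results/context_junction_%s.tsv", g),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cbind(genus = g, ctx$per_aa_gc),
              sprintf("results/context_per_aa_%s.tsv", g),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
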