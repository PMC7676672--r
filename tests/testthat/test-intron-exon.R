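# Split-codon assignment and intron/exon-resolved ratios.

test_that("split codons follow the 1|2-downstream / 2|1-upstream rule", {
  # exon lengths (4, 8): codon 2 is split after its 1st nt -> exon 2
  m <- make_model("ATGAAATTTTAA", exon_lengths = c(4L, 8L))
  p <- partition_codons(m)
  expect_equal(p$codon_exon, c(1L, 2L, 2L, 2L))
  expect_equal(p$assignment_log$codon_index, 2L)
  expect_equal(p$assignment_log$split_phase, 1L)
  expect_equal(p$assignment_log$assigned_exon, 2L)
  expect_equal(as.integer(table(p$codon_exon)), c(1L, 3L))

  # exon lengths (5, 7): codon 2 split after its 2nd nt -> exon 1
  m <- make_model("ATGAAATTTTAA", exon_lengths = c(5L, 7L))
  p <- partition_codons(m)
  expect_equal(p$codon_exon, c(1L, 1L, 2L, 2L))
  expect_equal(p$assignment_log$split_phase, 2L)
  expect_equal(p$assignment_log$assigned_exon, 1L)

  # exon lengths (6, 6): no split codons
  m <- make_model("ATGAAATTTTAA", exon_lengths = c(6L, 6L))
  p <- partition_codons(m)
  expect_equal(p$codon_exon, c(1L, 1L, 2L, 2L))
  expect_equal(nrow(p$assignment_log), 0L)
})

test_that("assignment matches the brute-force phase walker on random architectures", {
  set.seed(2024)
  for (i in 1:100) {
    arch <- random_architecture()
    cds <- random_cds(sum(arch) %/% 3L)
    m <- make_model(cds, exon_lengths = arch)
    if (!m$passes_filter) next
    p <- partition_codons(m)
    expect_equal(p$codon_exon, phase_walker(arch))
    # conservation: every codon assigned to exactly one exon
    expect_equal(length(p$codon_exon), nchar(cds) %/% 3L)
  }
})

test_that("intron-class ratios pool eligible codons per class", {
  # single gene: internal codons AAA (NNA) and AAG (NNG) -> ratio 1
  one <- scub_by_intron_class(list(make_model("ATGAAAAAGTAA")))
  expect_equal(one$intron_class, 0L)
  expect_equal(one$NNA, 1L)
  expect_equal(one$NNG, 1L)
  expect_equal(one$ratio, 1.0)

  # biased (theta = 0.75) intronless genes vs unbiased (0.5) one-intron genes
  biased <- generate_record(synthetic_truth(
    seed = 21L, theta = 0.75, n_genes_by_intron_class = c("0" = 10L),
    mean_gene_len_codons = 120L))
  unbiased <- generate_record(synthetic_truth(
    seed = 22L, theta = 0.5, n_genes_by_intron_class = c("1" = 10L),
    mean_gene_len_codons = 120L))
  models <- c(build_gene_models(biased$record),
              build_gene_models(unbiased$record))
  by_class <- scub_by_intron_class(models)
  expect_equal(by_class$intron_class, c(0L, 1L))
  expect_lt(by_class$ratio[[1]], by_class$ratio[[2]])

  # per-gene averaging mode stays close to the pooled value here
  pg <- scub_by_intron_class(models, per_gene = TRUE)
  expect_equal(pg$ratio, by_class$ratio, tolerance = 0.1)
})

test_that("ratios are invariant to gene input order", {
  gen <- generate_record(synthetic_truth(
    seed = 31L, n_genes_by_intron_class = c("0" = 5L, "1" = 3L, "2" = 2L),
    mean_gene_len_codons = 80L))
  models <- build_gene_models(gen$record)
  set.seed(1)
  shuffled <- models[sample(seq_along(models))]
  expect_equal(scub_by_intron_class(models), scub_by_intron_class(shuffled))
  expect_equal(scub_by_exon_position(models, 1L),
               scub_by_exon_position(shuffled, 1L))
})

test_that("exon-position ratios handle degenerate one-sided compositions", {
  # exon 1 holds only NNC codons, exon 2 only NNT codons
  cds <- paste0("ATG", "GCCGCC", "GCTGCT", "TAA")
  m <- make_model(cds, exon_lengths = c(9L, 9L))
  out <- scub_by_exon_position(list(m), 1L)
  expect_equal(out$exon_rank, c(1L, 2L))
  expect_true(is.na(out$ratio[[1]]))  # no A/T-ending codons in exon 1
  expect_equal(out$ratio[[2]], 0)

  expect_error(scub_by_exon_position(list(m), 3L), "no filtered genes")
})

test_that("per-exon-rank theta shows up in the exon-position ratios", {
  # three-exon genes with A/T preference (0.5, 0.8, 0.5): middle exon lowest
  gens <- lapply(1:5, function(i) generate_record(synthetic_truth(
    seed = 100L + i, theta = c(0.5, 0.8, 0.5),
    n_genes_by_intron_class = c("2" = 12L), mean_gene_len_codons = 150L)))
  models <- do.call(c, lapply(gens, function(g) build_gene_models(g$record)))
  out <- scub_by_exon_position(models, 2L)
  expect_equal(out$exon_rank, 1:3)
  expect_lt(out$ratio[[2]], out$ratio[[1]])
  expect_lt(out$ratio[[2]], out$ratio[[3]])
})

test_that("codons are conserved across exon ranks including excluded ones", {
  gen <- generate_record(synthetic_truth(
    seed = 55L, n_genes_by_intron_class = c("1" = 4L, "2" = 3L),
    mean_gene_len_codons = 60L, internal_stop_rate = 1))
  for (m in build_gene_models(gen$record)) {
    p <- partition_codons(m)
    expect_equal(length(p$codon_exon), nchar(m$spliced_cds) %/% 3L)
    expect_true(all(p$codon_exon >= 1L & p$codon_exon <= m$intron_count + 1L))
    # split codons assigned to exactly one exon each
    expect_true(all(table(p$assignment_log$codon_index) == 1L))
  }
})
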