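# Codon counting under the 59-SC eligibility rules, RSCU, CAI, SCUB profile.

test_that("counting excludes start, stop, TGG, internal ATG and ambiguous codons", {
  t1 <- count_codons(list(make_model("ATGGCTGCCTAA")))
  expect_equal(t1$counts[["GCT"]], 1L)
  expect_equal(t1$counts[["GCC"]], 1L)
  expect_equal(t1$eligible_total, 2L)
  expect_equal(t1$excluded_tally[["start"]], 1L)
  expect_equal(t1$excluded_tally[["stop"]], 1L)

  t2 <- count_codons(list(make_model("ATGTGGAAATAA")))
  expect_equal(t2$counts[["AAA"]], 1L)
  expect_equal(t2$excluded_tally[["TGG"]], 1L)

  t3 <- count_codons(list(make_model("ACGGCTTAA")))
  expect_equal(t3$counts[["GCT"]], 1L)
  expect_equal(t3$eligible_total, 1L)
  expect_equal(t3$excluded_tally[["atypical_start"]], 1L)

  t4 <- count_codons(list(make_model("ATGATGNNNTAATCGTAA")))
  expect_equal(t4$excluded_tally[["ATG"]], 1L)        # internal ATG
  expect_equal(t4$excluded_tally[["ambiguous"]], 1L)  # NNN
  expect_equal(t4$excluded_tally[["internal_stop"]], 1L)
  expect_equal(t4$eligible_total, 1L)                 # TCG

  empty <- count_codons(list())
  expect_equal(empty$eligible_total, 0L)
  expect_true(all(empty$counts == 0L))
})

test_that("RSCU follows the family-normalized definition and sums to family size", {
  lys <- codon_count_table(c(AAA = 3L, AAG = 1L))
  r <- rscu(lys)
  expect_equal(r[["AAA"]], 1.5)
  expect_equal(r[["AAG"]], 0.5)
  expect_true(all(is.na(r[setdiff(names(r), c("AAA", "AAG"))])))

  uniform <- codon_count_table(stats::setNames(rep(5L, 59), synonymous_codons()))
  expect_equal(unname(rscu(uniform)), rep(1, 59))

  # family sums equal family sizes for an arbitrary table
  set.seed(42)
  tab <- codon_count_table(stats::setNames(
    sample(1:50, 59, replace = TRUE), synonymous_codons()))
  r <- rscu(tab)
  for (fam in sc_families()) {
    expect_equal(sum(r[fam]), length(fam))
  }
})

test_that("CAI is the geometric mean of weights over codon occurrences", {
  sc <- synonymous_codons()
  w1 <- stats::setNames(rep(1, 59), sc)
  tab <- codon_count_table(c(GCT = 4L, AAA = 2L))
  expect_equal(cai(tab, weights = w1), 1)

  one <- codon_count_table(c(GCT = 1L))
  w <- w1; w[["GCT"]] <- 0.25
  expect_equal(cai(one, weights = w), 0.25)

  two <- codon_count_table(c(GCT = 1L, AAA = 1L))
  w2 <- w1; w2[["GCT"]] <- 0.25
  expect_equal(cai(two, weights = w2), sqrt(0.25 * 1))

  # self-derived weights: the most-used codon of each family has weight 1,
  # so a table using only family-preferred codons has CAI 1
  pref <- codon_count_table(c(GCT = 10L, AAA = 7L))
  expect_equal(cai(pref), 1)
})

test_that("the SCUB profile reproduces hand-computed ratios and frequencies", {
  tab <- codon_count_table(c(GCT = 3L, GCC = 1L, GCA = 1L, GCG = 1L))
  pr <- scub_profile(tab)
  expect_equal(pr$per_aa_ratio[["A"]], 0.5)
  expect_equal(pr$terminal_freq, c(A = 1/6, T = 3/6, C = 1/6, G = 1/6))
  expect_equal(pr$nncg_to_nnat, 0.5)
  expect_equal(sum(pr$terminal_freq), 1)

  # perfectly balanced table: 2-fold families have ratio 1; the global ratio
  # follows the 59-SC universe composition (29 C/G-ending vs 30 A/T-ending)
  balanced <- codon_count_table(stats::setNames(rep(4L, 59), synonymous_codons()))
  prb <- scub_profile(balanced)
  twofold <- names(Filter(function(f) length(f) == 2L, sc_families()))
  expect_true(all(abs(prb$per_aa_ratio[twofold] - 1) < 1e-12))
  gc3 <- table(substr(names(Biostrings::GENETIC_CODE), 3, 3)[
    !(Biostrings::GENETIC_CODE %in% "*") &
      !(names(Biostrings::GENETIC_CODE) %in% c("ATG", "TGG"))])
  expect_equal(prb$nncg_to_nnat,
               (gc3[["C"]] + gc3[["G"]]) / (gc3[["A"]] + gc3[["T"]]))
  expect_equal(prb$nncg_to_nnat, 29 / 30)
})

test_that("per-codon frequencies match a brute-force triplet scan", {
  set.seed(7)
  cds <- vapply(1:5, function(i) {
    paste0("ATG", random_cds(sample(10:30, 1L)), "TAA")
  }, character(1))
  models <- lapply(cds, make_model)
  tab <- count_codons(models)
  # oracle: scan every CDS, drop first/last codon, drop ineligible triplets
  oracle <- stats::setNames(integer(64), names(Biostrings::GENETIC_CODE))
  for (s in cds) {
    starts <- seq.int(1L, nchar(s) - 2L, by = 3L)
    trip <- substring(s, starts, starts + 2L)
    internal <- trip[-c(1L, length(trip))]
    keep <- internal[internal %in% synonymous_codons()]
    for (k in keep) oracle[[k]] <- oracle[[k]] + 1L
  }
  expect_equal(tab$counts, oracle)
  pr <- scub_profile(tab)
  expect_equal(pr$per_codon_freq,
               (oracle / sum(oracle))[synonymous_codons()])
})

test_that("pooled counting equals the sum of per-gene tables", {
  set.seed(13)
  models <- lapply(1:6, function(i) {
    make_model(paste0("ATG", random_cds(sample(5:20, 1L)), "TAA"))
  })
  pooled <- count_codons(models)
  per_gene <- lapply(models, function(m) count_codons(list(m)))
  summed <- pool_codon_tables(per_gene)
  expect_equal(pooled$counts, summed$counts)
  expect_equal(pooled$excluded_tally, summed$excluded_tally)
  expect_equal(pooled$eligible_total, summed$eligible_total)
})

test_that("genomic and gene-body GC/AT ratios match hand counts", {
  rec <- structure(list(accession = "X", organism = "x", sequence = "ATGC",
                        length = 4L, circular = FALSE, features = list()),
                   class = "plastome_record")
  out <- gc_vs_at_genomic(rec, list())
  expect_equal(out$genome_gc_at, 1.0)

  rec$sequence <- "AAAAAA"
  expect_equal(gc_vs_at_genomic(rec, list())$genome_gc_at, 0)

  rec$sequence <- "ATGGCTTAAGGGCCC"
  m <- make_model("ATGGCTTAA")
  out <- gc_vs_at_genomic(rec, list(m))
  # genome: G5+C4 vs A3+T3; gene body ATGGCTTAA: G2+C1 vs A3+T3
  expect_equal(out$genome_gc_at, 9 / 6)
  expect_equal(out$gene_body_gc_at, 3 / 6)
})

test_that("include_internal_atg enlarges only the denominator", {
  m <- make_model("ATGATGGCTTAA")  # internal ATG + GCT
  strict <- count_codons(list(m))
  loose <- count_codons(list(m), include_internal_atg = TRUE)
  expect_equal(strict$eligible_total, loose$eligible_total)
  expect_equal(strict$denominator_total, 1L)
  expect_equal(loose$denominator_total, 2L)
  expect_lt(sum(scub_profile(loose)$terminal_freq), 1)
  expect_equal(sum(scub_profile(strict)$terminal_freq), 1)
})
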