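# GenBank reading, location semantics, gene models and terminus classes.

test_that("a minimal record with one forward CDS parses to an identity gene model", {
  path <- write_toy_genbank("ATGTAA", list("1..6"), genes = "toy1")
  rec <- read_genbank(path)
  expect_s3_class(rec, "plastome_record")
  expect_equal(rec$accession, "TOY001")
  expect_equal(rec$sequence, "ATGTAA")
  expect_length(rec$features, 1L)
  models <- build_gene_models(rec)
  expect_length(models, 1L)
  expect_equal(models[[1]]$spliced_cds, "ATGTAA")
  expect_equal(models[[1]]$intron_count, 0L)
})

test_that("compound join locations keep their listed part order", {
  seq <- paste(rep("ACGT", 10), collapse = "")
  path <- write_toy_genbank(seq, list("join(1..4,10..17)"))
  rec <- read_genbank(path)
  expect_equal(rec$features[[1]]$parts$start, c(1L, 10L))
  expect_equal(rec$features[[1]]$parts$end, c(4L, 17L))
  m <- build_gene_models(rec)[[1]]
  expect_equal(nchar(m$spliced_cds), 12L)
  expect_equal(m$intron_count, 1L)
})

test_that("complement(join(...)) yields mRNA ranks in reverse genome order, revcomp'd", {
  # genome: exon2' = positions 1..6, exon1' = positions 10..15
  # gene on minus strand: mRNA = revcomp(seq[10..15]) + revcomp(seq[1..6])
  seq <- "TTACATCCCGGCATA"
  path <- write_toy_genbank(seq, list("complement(join(1..6,10..15))"))
  rec <- read_genbank(path)
  f <- rec$features[[1]]
  expect_equal(f$strand, "-")
  expect_equal(f$parts$start, c(10L, 1L))  # mRNA order reverses listed order
  m <- build_gene_models(rec)[[1]]
  manual <- paste0(
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(substr(seq, 10, 15)))),
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(substr(seq, 1, 6))))
  )
  expect_equal(m$spliced_cds, manual)
})

test_that("a minus-strand single-exon CDS is reverse-complemented", {
  path <- write_toy_genbank("TTACAT", list("complement(1..6)"))
  m <- build_gene_models(read_genbank(path))[[1]]
  expect_equal(m$spliced_cds, "ATGTAA")
})

test_that("terminus classification follows the ATG / stop-triplet rules", {
  expect_equal(
    classify_termini(make_model("ATGGCTTAA"))[c("start_class", "stop_class", "internal_stop_count")],
    list(start_class = "typical_ATG", stop_class = "TAA", internal_stop_count = 0L)
  )
  acg <- classify_termini(make_model("ACGGCTTGA"))
  expect_equal(acg$start_class, "atypical:ACG")
  expect_equal(acg$stop_class, "TGA")
  withstop <- classify_termini(make_model("ATGTAAGCTTAG"))
  expect_equal(withstop$start_class, "typical_ATG")
  expect_equal(withstop$stop_class, "TAG")
  expect_equal(withstop$internal_stop_count, 1L)
  expect_equal(withstop$internal_stop_identities, "TAA")
  expect_error(classify_termini(make_model("ATG")), "shorter")
})

test_that("structure summary tallies intron classes and codon termini", {
  empty <- summarize_structure(list())
  expect_equal(empty$total, 0L)

  models <- list(make_model("ATGGCTTAA"), make_model("ATGAAATAA"),
                 make_model("ACGGCTTGA"))
  s <- summarize_structure(models)
  expect_equal(s$intron_class_counts, c("0" = 3L))
  expect_equal(s$total, 3L)
  expect_equal(s$start_codon_tally[["ATG"]], 2L)
  expect_equal(s$start_codon_tally[["ACG"]], 1L)
  expect_equal(sum(s$start_codon_tally), s$total)
  expect_equal(s$stop_codon_tally[["TAA"]], 2L)
})

test_that("pseudo, invalid-coordinate and frame-breaking CDS land in the rejection log", {
  seq <- paste(rep("ATGGCTTAA", 4), collapse = "")
  path <- write_toy_genbank(seq, list("1..9", "10..18"), genes = c("ok", "bad"))
  lines <- readLines(path)
  # make gene "bad" pseudo, add an out-of-range and a non-multiple-of-3 CDS
  i <- grep('/gene="bad"', lines)
  lines <- append(lines, "                     /pseudo", after = i)
  i <- grep("^ORIGIN", lines)
  lines <- append(lines, c("     CDS             19..500",
                           "     CDS             19..26"), after = i - 1L)
  writeLines(lines, path)

  models <- suppressWarnings(build_gene_models(read_genbank(path)))
  rej <- rejection_log(models)
  expect_setequal(rej$reason,
                  c("pseudo flag", "coordinates invalid", "length not divisible by 3"))
  # pseudo and invalid-coordinate CDS dropped; frame-breaker retained, flagged
  expect_length(models, 2L)
  flags <- vapply(models, function(m) m$passes_filter, logical(1))
  expect_equal(sum(flags), 1L)
})

test_that("synthetic records round-trip through GenBank byte-identically in structure", {
  gen <- generate_record(synthetic_truth(
    seed = 7L, n_genes_by_intron_class = c("0" = 4L, "1" = 2L, "2" = 1L),
    mean_gene_len_codons = 60L))
  path <- tempfile(fileext = ".gb")
  write_genbank(gen$record, path)
  rec2 <- read_genbank(path)
  m1 <- build_gene_models(gen$record)
  m2 <- build_gene_models(rec2)
  expect_equal(length(m1), length(m2))
  for (i in seq_along(m1)) {
    expect_equal(m1[[i]]$spliced_cds, m2[[i]]$spliced_cds)
    expect_equal(m1[[i]]$strand, m2[[i]]$strand)
    expect_equal(m1[[i]]$exons, m2[[i]]$exons)
  }
})

test_that("spliced length equals the sum of exon lengths on generated records", {
  gen <- generate_record(synthetic_truth(
    seed = 11L, n_genes_by_intron_class = c("0" = 3L, "1" = 3L, "2" = 2L),
    mean_gene_len_codons = 50L))
  for (m in build_gene_models(gen$record)) {
    expect_equal(nchar(m$spliced_cds), sum(m$exons$end - m$exons$start + 1L))
  }
})

test_that("an origin-wrapping gene is normalized on a circular record", {
  t0 <- synthetic_truth(seed = 5L, n_genes_by_intron_class = c("0" = 3L),
                        mean_gene_len_codons = 40L)
  plain <- generate_record(t0)
  wrapped <- generate_record(synthetic_truth(
    seed = 5L, n_genes_by_intron_class = c("0" = 3L),
    mean_gene_len_codons = 40L, wrap_gene = TRUE))
  # rotation moves coordinates but must not change any spliced CDS
  s1 <- sort(vapply(build_gene_models(plain$record), `[[`, character(1), "spliced_cds"))
  s2 <- sort(vapply(build_gene_models(wrapped$record), `[[`, character(1), "spliced_cds"))
  expect_equal(s1, s2)
  # and at least one feature must actually straddle the origin
  straddles <- vapply(wrapped$record$features, function(f) {
    any(f$parts$start > f$parts$end)
  }, logical(1))
  expect_true(any(straddles))
})

test_that("the reader agrees with Biopython on a synthetic record", {
  gen <- generate_record(synthetic_truth(
    seed = 3L, n_genes_by_intron_class = c("0" = 3L, "1" = 2L),
    mean_gene_len_codons = 40L, minus_strand_prob = 0.5))
  path <- tempfile(fileext = ".gb")
  write_genbank(gen$record, path)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "from Bio import SeqIO",
    "rec = SeqIO.read(sys.argv[1], 'genbank')",
    "for f in rec.features:",
    "    if f.type == 'CDS':",
    "        print(str(f.extract(rec.seq)))"
  ), script)
  out <- tryCatch(system2("python", c(script, path), stdout = TRUE),
                  warning = function(w) NULL, error = function(e) NULL)
  expect_false(is.null(out))
  ours <- vapply(build_gene_models(read_genbank(path)), `[[`,
                 character(1), "spliced_cds")
  expect_equal(toupper(out), unname(ours))
})

test_that("a record without CDS features warns but still parses", {
  path <- write_toy_genbank("ATGTAA", list())
  expect_warning(rec <- read_genbank(path), "no CDS")
  expect_equal(rec$length, 6L)
})
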