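# Shared fixtures and independent oracles, all built in code.

# a gene_model directly from a spliced CDS and exon lengths (mRNA order)
make_model <- function(cds, exon_lengths = nchar(cds), gene = "toy",
                       strand = "+") {
  stopifnot(sum(exon_lengths) == nchar(cds))
  ends <- cumsum(exon_lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  m <- structure(list(
    gene_name = gene, strand = strand,
    exons = data.frame(start = starts, end = ends,
                       rank = seq_along(exon_lengths)),
    spliced_cds = cds,
    intron_count = length(exon_lengths) - 1L,
    passes_filter = nchar(cds) %% 3L == 0L,
    has_ambiguous = grepl("[^ACGT]", cds)
  ), class = "gene_model")
  if (m$passes_filter && nchar(cds) >= 6L) {
    m <- c(m, classify_termini(m))
    class(m) <- "gene_model"
  }
  m
}

# write a handcrafted GenBank file and return its path
write_toy_genbank <- function(sequence, cds_locations, genes = NULL,
                              circular = FALSE) {
  path <- tempfile(fileext = ".gb")
  topo <- if (circular) "circular" else "linear"
  lines <- c(
    sprintf("LOCUS       TOY              %d bp    DNA     %s PLN 01-JAN-2024",
            nchar(sequence), topo),
    "DEFINITION  toy record.",
    "ACCESSION   TOY001",
    "SOURCE      Toyus exampleus",
    "  ORGANISM  Toyus exampleus",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(sequence))
  )
  for (i in seq_along(cds_locations)) {
    lines <- c(lines, sprintf("     CDS             %s", cds_locations[[i]]))
    if (!is.null(genes)) {
      lines <- c(lines, sprintf('                     /gene="%s"', genes[[i]]))
    }
  }
  lines <- c(lines, "ORIGIN")
  s <- tolower(sequence)
  for (p in seq.int(1L, nchar(s), by = 60L)) {
    chunk <- substr(s, p, min(p + 59L, nchar(s)))
    blocks <- substring(chunk, seq.int(1L, nchar(chunk), by = 10L),
                        pmin(seq.int(10L, nchar(chunk) + 9L, by = 10L),
                             nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", p, paste(blocks, collapse = " ")))
  }
  writeLines(c(lines, "//"), path)
  path
}

# independent oracle: assign each codon to an exon by walking nucleotides
# one at a time and applying the split rule on the recorded per-nt exons
phase_walker <- function(exon_lengths) {
  nt_exon <- rep(seq_along(exon_lengths), times = exon_lengths)
  n_codons <- length(nt_exon) %/% 3L
  vapply(seq_len(n_codons), function(i) {
    e <- nt_exon[(3L * i - 2L):(3L * i)]
    if (e[1] == e[3]) {
      e[1]
    } else if (e[2] == e[3]) {
      e[2]  # break after nt 1: downstream
    } else if (e[1] == e[2]) {
      e[1]  # break after nt 2: upstream
    } else {
      e[2]  # broken twice (1-nt exon): middle exon convention
    }
  }, integer(1))
}

# independent oracle: codon counts of a CDS by a simple seq/substr scan
brute_force_codons <- function(cds) {
  starts <- seq.int(1L, nchar(cds) - 2L, by = 3L)
  table(substring(cds, starts, starts + 2L))
}

# random exon architecture whose total length is a multiple of 3
random_architecture <- function(max_exons = 5L, max_len = 40L) {
  k <- sample.int(max_exons, 1L)
  len <- sample.int(max_len, k, replace = TRUE)
  rem <- sum(len) %% 3L
  if (rem != 0L) len[k] <- len[k] + (3L - rem)
  len
}

# random CDS of n codons (arbitrary triplets over ACGT)
random_cds <- function(n_codons) {
  paste(sample(c("A", "C", "G", "T"), 3L * n_codons, replace = TRUE),
        collapse = "")
}
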