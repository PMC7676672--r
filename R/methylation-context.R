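# Sequence-context proxy ratios for CpG-methylation-driven C-to-T
# conversion: second-position NXG/NXC ratios, codon-junction NC|X / NG|X
# ratios, the NCG/NCA ratio, and per-amino-acid NNG/NNC pair ratios.
# Raw numerator/denominator counts are always kept so chi-square tests can
# run on counts rather than ratios.

#' Second-position NXG/NXC ratios
#'
#' For each second-position base X, the ratio of eligible codons with third
#' base G to those with third base C.
#'
#' @param table A `codon_count_table`.
#' @return Data frame: `X`, `NXG` (count), `NXC` (count), `ratio` (`NA` when
#'   the denominator is zero).
#' @export
second_position_ratios <- function(table) {
  sc <- synonymous_codons()
  cnt <- table$counts[sc]
  b2 <- substr(sc, 2L, 2L)
  b3 <- third_base(sc)
  out <- lapply(c("A", "C", "G", "T"), function(x) {
    g <- sum(cnt[b2 == x & b3 == "G"])
    c_ <- sum(cnt[b2 == x & b3 == "C"])
    data.frame(X = x, NXG = g, NXC = c_,
               ratio = if (c_ == 0L) NA_real_ else g / c_)
  })
  do.call(rbind, out)
}

#' Codon-junction NC|X / NG|X ratios
#'
#' Scans consecutive codon pairs within each spliced CDS (mRNA frame; an
#' intron between two codons does not break the pair). The focal codon must
#' be internal and eligible (in the 59-SC universe, no ambiguous base) and
#' end in C or G; the successor must be internal but may be any codon, since
#' only its first base matters. For each successor first base X the ratio is
#' the count of C|X junctions over G|X junctions.
#'
#' @param models List of `gene_model` objects.
#' @return Data frame: `X`, `NC_X`, `NG_X`, `ratio` (`NA` on zero
#'   denominator). Genes shorter than four codons contribute no junctions.
#' @export
junction_ratios <- function(models) {
  keep <- Filter(function(m) isTRUE(m$passes_filter), models)
  acc <- matrix(0L, nrow = 2L, ncol = 4L,
                dimnames = list(c("C", "G"), c("A", "C", "G", "T")))
  for (m in keep) {
    codons <- codon_split(m$spliced_cds)
    n <- length(codons)
    if (n < 4L) next
    for (i in 2:(n - 2L)) {
      focal <- codons[[i]]
      if (.codon_class(focal) != "eligible") next
      tb <- third_base(focal)
      if (!(tb %in% c("C", "G"))) next
      x <- substr(codons[[i + 1L]], 1L, 1L)
      if (!(x %in% c("A", "C", "G", "T"))) next
      acc[tb, x] <- acc[tb, x] + 1L
    }
  }
  data.frame(
    X = colnames(acc),
    NC_X = acc["C", ],
    NG_X = acc["G", ],
    ratio = ifelse(acc["G", ] == 0L, NA_real_, acc["C", ] / acc["G", ]),
    row.names = NULL
  )
}

#' NCG/NCA ratio
#'
#' Eligible codons with second base C: count of third-base G over third-base
#' A — the direct second/third-position CpG context whose depletion marks
#' methylation-mediated conversion.
#'
#' @param table A `codon_count_table`.
#' @return List with `NCG`, `NCA` (counts) and `ratio` (`NA` on zero
#'   denominator).
#' @export
ncg_nca_ratio <- function(table) {
  sc <- synonymous_codons()
  cnt <- table$counts[sc]
  b2 <- substr(sc, 2L, 2L)
  b3 <- third_base(sc)
  g <- sum(cnt[b2 == "C" & b3 == "G"])
  a <- sum(cnt[b2 == "C" & b3 == "A"])
  list(NCG = g, NCA = a, ratio = if (a == 0L) NA_real_ else g / a)
}

# the eight amino acids with a same-prefix NNG/NNC codon pair
.G_TO_C_PAIRS <- data.frame(
  aa = c("Ala", "Pro", "Ser", "Thr", "Arg", "Gly", "Leu", "Val"),
  prefix = c("GC", "CC", "TC", "AC", "CG", "GG", "CT", "GT"),
  stringsAsFactors = FALSE
)

#' Per-amino-acid NNG/NNC pair ratios
#'
#' For the eight amino acids encoded by both a G-ending and a C-ending codon
#' sharing first and second positions (Ala GCG/GCC, Pro CCG/CCC, Ser TCG/TCC,
#' Thr ACG/ACC, Arg CGG/CGC, Gly GGG/GGC, Leu CTG/CTC, Val GTG/GTC): the
#' ratio of the G-ending to the C-ending count. For the six-codon families
#' (Ser, Leu, Arg) only the same-prefix pair is used.
#'
#' @param table A `codon_count_table`.
#' @return Data frame: `aa`, `NNG_codon`, `NNC_codon`, `NNG`, `NNC`, `ratio`
#'   (`NA` on zero denominator).
#' @export
per_aa_g_to_c <- function(table) {
  p <- .G_TO_C_PAIRS
  gcod <- paste0(p$prefix, "G")
  ccod <- paste0(p$prefix, "C")
  g <- as.integer(table$counts[gcod])
  c_ <- as.integer(table$counts[ccod])
  data.frame(aa = p$aa, NNG_codon = gcod, NNC_codon = ccod,
             NNG = g, NNC = c_,
             ratio = ifelse(c_ == 0L, NA_real_, g / c_))
}

#' All methylation-context ratios of one species
#'
#' Bundles [second_position_ratios()], [junction_ratios()],
#' [ncg_nca_ratio()] and [per_aa_g_to_c()] from the same gene models.
#'
#' @param models List of `gene_model` objects.
#' @param table Optional precomputed `codon_count_table` (pooled over
#'   `models`); computed if missing.
#' @return A `context_ratio_set`: list with `second_pos`, `junction`,
#'   `ncg_nca`, `per_aa_gc`.
#' @export
context_ratio_set <- function(models, table = NULL) {
  if (is.null(table)) table <- count_codons(models)
  structure(list(
    second_pos = second_position_ratios(table),
    junction = junction_ratios(models),
    ncg_nca = ncg_nca_ratio(table),
    per_aa_gc = per_aa_g_to_c(table)
  ), class = "context_ratio_set")
}
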