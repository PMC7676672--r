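# Codon universe helpers built on the standard genetic code.
#
# The analysis works over the 59 "synonymous codons" (SCs): the 64 triplets
# minus the three stops (TAA, TAG, TGA) and the two single-codon amino acids
# Met (ATG) and Trp (TGG). The 59 SCs encode 18 amino acids, each by >= 2
# codons, so a within-family choice of codon is always possible.

#' Standard genetic code as codon -> amino-acid (one-letter) map
#'
#' Thin accessor over `Biostrings::GENETIC_CODE` so every module shares one
#' source of truth for codon identities.
#'
#' @return Named character vector of length 64; names are DNA codons,
#'   values one-letter amino-acid codes (`"*"` for stop).
#' @export
genetic_code <- function() {
  Biostrings::GENETIC_CODE
}

#' The three stop codons
#' @return Character vector `c("TAA","TAG","TGA")`.
#' @export
stop_codons <- function() c("TAA", "TAG", "TGA")

#' The 59 synonymous codons (SC universe)
#'
#' All codons except the three stops, ATG (Met) and TGG (Trp); the eligible
#' universe for every codon-usage statistic in the package.
#'
#' @return Character vector of 59 codons, alphabetical.
#' @export
synonymous_codons <- function() {
  gc <- genetic_code()
  sort(names(gc)[!(gc %in% "*") & !(names(gc) %in% c("ATG", "TGG"))])
}

#' Synonymous-codon families
#'
#' @return Named list: one character vector of codons per amino acid
#'   (one-letter code) over the 59-SC universe. 18 families.
#' @export
sc_families <- function() {
  sc <- synonymous_codons()
  split(sc, genetic_code()[sc])
}

#' Third-position base of each codon
#' @param codons Character vector of codons.
#' @return Character vector of third bases.
#' @export
third_base <- function(codons) substr(codons, 3L, 3L)

#' Reverse-complement of a DNA string
#'
#' @param x Character scalar over `{A,C,G,T,N}` (case-insensitive).
#' @return Upper-case reverse complement.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Split a CDS string into codons
#' @param cds Character scalar; length must be a multiple of 3.
#' @return Character vector of consecutive triplets.
#' @export
codon_split <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    stop("CDS length ", n, " is not a multiple of 3")
  }
  if (n == 0L) return(character(0))
  starts <- seq.int(1L, n, by = 3L)
  substring(cds, starts, starts + 2L)
}

# internal: classify one codon under the eligibility rules shared by
# count_codons() and partition_codons(). Position-independent part only.
.codon_class <- function(codon) {
  if (grepl("[^ACGT]", codon)) return("ambiguous")
  if (codon %in% stop_codons()) return("stop")
  if (codon == "ATG") return("ATG")
  if (codon == "TGG") return("TGG")
  "eligible"
}
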