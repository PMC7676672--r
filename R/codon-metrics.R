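# Codon counting under the 59-SC eligibility rules, RSCU, CAI and the
# third-position SCUB frequency statistics.

#' Count codons across gene models under the eligibility rules
#'
#' Pools in-frame codons over all filtered gene models. The eligible universe
#' is the 59 synonymous codons: the first codon of each gene (typical or
#' atypical start), the final codon (typical or atypical stop), internal stop
#' codons, TGG, internal ATG and codons containing a non-ACGT base are all
#' excluded from the eligible counts, each tracked in its own exclusion tally.
#'
#' @param models List of `gene_model` objects; models failing the length
#'   filter are ignored.
#' @param include_internal_atg Logical; if `TRUE`, internal ATG codons are
#'   added to the denominator total (`denominator_total`) used for terminal
#'   base frequencies, reproducing the looser reading in which internal Met
#'   codons count among "all codons". They are never part of the 59-SC counts.
#' @return A `codon_count_table`: list with `counts` (named integer vector
#'   over all 64 codons; nonzero only on the 59-SC universe),
#'   `excluded_tally` (named integer vector: `start`, `stop`,
#'   `atypical_start`, `atypical_stop`, `internal_stop`, `TGG`, `ATG`,
#'   `ambiguous`), `eligible_total` and `denominator_total`.
#' @export
count_codons <- function(models, include_internal_atg = FALSE) {
  all_codons <- names(genetic_code())
  counts <- stats::setNames(integer(64), all_codons)
  excl <- stats::setNames(integer(8), c("start", "stop", "atypical_start",
                                        "atypical_stop", "internal_stop",
                                        "TGG", "ATG", "ambiguous"))
  keep <- Filter(function(m) isTRUE(m$passes_filter), models)
  for (m in keep) {
    codons <- codon_split(m$spliced_cds)
    n <- length(codons)
    if (n == 0L) next
    excl[["start"]] <- excl[["start"]] + as.integer(codons[[1]] == "ATG")
    excl[["atypical_start"]] <- excl[["atypical_start"]] + as.integer(codons[[1]] != "ATG")
    if (n >= 2L) {
      last <- codons[[n]]
      excl[["stop"]] <- excl[["stop"]] + as.integer(last %in% stop_codons())
      excl[["atypical_stop"]] <- excl[["atypical_stop"]] + as.integer(!(last %in% stop_codons()))
    }
    if (n > 2L) {
      for (codon in codons[2:(n - 1L)]) {
        cls <- .codon_class(codon)
        if (cls == "eligible") {
          counts[[codon]] <- counts[[codon]] + 1L
        } else if (cls == "stop") {
          excl[["internal_stop"]] <- excl[["internal_stop"]] + 1L
        } else {
          excl[[cls]] <- excl[[cls]] + 1L
        }
      }
    }
  }
  eligible_total <- sum(counts)
  denom <- eligible_total + if (include_internal_atg) excl[["ATG"]] else 0L
  structure(list(counts = counts, excluded_tally = excl,
                 eligible_total = eligible_total, denominator_total = denom,
                 include_internal_atg = include_internal_atg),
            class = "codon_count_table")
}

#' Build a codon count table directly from named counts
#'
#' Convenience constructor for tests and toy examples: takes eligible counts
#' only (names must lie in the 59-SC universe).
#'
#' @param counts Named integer vector of eligible codon counts.
#' @return A `codon_count_table` with empty exclusion tallies.
#' @export
codon_count_table <- function(counts) {
  sc <- synonymous_codons()
  if (!all(names(counts) %in% sc)) {
    stop("counts contain codons outside the 59-SC universe: ",
         paste(setdiff(names(counts), sc), collapse = ", "))
  }
  full <- stats::setNames(integer(64), names(genetic_code()))
  full[names(counts)] <- as.integer(counts)
  structure(list(
    counts = full,
    excluded_tally = stats::setNames(integer(8), c("start", "stop",
      "atypical_start", "atypical_stop", "internal_stop", "TGG", "ATG",
      "ambiguous")),
    eligible_total = sum(full), denominator_total = sum(full),
    include_internal_atg = FALSE
  ), class = "codon_count_table")
}

#' Pool codon count tables
#' @param tables List of `codon_count_table` objects.
#' @return A `codon_count_table` with elementwise-summed counts and tallies.
#' @export
pool_codon_tables <- function(tables) {
  stopifnot(length(tables) >= 1L)
  out <- tables[[1]]
  for (t in tables[-1]) {
    out$counts <- out$counts + t$counts
    out$excluded_tally <- out$excluded_tally + t$excluded_tally
    out$eligible_total <- out$eligible_total + t$eligible_total
    out$denominator_total <- out$denominator_total + t$denominator_total
  }
  out
}

#' Relative synonymous codon usage
#'
#' For each codon in the 59-SC universe: observed count times family size
#' divided by the family total, so values within each amino-acid family
#' average to 1. Families with zero total are reported `NA` (undefined),
#' not 0.
#'
#' @param table A `codon_count_table`.
#' @return Named numeric vector over the 59 synonymous codons.
#' @export
rscu <- function(table) {
  fam <- sc_families()
  out <- stats::setNames(numeric(0), character(0))
  for (codons in fam) {
    cnt <- table$counts[codons]
    tot <- sum(cnt)
    val <- if (tot == 0L) rep(NA_real_, length(codons)) else
      cnt * length(codons) / tot
    out[codons] <- val
  }
  out[sort(names(out))]
}

#' Codon adaptation index
#'
#' Geometric mean of relative-adaptiveness weights over all eligible codon
#' occurrences. By default the weights are derived from the table itself:
#' within each family, w = RSCU / max(RSCU). Codons with zero weight (unused
#' in the reference) are floored at `zero_weight_floor` before taking logs.
#'
#' @param table A `codon_count_table`.
#' @param weights Optional named numeric vector of weights in (0, 1] over the
#'   59-SC universe; defaults to self-derived RSCU weights.
#' @param zero_weight_floor Replacement for zero weights (default 0.01).
#' @return CAI in (0, 1].
#' @export
cai <- function(table, weights = NULL, zero_weight_floor = 0.01) {
  sc <- synonymous_codons()
  if (is.null(weights)) {
    r <- rscu(table)
    fam <- sc_families()
    weights <- stats::setNames(numeric(length(sc)), sc)
    for (codons in fam) {
      rmax <- suppressWarnings(max(r[codons], na.rm = TRUE))
      weights[codons] <- if (is.finite(rmax) && rmax > 0) r[codons] / rmax else NA_real_
    }
  }
  floored <- weights
  floored[!is.na(floored) & floored <= 0] <- zero_weight_floor
  cnt <- table$counts[sc]
  use <- cnt > 0 & !is.na(floored[sc])
  if (!any(use)) stop("no eligible codon occurrences; CAI undefined")
  exp(sum(cnt[use] * log(floored[sc][use])) / sum(cnt[use]))
}

#' Third-position SCUB profile of a codon count table
#'
#' Computes, over the 59-SC universe: per-codon relative frequencies, RSCU,
#' CAI, terminal-base frequencies (fractions of codons ending in A, T, C, G),
#' per-amino-acid NNC/G-to-NNA/T ratios for the 18 multi-codon families, and
#' the global NNC/G-to-NNA/T ratio.
#'
#' @param table A `codon_count_table` with `eligible_total > 0`.
#' @return A `scub_profile`: list with `per_codon_freq`, `rscu`, `cai`,
#'   `per_aa_ratio` (named by one-letter amino-acid code; `NA` when a family
#'   has no A/T-ending occurrences), `terminal_freq` (named `A`,`T`,`C`,`G`)
#'   and `nncg_to_nnat`.
#' @export
scub_profile <- function(table) {
  if (table$eligible_total <= 0L) stop("empty table: no eligible codons")
  sc <- synonymous_codons()
  cnt <- table$counts[sc]
  denom <- table$denominator_total
  per_codon_freq <- cnt / denom

  tb <- third_base(sc)
  terminal <- vapply(c(A = "A", T = "T", C = "C", G = "G"),
                     function(b) sum(cnt[tb == b]) / denom, numeric(1))

  fam <- sc_families()
  per_aa <- vapply(fam, function(codons) {
    b <- third_base(codons)
    at <- sum(table$counts[codons[b %in% c("A", "T")]])
    cg <- sum(table$counts[codons[b %in% c("C", "G")]])
    if (at == 0L) NA_real_ else cg / at
  }, numeric(1))

  at_tot <- sum(cnt[tb %in% c("A", "T")])
  cg_tot <- sum(cnt[tb %in% c("C", "G")])

  structure(list(
    per_codon_freq = per_codon_freq,
    rscu = rscu(table),
    cai = cai(table),
    per_aa_ratio = per_aa,
    terminal_freq = terminal,
    nncg_to_nnat = if (at_tot == 0L) NA_real_ else cg_tot / at_tot
  ), class = "scub_profile")
}

#' Genomic and gene-body GC/AT composition ratios
#'
#' Simple base-composition ratios for comparing the third-position
#' NNC/G-to-NNA/T ratio with overall composition: (G+C)/(A+T) over the whole
#' genome sequence and over the concatenated spliced CDS (gene body).
#'
#' @param record A `plastome_record`.
#' @param models Gene models of the record.
#' @return List with `genome_gc_at`, `gene_body_gc_at` and `nncg_to_nnat`
#'   (third-position ratio from the pooled codon table of `models`).
#' @export
gc_vs_at_genomic <- function(record, models) {
  gc_at <- function(s) {
    b <- strsplit(s, "")[[1]]
    gc <- sum(b %in% c("G", "C"))
    at <- sum(b %in% c("A", "T"))
    if (at == 0L) {
      if (gc == 0L) NA_real_ else Inf
    } else gc / at
  }
  keep <- Filter(function(m) isTRUE(m$passes_filter), models)
  body <- paste(vapply(keep, `[[`, character(1), "spliced_cds"), collapse = "")
  tab <- count_codons(models)
  nn <- if (tab$eligible_total > 0L) scub_profile(tab)$nncg_to_nnat else NA_real_
  list(genome_gc_at = gc_at(record$sequence),
       gene_body_gc_at = gc_at(body),
       nncg_to_nnat = nn)
}
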