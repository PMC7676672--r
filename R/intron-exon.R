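# Intron/exon-resolved codon usage. The key rule: a codon interrupted by an
# intron after its first nucleotide (phase 1|2) belongs to the downstream
# exon; interrupted after its second nucleotide (phase 2|1) it belongs to the
# upstream exon.

#' Assign each codon of a gene to an exon
#'
#' Walks the spliced CDS against the cumulative exon lengths. A codon fully
#' inside one exon belongs to it; split codons follow the 1|2-downstream /
#' 2|1-upstream rule. (In the degenerate case of a codon spanning three
#' exons — only possible with a 1-nt middle exon — the middle exon is used.)
#'
#' @param model A filtered `gene_model`.
#' @return An `exon_codon_partition`: list with `gene_name`, `codon_exon`
#'   (integer vector: the assigned exon rank of every codon, in order),
#'   `codons` (character vector of codon triplets), and `assignment_log`
#'   (data frame of split codons: `codon_index`, `split_phase` (1 or 2),
#'   `assigned_exon`).
#' @export
partition_codons <- function(model) {
  if (!isTRUE(model$passes_filter)) stop("gene does not pass the length filter")
  exon_len <- model$exons$end - model$exons$start + 1L
  # origin-wrapping exons have end < start; compute via spliced length share
  if (any(exon_len <= 0L)) {
    exon_len <- .exon_lengths(model)
  }
  if (any(exon_len <= 0L)) stop("exon of length 0")
  codons <- codon_split(model$spliced_cds)
  bounds <- cumsum(exon_len)
  exon_of <- function(pos) findInterval(pos - 1L, bounds) + 1L

  n <- length(codons)
  codon_exon <- integer(n)
  log_rows <- list()
  for (i in seq_len(n)) {
    p1 <- 3L * i - 2L
    e1 <- exon_of(p1); e2 <- exon_of(p1 + 1L); e3 <- exon_of(p1 + 2L)
    if (e1 == e3) {
      codon_exon[[i]] <- e1
    } else if (e2 == e3) {            # split after nt 1 -> downstream exon
      codon_exon[[i]] <- e2
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(codon_index = i, split_phase = 1L, assigned_exon = e2)
    } else if (e1 == e2) {            # split after nt 2 -> upstream exon
      codon_exon[[i]] <- e1
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(codon_index = i, split_phase = 2L, assigned_exon = e1)
    } else {                          # spans three exons: middle
      codon_exon[[i]] <- e2
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(codon_index = i, split_phase = NA_integer_, assigned_exon = e2)
    }
  }
  structure(list(
    gene_name = model$gene_name,
    codon_exon = codon_exon,
    codons = codons,
    assignment_log = if (length(log_rows)) do.call(rbind, log_rows) else
      data.frame(codon_index = integer(0), split_phase = integer(0),
                 assigned_exon = integer(0))
  ), class = "exon_codon_partition")
}

# internal: exon lengths robust to origin wrap (uses spliced length check)
.exon_lengths <- function(model) {
  len <- model$exons$end - model$exons$start + 1L
  total <- nchar(model$spliced_cds)
  wrap <- which(len <= 0L)
  if (length(wrap)) {
    other <- sum(len[-wrap])
    len[wrap] <- total - other  # single wrapping exon supported
  }
  len
}

# internal: pooled eligible A/T vs C/G third-base counts for a codon vector,
# given which codons are internal (positions 2..n-1)
.at_cg_counts <- function(codons, internal_idx) {
  internal <- codons[internal_idx]
  eligible <- internal[vapply(internal, .codon_class, character(1)) == "eligible"]
  tb <- third_base(eligible)
  c(A = sum(tb == "A"), T = sum(tb == "T"),
    C = sum(tb == "C"), G = sum(tb == "G"))
}

#' NNC/G-to-NNA/T ratio by intron class
#'
#' Groups filtered genes by intron number, pools eligible internal codons per
#' group (same eligibility as [count_codons()]), and reports the ratio of
#' C/G-ending to A/T-ending codons per class.
#'
#' @param models List of `gene_model` objects.
#' @param per_gene Logical; if `TRUE` the per-class value is the mean of
#'   per-gene ratios instead of the codon-pooled ratio (default pooled, which
#'   is what count-based chi-square testing uses).
#' @return Data frame: `intron_class`, `n_genes`, `NNA`, `NNT`, `NNC`, `NNG`,
#'   `ratio`. Classes with no eligible A/T-ending codons report `NA`.
#' @export
scub_by_intron_class <- function(models, per_gene = FALSE) {
  keep <- Filter(function(m) isTRUE(m$passes_filter), models)
  if (!length(keep)) {
    return(data.frame(intron_class = integer(0), n_genes = integer(0),
                      NNA = integer(0), NNT = integer(0), NNC = integer(0),
                      NNG = integer(0), ratio = numeric(0)))
  }
  introns <- vapply(keep, `[[`, integer(1), "intron_count")
  out <- lapply(sort(unique(introns)), function(k) {
    grp <- keep[introns == k]
    per <- lapply(grp, function(m) {
      codons <- codon_split(m$spliced_cds)
      n <- length(codons)
      .at_cg_counts(codons, if (n > 2L) 2:(n - 1L) else integer(0))
    })
    tot <- Reduce(`+`, per)
    at <- tot[["A"]] + tot[["T"]]; cg <- tot[["C"]] + tot[["G"]]
    ratio <- if (per_gene) {
      r <- vapply(per, function(x) {
        a <- x[["A"]] + x[["T"]]
        if (a == 0L) NA_real_ else (x[["C"]] + x[["G"]]) / a
      }, numeric(1))
      mean(r, na.rm = TRUE)
    } else if (at == 0L) NA_real_ else cg / at
    data.frame(intron_class = k, n_genes = length(grp),
               NNA = tot[["A"]], NNT = tot[["T"]],
               NNC = tot[["C"]], NNG = tot[["G"]], ratio = ratio)
  })
  do.call(rbind, out)
}

#' NNC/G-to-NNA/T ratio by exon position
#'
#' Restricts to genes with exactly `intron_count` introns, assigns codons to
#' exons via [partition_codons()], pools eligible codons across genes by mRNA
#' exon rank, and reports the ratio per rank.
#'
#' @param models List of `gene_model` objects.
#' @param intron_count Intron class to analyse (number of exons minus 1).
#' @return Data frame: `exon_rank`, `NNA`, `NNT`, `NNC`, `NNG`, `ratio`
#'   (ordered by rank; `NA` ratio when a rank has no A/T-ending codons).
#' @export
scub_by_exon_position <- function(models, intron_count) {
  keep <- Filter(function(m) {
    isTRUE(m$passes_filter) && m$intron_count == intron_count
  }, models)
  if (!length(keep)) stop("no filtered genes with ", intron_count, " introns")
  n_ranks <- intron_count + 1L
  acc <- matrix(0L, nrow = n_ranks, ncol = 4L,
                dimnames = list(NULL, c("A", "T", "C", "G")))
  for (m in keep) {
    part <- partition_codons(m)
    n <- length(part$codons)
    internal <- if (n > 2L) 2:(n - 1L) else integer(0)
    for (i in internal) {
      codon <- part$codons[[i]]
      if (.codon_class(codon) != "eligible") next
      b <- third_base(codon)
      r <- part$codon_exon[[i]]
      acc[r, b] <- acc[r, b] + 1L
    }
  }
  at <- acc[, "A"] + acc[, "T"]
  cg <- acc[, "C"] + acc[, "G"]
  data.frame(exon_rank = seq_len(n_ranks),
             NNA = acc[, "A"], NNT = acc[, "T"],
             NNC = acc[, "C"], NNG = acc[, "G"],
             ratio = ifelse(at == 0L, NA_real_, cg / at))
}
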