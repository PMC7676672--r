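# Synthetic annotated-plastome generator with known ground truth.
#
# Genes are built codon-by-codon: amino acid uniform over the 18 multi-codon
# families, then a within-family synonymous choice that ends in A/T with
# probability theta (the third-position A/T preference). With theta the only
# bias, the expected NNC/G-to-NNA/T ratio is (1 - theta) / theta, which is
# what recovery tests check. Introns are inserted at random in-gene positions
# (>= 3 nt from either end) so split-codon phases are exercised while start
# and stop codons stay intact.

#' Ground-truth parameter set for the synthetic generator
#'
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param n_genes_by_intron_class Named integer vector: genes per intron
#'   class, e.g. `c("0" = 70, "1" = 11, "2" = 4)`.
#' @param theta Third-position A/T preference in (0, 1): probability that a
#'   synonymous choice ends in A or T. Scalar (global); an unnamed vector is
#'   recycled over mRNA exon ranks (exon-rank-dependent bias); a vector
#'   named by one-letter amino-acid codes sets a per-family bias profile.
#' @param atypical_start_rate Probability a gene starts with ACG instead of
#'   ATG.
#' @param internal_stop_rate Expected number of internal stop codons (TAA)
#'   per gene (Poisson).
#' @param cpg_depletion Probability in [0, 1] that a codon-junction CpG
#'   (third base C followed by a codon starting with G) is deaminated:
#'   the focal third base C converts to T (sense-strand 5mC -> T;
#'   synonymous for every NNC). The expected NC|G / NG|G junction ratio
#'   scales by (1 - cpg_depletion).
#' @param ncg_depletion Probability in [0, 1] that a codon-internal CpG
#'   (second base C, third base G) is deaminated on the antisense strand:
#'   NCG -> NCA (synonymous for all four NCG codons). Drives the NCG/NCC
#'   and NCG/NCA deficits.
#' @param mean_gene_len_codons Mean gene length in codons (Poisson; floor
#'   10). Must be >= 3.
#' @param minus_strand_prob Probability a gene is placed on the minus
#'   strand.
#' @param wrap_gene If `TRUE`, the assembled circular genome is rotated so
#'   that the first gene spans the origin (exercises wrap-around
#'   coordinates).
#' @param accession,organism Record identifiers.
#' @return A `synthetic_truth` list echoing all parameters.
#' @export
synthetic_truth <- function(seed = 1L,
                            n_genes_by_intron_class = c("0" = 20L, "1" = 4L, "2" = 2L),
                            theta = 0.5,
                            atypical_start_rate = 0,
                            internal_stop_rate = 0,
                            cpg_depletion = 0,
                            ncg_depletion = 0,
                            mean_gene_len_codons = 250L,
                            minus_strand_prob = 0.3,
                            wrap_gene = FALSE,
                            accession = sprintf("SYN_%06d", seed),
                            organism = "Synthetica plastomica") {
  stopifnot(all(theta > 0 & theta < 1),
            atypical_start_rate >= 0, atypical_start_rate <= 1,
            cpg_depletion >= 0, cpg_depletion <= 1,
            ncg_depletion >= 0, ncg_depletion <= 1,
            internal_stop_rate >= 0,
            all(n_genes_by_intron_class >= 0))
  if (mean_gene_len_codons < 3) stop("genes must be at least 3 codons long")
  if (!is.null(names(theta))) {
    fam_codes <- sort(unique(unname(genetic_code()[synonymous_codons()])))
    if (!setequal(names(theta), fam_codes)) {
      stop("named theta must cover exactly the 18 multi-codon amino acids")
    }
  }
  structure(list(
    seed = as.integer(seed),
    n_genes_by_intron_class = n_genes_by_intron_class,
    theta = theta,
    atypical_start_rate = atypical_start_rate,
    internal_stop_rate = internal_stop_rate,
    cpg_depletion = cpg_depletion,
    ncg_depletion = ncg_depletion,
    mean_gene_len_codons = mean_gene_len_codons,
    minus_strand_prob = minus_strand_prob,
    wrap_gene = wrap_gene,
    accession = accession,
    organism = organism
  ), class = "synthetic_truth")
}

# run code under a local RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# internal: codon families split by third-base class, fixed at load time
.family_split <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fam <- sc_families()
      cache <<- lapply(fam, function(codons) {
        b <- third_base(codons)
        list(at = codons[b %in% c("A", "T")], cg = codons[b %in% c("C", "G")])
      })
    }
    cache
  }
})

# internal: draw n internal codons with third-position A/T probability theta
# (scalar, or named per-amino-acid vector)
.draw_codons <- function(n, theta) {
  fams <- .family_split()
  fam_idx <- sample.int(length(fams), n, replace = TRUE)
  th <- if (!is.null(names(theta))) {
    unname(theta[names(fams)[fam_idx]])
  } else {
    rep(theta, length.out = n)
  }
  pick_at <- stats::runif(n) < th
  vapply(seq_len(n), function(i) {
    f <- fams[[fam_idx[[i]]]]
    pool <- if (pick_at[[i]]) f$at else f$cg
    pool[[sample.int(length(pool), 1L)]]
  }, character(1))
}

# internal: one gene as (cds codons, intron positions in CDS-nt coordinates)
.draw_gene <- function(truth, intron_count) {
  len <- max(10L, stats::rpois(1L, truth$mean_gene_len_codons))
  n_nt <- 3L * len

  # intron insertion points: intron k falls after CDS nt position p_k
  positions <- integer(0)
  if (intron_count > 0L) {
    lo <- 4L
    hi <- n_nt - 4L
    positions <- sort(sample(seq.int(lo, hi), intron_count))
  }
  exon_len <- diff(c(0L, positions, n_nt))

  # per-codon exon rank (same split rule the analysis uses), for per-rank theta
  bounds <- cumsum(exon_len)
  exon_of <- function(pos) findInterval(pos - 1L, bounds) + 1L
  rank_of_codon <- vapply(seq_len(len), function(i) {
    p1 <- 3L * i - 2L
    e1 <- exon_of(p1); e2 <- exon_of(p1 + 1L); e3 <- exon_of(p1 + 2L)
    if (e1 == e3) e1 else if (e2 == e3) e2 else e1
  }, integer(1))
  per_family <- !is.null(names(truth$theta))
  theta_by_rank <- if (per_family) NULL else
    rep(truth$theta, length.out = length(exon_len))

  codons <- character(len)
  codons[[1]] <- if (stats::runif(1) < truth$atypical_start_rate) "ACG" else "ATG"
  codons[[len]] <- sample(stop_codons(), 1L)
  internal <- seq.int(2L, len - 1L)
  if (per_family) {
    codons[internal] <- .draw_codons(length(internal), truth$theta)
  } else {
    for (r in unique(rank_of_codon[internal])) {
      idx <- internal[rank_of_codon[internal] == r]
      codons[idx] <- .draw_codons(length(idx), theta_by_rank[[r]])
    }
  }

  if (truth$internal_stop_rate > 0) {
    n_stop <- stats::rpois(1L, truth$internal_stop_rate)
    n_stop <- min(n_stop, length(internal))
    if (n_stop > 0L) {
      codons[sample(internal, n_stop)] <- "TAA"
    }
  }

  if (truth$cpg_depletion > 0 || truth$ncg_depletion > 0) {
    for (i in internal) {
      codon <- codons[[i]]
      if (.codon_class(codon) != "eligible") next
      # codon-internal CpG (2nd C, 3rd G): antisense 5mC deamination, NCG -> NCA
      if (truth$ncg_depletion > 0 && substr(codon, 2L, 3L) == "CG" &&
          stats::runif(1) < truth$ncg_depletion) {
        codons[[i]] <- paste0(substr(codon, 1L, 2L), "A")
        next
      }
      # junction CpG (3rd C, next codon starts G): sense deamination, C -> T
      if (truth$cpg_depletion > 0 && i + 1L <= len &&
          substr(codon, 3L, 3L) == "C" &&
          substr(codons[[i + 1L]], 1L, 1L) == "G" &&
          stats::runif(1) < truth$cpg_depletion) {
        codons[[i]] <- paste0(substr(codon, 1L, 2L), "T")
      }
    }
  }

  list(codons = codons, intron_positions = positions)
}

# internal: random intron / spacer sequence, AT-rich like plastid DNA
.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(0.33, 0.17, 0.17, 0.33)), collapse = "")
}

#' Generate a synthetic annotated plastome record
#'
#' Builds the configured gene architecture, assembles a genome with random
#' intergenic spacers and intron sequences, and returns a `plastome_record`
#' carrying CDS features with correct compound locations (plus the truth
#' echo). Deterministic for a fixed seed: the same truth yields
#' byte-identical GenBank output via [write_genbank()].
#'
#' @param truth A `synthetic_truth`.
#' @return List with `record` (a `plastome_record`) and `truth`.
#' @export
generate_record <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  .with_seed(truth$seed, {
    classes <- truth$n_genes_by_intron_class
    plan <- rep(as.integer(names(classes)), times = classes)

    seq_parts <- character(0)
    offset <- 0L
    features <- list()
    add <- function(s) {
      seq_parts[[length(seq_parts) + 1L]] <<- s
      offset <<- offset + nchar(s)
    }

    for (gi in seq_along(plan)) {
      add(.random_dna(sample(100:300, 1L)))
      g <- .draw_gene(truth, plan[[gi]])
      cds <- paste(g$codons, collapse = "")
      n_nt <- nchar(cds)

      # pre-mRNA: CDS with introns spliced in after each insertion point
      cuts <- c(0L, g$intron_positions, n_nt)
      exon_seqs <- substring(cds, cuts[-length(cuts)] + 1L, cuts[-1L])
      introns <- vapply(seq_along(g$intron_positions),
                        function(i) .random_dna(sample(80:200, 1L)), character(1))
      pre <- exon_seqs[[1]]
      for (i in seq_along(introns)) pre <- paste0(pre, introns[[i]], exon_seqs[[i + 1L]])
      pre_len <- nchar(pre)

      # local exon spans on the pre-mRNA (sense) strand
      local_start <- integer(0); local_end <- integer(0)
      pos <- 0L
      for (i in seq_along(exon_seqs)) {
        local_start[[i]] <- pos + 1L
        local_end[[i]] <- pos + nchar(exon_seqs[[i]])
        pos <- local_end[[i]] + if (i <= length(introns)) nchar(introns[[i]]) else 0L
      }

      strand <- if (stats::runif(1) < truth$minus_strand_prob) "-" else "+"
      g0 <- offset  # 0-based genome offset of the gene segment
      if (strand == "+") {
        add(pre)
        parts <- data.frame(start = g0 + local_start, end = g0 + local_end)
      } else {
        add(revcomp(pre))
        parts <- data.frame(start = g0 + pre_len - local_end + 1L,
                            end = g0 + pre_len - local_start + 1L)
      }
      features[[length(features) + 1L]] <- list(
        gene = sprintf("syn%03d", gi), strand = strand, parts = parts,
        pseudo = FALSE,
        location_text = NA_character_
      )
    }
    add(.random_dna(sample(100:300, 1L)))
    genome <- paste(seq_parts, collapse = "")

    record <- structure(list(
      accession = truth$accession, organism = truth$organism,
      sequence = genome, length = nchar(genome), circular = TRUE,
      features = features
    ), class = "plastome_record")

    if (isTRUE(truth$wrap_gene) && length(features)) {
      record <- .rotate_origin(record,
                               shift = features[[1]]$parts$start[[1]] + 3L)
    }
    list(record = record, truth = truth)
  })
}

# internal: rotate a circular record so position `shift`+1 becomes position 1;
# features whose parts then straddle the origin get start > end (wrap form)
.rotate_origin <- function(record, shift) {
  n <- record$length
  shift <- ((shift - 1L) %% n) + 1L
  remap <- function(x) ((x - shift - 1L) %% n) + 1L
  record$sequence <- paste0(substr(record$sequence, shift + 1L, n),
                            substr(record$sequence, 1L, shift))
  record$features <- lapply(record$features, function(f) {
    f$parts$start <- remap(f$parts$start)
    f$parts$end <- remap(f$parts$end)
    f
  })
  record
}

#' Per-family third-position A/T preference profiles for the presets
#'
#' Fixed per-amino-acid theta profiles with mean about 0.73, spanning
#' roughly 0.64-0.79 so the implied per-family NNC/G-to-NNA/T ratios
#' (1-theta)/theta span about 0.27-0.56 — the heterogeneity observed across
#' amino acids in chloroplast genes. The two genus profiles differ modestly
#' but systematically (most visibly Leu, biased more strongly in the cotton
#' profile, and Ser, more strongly in the wheat profile), so synthetic
#' congeners share a near-identical profile while the two genera remain
#' distinguishable — the structure the cross-species consistency statistics
#' and the ordination rest on.
#'
#' @param taxon `"cotton"` or `"wheat"`.
#' @return Named numeric vector over the 18 multi-codon amino acids.
#' @export
chloroplast_theta_profile <- function(taxon = c("cotton", "wheat")) {
  taxon <- match.arg(taxon)
  switch(taxon,
    cotton = c(A = 0.74, C = 0.72, D = 0.76, E = 0.75, F = 0.77, G = 0.70,
               H = 0.75, I = 0.78, K = 0.76, L = 0.66, N = 0.77, P = 0.64,
               Q = 0.74, R = 0.72, S = 0.69, T = 0.73, V = 0.72, Y = 0.76),
    wheat = c(A = 0.76, C = 0.74, D = 0.79, E = 0.77, F = 0.74, G = 0.73,
              H = 0.73, I = 0.785, K = 0.785, L = 0.70, N = 0.745, P = 0.645,
              Q = 0.72, R = 0.69, S = 0.655, T = 0.75, V = 0.70, Y = 0.775)
  )
}

# internal: compensate the per-family draw theta so that after CpG
# deamination the realized NNC/G-to-NNA/T ratio of every family still
# matches the profile target. Both channels move a C/G-ending codon into
# the A/T pool: the NCG codon of a family converts with probability d_ncg,
# and each C-ending codon converts with probability d_cpg * P(successor
# starts with G). With q = expected converted fraction of the family's C/G
# pool, solving (1-th)(1-q) = r (th + (1-th) q) for th gives th = c/(c+r)
# with c = 1 - q (1+r).
.depletion_adjusted_theta <- function(profile, d_cpg, d_ncg) {
  if (d_cpg <= 0 && d_ncg <= 0) return(profile)
  fams <- .family_split()
  # P(successor codon starts with G) under uniform family choice: fraction
  # of families all of whose codons start with G (Ala, Asp, Glu, Gly, Val)
  p_g <- mean(vapply(fams, function(f) {
    all(substr(c(f$at, f$cg), 1L, 1L) == "G")
  }, logical(1)))
  for (aa in names(profile)) {
    cg <- fams[[aa]]$cg
    k <- length(cg)
    n_ncg <- sum(substr(cg, 2L, 3L) == "CG")
    n_c <- sum(substr(cg, 3L, 3L) == "C")
    q <- (d_ncg * n_ncg + d_cpg * p_g * n_c) / k
    r <- (1 - profile[[aa]]) / profile[[aa]]
    c_ <- 1 - q * (1 + r)
    profile[[aa]] <- c_ / (c_ + r)
  }
  profile
}

#' Synthetic-truth presets emulating the published gene architectures
#'
#' The cotton preset mirrors the Gossypium plastome architecture (about 70
#' intronless genes, 11 one-intron, 4 two-intron; one atypical ACG start);
#' the wheat preset mirrors the diploid Triticum/Aegilops architecture
#' (about 71 intronless, 7 one-intron, 1 two-intron). Both use a
#' per-family third-position A/T preference profile with mean theta = 0.73
#' (see [chloroplast_theta_profile()]), so the expected NNC/G-to-NNA/T ratio
#' (1 - theta)/theta is about 0.37, the magnitude observed in these
#' chloroplast genomes. CpG deamination runs at rate 0.3, reproducing the
#' observed NCG deficit (NCG/NCC well below 1) while the draw theta of the
#' four NCG-bearing families is compensated so their realized ratios still
#' follow the profile.
#'
#' @param taxon `"cotton"` or `"wheat"`.
#' @param seed Integer seed.
#' @param ... Overrides passed to [synthetic_truth()].
#' @return A `synthetic_truth`.
#' @export
emulate_paper_architecture <- function(taxon = c("cotton", "wheat"),
                                       seed = 1L, ...) {
  taxon <- match.arg(taxon)
  preset <- switch(taxon,
    cotton = list(
      n_genes_by_intron_class = c("0" = 70L, "1" = 11L, "2" = 4L),
      atypical_start_rate = 1 / 85,
      organism = "Gossypium syntheticum"
    ),
    wheat = list(
      n_genes_by_intron_class = c("0" = 71L, "1" = 7L, "2" = 1L),
      atypical_start_rate = 1 / 79,
      organism = "Triticum syntheticum"
    )
  )
  args <- utils::modifyList(
    c(list(seed = seed, theta = chloroplast_theta_profile(taxon),
           cpg_depletion = 0.3, ncg_depletion = 0.3,
           mean_gene_len_codons = 250L), preset),
    list(...)
  )
  args$theta <- .depletion_adjusted_theta(args$theta, args$cpg_depletion,
                                          args$ncg_depletion)
  do.call(synthetic_truth, args)
}

#' Generate a genus: one ancestral plastome plus diverged congeners
#'
#' Real congeneric chloroplast genomes are nearly identical in sequence, so
#' species of a genus are emulated as light synonymous mutants of a shared
#' ancestor rather than as independent draws: an ancestor record is generated
#' from `truth`, then each species redraws a small fraction of internal
#' codons (from the same per-family bias) in place, leaving gene
#' architecture, intergenic sequence and all coordinates untouched.
#'
#' @param truth A `synthetic_truth` describing the ancestor (its `seed`
#'   drives the whole genus deterministically).
#' @param n_species Number of congeners to derive.
#' @param divergence Per-codon probability that an internal codon is
#'   redrawn in a given species (default 0.01, the percent-scale CDS
#'   divergence typical of congeneric plastomes).
#' @param accessions Optional character vector of accessions (default
#'   `<ancestor accession>_1 ... _n`).
#' @return List of `n_species` elements, each as [generate_record()]:
#'   `record` plus `truth` (with `divergence` echoed).
#' @export
generate_genus <- function(truth, n_species, divergence = 0.01,
                           accessions = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"), n_species >= 1L,
            divergence >= 0, divergence <= 1)
  if (is.null(accessions)) {
    accessions <- sprintf("%s_%d", truth$accession, seq_len(n_species))
  }
  ancestor <- generate_record(truth)
  models <- build_gene_models(ancestor$record)
  .with_seed(truth$seed + 777L, {
    lapply(seq_len(n_species), function(j) {
      rec <- .mutate_record(ancestor$record, models, truth, divergence)
      rec$accession <- accessions[[j]]
      tr <- truth
      tr$accession <- accessions[[j]]
      tr$divergence <- divergence
      list(record = rec, truth = tr)
    })
  })
}

# internal: redraw a fraction of internal codons of every gene in place,
# writing the new bases back through the exon coordinate map (strand-aware)
.mutate_record <- function(record, models, truth, divergence) {
  seq_chars <- strsplit(record$sequence, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  for (m in models) {
    # genome position of every spliced-CDS base, in mRNA order
    pos <- unlist(lapply(seq_len(nrow(m$exons)), function(e) {
      s <- m$exons$start[[e]]; t <- m$exons$end[[e]]
      if (m$strand == "+") s:t else t:s
    }))
    n <- nchar(m$spliced_cds) %/% 3L
    if (n <= 2L) next
    hit <- which(stats::runif(n - 2L) < divergence) + 1L
    if (!length(hit)) next
    new_codons <- .draw_codons(length(hit), truth$theta)
    for (h in seq_along(hit)) {
      i <- hit[[h]]
      chars <- strsplit(new_codons[[h]], "")[[1]]
      if (m$strand == "-") chars <- comp[chars]
      seq_chars[pos[(3L * i - 2L):(3L * i)]] <- chars
    }
  }
  record$sequence <- paste(seq_chars, collapse = "")
  record
}

#' Write a synthetic record with its truth sidecar
#'
#' @param gen Result of [generate_record()].
#' @param dir Output directory (created if missing).
#' @return Named list of the two file paths (`genbank`, `truth`), invisibly.
#' @export
write_synthetic_record <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gb <- file.path(dir, paste0(gen$truth$accession, ".gb"))
  js <- file.path(dir, paste0(gen$truth$accession, ".truth.json"))
  write_genbank(gen$record, gb)
  jsonlite::write_json(unclass(gen$truth), js, auto_unbox = TRUE, digits = NA)
  invisible(list(genbank = gb, truth = js))
}
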