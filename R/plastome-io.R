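# GenBank flat-file I/O and gene-model extraction.
#
# No installed R package parses GenBank feature tables with compound
# join()/complement() locations, so the reader/writer live here. Coordinates
# are 1-based inclusive both internally and at the GenBank boundary (the R /
# IRanges idiom); split-codon arithmetic works on cumulative exon lengths, so
# no half-open convention is needed.

#' Read an annotated genome record from a GenBank flat file
#'
#' Captures the sequence, topology and every CDS feature, including compound
#' `join(...)` locations, `complement(...)` strands and `/pseudo` flags.
#'
#' @param path Path to a GenBank flat file containing one record.
#' @return A `plastome_record`: list with `accession`, `organism`, `sequence`
#'   (upper-case DNA string), `length`, `circular` (logical) and `features`
#'   (list of CDS feature descriptors with `gene`, `strand`, `parts` — a
#'   data frame of `start`/`end` genome coordinates in mRNA (5'->3') order —
#'   and `pseudo`).
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[[1]])) {
    stop("not a GenBank flat file (missing LOCUS line): ", path)
  }

  locus <- strsplit(trimws(sub("^LOCUS", "", lines[[1]])), "\\s+")[[1]]
  circular <- any(tolower(locus) == "circular")
  name <- locus[[1]]

  accession <- name
  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc_line)) {
    tok <- strsplit(trimws(sub("^ACCESSION", "", acc_line[[1]])), "\\s+")[[1]]
    if (length(tok) && nzchar(tok[[1]])) accession <- tok[[1]]
  }

  organism <- NA_character_
  org_line <- grep("^\\s+ORGANISM", lines, value = TRUE)
  if (length(org_line)) organism <- trimws(sub("^\\s+ORGANISM", "", org_line[[1]]))

  feat_start <- grep("^FEATURES", lines)
  origin_start <- grep("^ORIGIN", lines)
  if (!length(origin_start)) stop("malformed GenBank file (no ORIGIN): ", path)

  # sequence: numbered 60-base lines until "//"
  seq_lines <- lines[seq.int(origin_start[[1]] + 1L, length(lines))]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nchar(sequence)) stop("malformed GenBank file (empty ORIGIN): ", path)

  features <- list()
  if (length(feat_start)) {
    feat_lines <- lines[seq.int(feat_start[[1]] + 1L, origin_start[[1]] - 1L)]
    features <- .parse_cds_features(feat_lines, nchar(sequence))
  }
  if (!length(features)) {
    warning("no CDS features in record ", accession)
  }

  structure(
    list(accession = accession, organism = organism, sequence = sequence,
         length = nchar(sequence), circular = circular, features = features),
    class = "plastome_record"
  )
}

# internal: collect CDS feature blocks (key at column 6, qualifiers indented)
.parse_cds_features <- function(feat_lines, seq_len) {
  key_idx <- grep("^ {5}\\S", feat_lines)
  features <- list()
  for (i in seq_along(key_idx)) {
    first <- key_idx[[i]]
    last <- if (i < length(key_idx)) key_idx[[i + 1L]] - 1L else length(feat_lines)
    block <- feat_lines[first:last]
    key <- strsplit(trimws(block[[1]]), "\\s+")[[1]][[1]]
    if (key != "CDS") next

    # location may continue over lines until the first qualifier
    qual_at <- grep("^\\s+/", block)
    loc_end <- if (length(qual_at)) qual_at[[1]] - 1L else length(block)
    loc_text <- paste(trimws(sub("^ {5}CDS", "", block[1:loc_end])), collapse = "")

    loc <- tryCatch(
      parse_genbank_location(loc_text),
      error = function(e) stop("cannot parse CDS location near line: ",
                               trimws(block[[1]]), " (", conditionMessage(e), ")")
    )

    quals <- paste(block[seq_along(block) > loc_end], collapse = "\n")
    gene <- NA_character_
    m <- regmatches(quals, regexpr('/gene="[^"]*"', quals))
    if (length(m) && nzchar(m)) gene <- sub('/gene="([^"]*)"', "\\1", m)
    if (is.na(gene)) {
      m <- regmatches(quals, regexpr('/locus_tag="[^"]*"', quals))
      if (length(m) && nzchar(m)) gene <- sub('/locus_tag="([^"]*)"', "\\1", m)
    }
    pseudo <- grepl("/pseudo\\b", quals)

    features[[length(features) + 1L]] <- list(
      gene = gene, strand = loc$strand, parts = loc$parts,
      pseudo = pseudo, location_text = loc_text
    )
  }
  features
}

#' Parse a GenBank location string
#'
#' Handles simple ranges, `join(...)`, `complement(...)` wrapped around a
#' join or a single range, part-level `complement(...)`, and partial-end
#' markers (`<`, `>`), which are stripped. Parts are returned in mRNA
#' (5'->3') order: for `complement(join(a..b, c..d))` that is the reverse of
#' the listed order, per GenBank semantics.
#'
#' @param text Location string, e.g. `"complement(join(10..20,30..44))"`.
#' @return List with `strand` (`"+"` or `"-"`) and `parts` (data frame of
#'   `start`, `end` genome coordinates, one row per exon in mRNA order).
#' @export
parse_genbank_location <- function(text) {
  s <- gsub("[<>[:space:]]", "", text)
  outer_comp <- FALSE
  if (grepl("^complement\\(.*\\)$", s)) {
    outer_comp <- TRUE
    s <- sub("^complement\\((.*)\\)$", "\\1", s)
  }
  if (grepl("^(join|order)\\(.*\\)$", s)) {
    s <- sub("^(join|order)\\((.*)\\)$", "\\2", s)
  }
  raw_parts <- strsplit(s, ",")[[1]]
  if (!length(raw_parts)) stop("empty location")

  parse_part <- function(p) {
    comp <- FALSE
    if (grepl("^complement\\(.*\\)$", p)) {
      comp <- TRUE
      p <- sub("^complement\\((.*)\\)$", "\\1", p)
    }
    if (grepl("^\\d+\\.\\.\\d+$", p)) {
      se <- as.integer(strsplit(p, "\\.\\.")[[1]])
    } else if (grepl("^\\d+$", p)) {
      se <- rep(as.integer(p), 2L)
    } else {
      stop("unsupported location part: ", p)
    }
    list(start = se[[1]], end = se[[2]], comp = comp)
  }
  parsed <- lapply(raw_parts, parse_part)
  comp_flags <- vapply(parsed, `[[`, logical(1), "comp")
  if (length(unique(comp_flags)) > 1L) stop("mixed-strand compound location")
  minus <- xor(outer_comp, comp_flags[[1]])

  parts <- data.frame(
    start = vapply(parsed, `[[`, integer(1), "start"),
    end = vapply(parsed, `[[`, integer(1), "end")
  )
  # mRNA order: outer complement reverses the listed order; part-level
  # complements are listed in transcript order already.
  if (outer_comp) parts <- parts[rev(seq_len(nrow(parts))), , drop = FALSE]
  rownames(parts) <- NULL
  list(strand = if (minus) "-" else "+", parts = parts)
}

#' Write a plastome record to a GenBank flat file
#'
#' Emits LOCUS, ACCESSION, SOURCE/ORGANISM, a FEATURES table with one CDS per
#' feature (locations in canonical `join`/`complement(join(...))` form) and a
#' numbered ORIGIN block. Round-trips through [read_genbank()].
#'
#' @param record A `plastome_record`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  stopifnot(inherits(record, "plastome_record"))
  out <- character(0)
  topo <- if (isTRUE(record$circular)) "circular" else "linear"
  out <- c(out, sprintf("LOCUS       %-18s%9d bp    DNA     %-8s PLN 01-JAN-2024",
                        record$accession, record$length, topo))
  out <- c(out, sprintf("DEFINITION  %s chloroplast, synthetic record.",
                        if (is.na(record$organism)) record$accession else record$organism))
  out <- c(out, sprintf("ACCESSION   %s", record$accession))
  out <- c(out, sprintf("SOURCE      %s", record$organism),
           sprintf("  ORGANISM  %s", record$organism))
  out <- c(out, "FEATURES             Location/Qualifiers")
  out <- c(out, sprintf("     source          1..%d", record$length))

  fmt_location <- function(f) {
    parts <- f$parts
    rng <- sprintf("%d..%d", parts$start, parts$end)
    if (f$strand == "-") {
      # genome-ascending listed order inside complement(): reverse mRNA order
      rng <- rev(rng)
      inner <- if (length(rng) > 1L) sprintf("join(%s)", paste(rng, collapse = ",")) else rng
      sprintf("complement(%s)", inner)
    } else {
      if (length(rng) > 1L) sprintf("join(%s)", paste(rng, collapse = ",")) else rng
    }
  }
  for (f in record$features) {
    out <- c(out, sprintf("     CDS             %s", fmt_location(f)))
    if (!is.na(f$gene)) out <- c(out, sprintf('                     /gene="%s"', f$gene))
    if (isTRUE(f$pseudo)) out <- c(out, "                     /pseudo")
  }

  out <- c(out, "ORIGIN")
  seq <- tolower(record$sequence)
  pos <- seq.int(1L, nchar(seq), by = 60L)
  for (p in pos) {
    chunk <- substr(seq, p, min(p + 59L, nchar(seq)))
    blocks <- substring(chunk, seq.int(1L, nchar(chunk), by = 10L),
                        pmin(seq.int(10L, nchar(chunk) + 9L, by = 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", p, paste(blocks, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

# internal: extract the genome slice for one exon part, handling circular wrap
.part_sequence <- function(sequence, start, end, circular) {
  n <- nchar(sequence)
  if (start <= end) return(substr(sequence, start, end))
  if (!circular) stop("descending coordinates in a linear record")
  paste0(substr(sequence, start, n), substr(sequence, 1L, end))
}

#' Build gene models from a parsed record
#'
#' One model per non-pseudo CDS feature: the spliced CDS is the concatenation
#' of exon slices in mRNA order, reverse-complemented on the minus strand.
#' Genes whose spliced length is not a multiple of 3 are retained with
#' `passes_filter = FALSE`; pseudo-flagged features and features with
#' out-of-range coordinates are dropped. Every dropped or failing CDS is
#' recorded in the rejection log (see [rejection_log()]).
#'
#' @param record A `plastome_record`.
#' @return List of `gene_model` objects with a `rejections` attribute
#'   (data frame: `accession`, `gene`, `reason`). Each model carries
#'   `gene_name`, `strand`, `exons` (data frame `start`, `end`, `rank`),
#'   `spliced_cds`, `intron_count`, `passes_filter`, `has_ambiguous`
#'   (non-ACGT base present), and — for filtered genes of length >= 6 —
#'   `start_class`, `stop_class`, `internal_stop_count`,
#'   `internal_stop_identities`.
#' @export
build_gene_models <- function(record) {
  stopifnot(inherits(record, "plastome_record"))
  models <- list()
  rej <- list()
  note <- function(gene, reason) {
    rej[[length(rej) + 1L]] <<- data.frame(
      accession = record$accession,
      gene = if (is.na(gene)) "" else gene, reason = reason
    )
  }

  for (f in record$features) {
    if (isTRUE(f$pseudo)) {
      note(f$gene, "pseudo flag")
      next
    }
    parts <- f$parts
    bad <- parts$start < 1L | parts$end < 1L |
      parts$start > record$length | parts$end > record$length
    if (any(bad)) {
      note(f$gene, "coordinates invalid")
      warning("skipping CDS ", f$gene, ": coordinates out of range")
      next
    }
    slices <- mapply(.part_sequence, parts$start, parts$end,
                     MoreArgs = list(sequence = record$sequence,
                                     circular = record$circular),
                     SIMPLIFY = TRUE)
    if (f$strand == "-") slices <- vapply(slices, revcomp, character(1))
    spliced <- paste(slices, collapse = "")

    model <- structure(
      list(
        gene_name = f$gene, strand = f$strand,
        exons = data.frame(start = parts$start, end = parts$end,
                           rank = seq_len(nrow(parts))),
        spliced_cds = spliced,
        intron_count = nrow(parts) - 1L,
        passes_filter = nchar(spliced) %% 3L == 0L,
        has_ambiguous = grepl("[^ACGT]", spliced)
      ),
      class = "gene_model"
    )
    if (!model$passes_filter) {
      note(f$gene, "length not divisible by 3")
    } else if (nchar(spliced) >= 6L) {
      model <- c(model, classify_termini(model))
      class(model) <- "gene_model"
    }
    models[[length(models) + 1L]] <- model
  }
  attr(models, "rejections") <- if (length(rej)) do.call(rbind, rej) else
    data.frame(accession = character(0), gene = character(0), reason = character(0))
  models
}

#' Rejection log of filtered-out CDS features
#' @param models Result of [build_gene_models()].
#' @return Data frame with columns `accession`, `gene`, `reason`.
#' @export
rejection_log <- function(models) {
  attr(models, "rejections")
}

#' Classify start codon, stop codon and internal stops of a gene
#'
#' The start is `"typical_ATG"` iff the first triplet is ATG, otherwise
#' `"atypical:<triplet>"`; the stop class is the final triplet, labelled
#' `"atypical:<triplet>"` unless it is TAA, TAG or TGA. Internal stops are
#' stop triplets at in-frame positions strictly between the first and last
#' codon.
#'
#' @param model A `gene_model` passing the length filter.
#' @return List with `start_class`, `stop_class`, `internal_stop_count`,
#'   `internal_stop_identities` (character vector, possibly empty).
#' @export
classify_termini <- function(model) {
  cds <- model$spliced_cds
  if (nchar(cds) %% 3L != 0L) stop("gene does not pass the length filter")
  if (nchar(cds) < 6L) stop("CDS shorter than two codons has no terminus structure")
  codons <- codon_split(cds)
  n <- length(codons)
  first <- codons[[1]]
  last <- codons[[n]]
  internal <- if (n > 2L) codons[2:(n - 1L)] else character(0)
  ist <- internal[internal %in% stop_codons()]
  list(
    start_class = if (first == "ATG") "typical_ATG" else paste0("atypical:", first),
    stop_class = if (last %in% stop_codons()) last else paste0("atypical:", last),
    internal_stop_count = length(ist),
    internal_stop_identities = ist
  )
}

#' Summarize gene structure across a set of gene models
#'
#' Tallies genes by intron number and start/stop/internal-stop codon
#' identities, over models passing the length filter.
#'
#' @param models List of `gene_model` objects (e.g. from
#'   [build_gene_models()]); models failing the filter are ignored.
#' @return A `gene_structure_summary`: list with `intron_class_counts`
#'   (named integer vector, names `"0"`, `"1"`, ...), `total`,
#'   `start_codon_tally`, `stop_codon_tally`, `internal_stop_tally`
#'   (named integer vectors of raw triplets).
#' @export
summarize_structure <- function(models) {
  keep <- Filter(function(m) isTRUE(m$passes_filter), models)
  if (!length(keep)) {
    return(structure(list(
      intron_class_counts = integer(0), total = 0L,
      start_codon_tally = integer(0), stop_codon_tally = integer(0),
      internal_stop_tally = integer(0)
    ), class = "gene_structure_summary"))
  }
  introns <- vapply(keep, `[[`, integer(1), "intron_count")
  firsts <- vapply(keep, function(m) substr(m$spliced_cds, 1L, 3L), character(1))
  lasts <- vapply(keep, function(m) {
    n <- nchar(m$spliced_cds)
    substr(m$spliced_cds, n - 2L, n)
  }, character(1))
  ist <- unlist(lapply(keep, function(m) m$internal_stop_identities %||% character(0)))
  tally <- function(x) {
    t <- table(x)
    stats::setNames(as.integer(t), names(t))
  }
  structure(list(
    intron_class_counts = tally(introns),
    total = length(keep),
    start_codon_tally = tally(firsts),
    stop_codon_tally = tally(lasts),
    internal_stop_tally = tally(ist)
  ), class = "gene_structure_summary")
}

#' Export the concatenated CDS of a record as FASTA
#'
#' Writes one FASTA entry per species: the spliced CDS of every filtered gene
#' concatenated in input order, the form used for whole-plastome codon-usage
#' indices.
#'
#' @param models List of `gene_model` objects.
#' @param name FASTA header (typically accession or organism).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(models, name, path) {
  keep <- Filter(function(m) isTRUE(m$passes_filter), models)
  cds <- paste(vapply(keep, `[[`, character(1), "spliced_cds"), collapse = "")
  x <- Biostrings::DNAStringSet(cds)
  names(x) <- name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
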