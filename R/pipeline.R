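# End-to-end orchestration: per-species SCUB analyses over one or many
# records, then cross-species statistics and ordination. All outputs are
# plain TSV / JSON / Newick so a rerun with identical inputs reproduces them
# byte for byte.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Analyse one species record
#'
#' Runs the per-species stages: gene models and filters, structure summary,
#' codon counting, SCUB profile, intron-class and exon-position ratios, and
#' methylation-context ratios.
#'
#' @param record A `plastome_record` (from [read_genbank()] or
#'   [generate_record()]).
#' @param include_internal_atg Passed to [count_codons()].
#' @return A `species_analysis`: list with `accession`, `organism`,
#'   `models`, `structure`, `table`, `profile`, `by_intron_class`,
#'   `by_exon_position` (list keyed by intron class >= 1), `context`,
#'   `composition` (from [gc_vs_at_genomic()]) and `rejections`.
#' @export
analyze_species <- function(record, include_internal_atg = FALSE) {
  models <- build_gene_models(record)
  table <- count_codons(models, include_internal_atg = include_internal_atg)
  by_intron <- scub_by_intron_class(models)
  classes <- by_intron$intron_class[by_intron$intron_class >= 1L]
  by_exon <- lapply(stats::setNames(classes, as.character(classes)),
                    function(k) scub_by_exon_position(models, k))
  structure(list(
    accession = record$accession,
    organism = record$organism,
    models = models,
    structure = summarize_structure(models),
    table = table,
    profile = scub_profile(table),
    by_intron_class = by_intron,
    by_exon_position = by_exon,
    context = context_ratio_set(models, table),
    composition = gc_vs_at_genomic(record, models),
    rejections = rejection_log(models)
  ), class = "species_analysis")
}

# internal: flat per-species summary row
.species_summary_row <- function(an) {
  pr <- an$profile
  data.frame(
    accession = an$accession,
    organism = an$organism,
    n_genes = an$structure$total,
    eligible_codons = an$table$eligible_total,
    cai = pr$cai,
    nncg_to_nnat = pr$nncg_to_nnat,
    freq_NNA = pr$terminal_freq[["A"]],
    freq_NNT = pr$terminal_freq[["T"]],
    freq_NNC = pr$terminal_freq[["C"]],
    freq_NNG = pr$terminal_freq[["G"]],
    mean_per_aa_ratio = mean(pr$per_aa_ratio, na.rm = TRUE),
    genome_gc_at = an$composition$genome_gc_at,
    gene_body_gc_at = an$composition$gene_body_gc_at
  )
}

#' Run the full SCUB pipeline over a set of records
#'
#' Per-species analyses plus, when two or more species are given, the
#' cross-species stages: per-amino-acid SCUB frequency correlations,
#' Cronbach's alpha of per-amino-acid frequencies, a one-sample t-test of
#' the per-amino-acid ratios against 1, average-linkage clustering on
#' correlation distance with the top-level two-clade split, PCA scores, and
#' (optionally) all report tables written under `out_dir`.
#'
#' @param records List of `plastome_record` objects, or character vector of
#'   GenBank file paths.
#' @param out_dir Optional output directory for the TSV/JSON/Newick report
#'   bundle; `NULL` skips writing.
#' @param matrix_mode `"frequency"` or `"rscu"` — values used for the
#'   species matrix in clustering/PCA.
#' @param include_internal_atg Passed to [count_codons()].
#' @return A `scub_pipeline_result`: list with `species` (named list of
#'   `species_analysis`), `summary` (one row per species) and — for >= 2
#'   species — `cross` (list with `matrix`, `distance`, `dendrogram`,
#'   `clades`, `pca` (>= 3 species), `pairwise_r`, `cronbach_alpha`,
#'   `t_vs_1`).
#' @export
run_scub_pipeline <- function(records, out_dir = NULL,
                              matrix_mode = c("frequency", "rscu"),
                              include_internal_atg = FALSE) {
  matrix_mode <- match.arg(matrix_mode)
  if (is.character(records)) records <- lapply(records, read_genbank)
  stopifnot(length(records) >= 1L)

  species <- lapply(records, analyze_species,
                    include_internal_atg = include_internal_atg)
  names(species) <- vapply(species, `[[`, character(1), "accession")
  summary_df <- do.call(rbind, lapply(species, .species_summary_row))
  rownames(summary_df) <- NULL

  cross <- NULL
  if (length(species) >= 2L) {
    tables <- lapply(species, `[[`, "table")
    m <- species_matrix(tables, mode = matrix_mode)
    d <- correlation_distance(m)
    hc <- average_linkage(d)

    # pairwise Pearson r of per-amino-acid SCUB frequencies
    aa_mat <- do.call(cbind, lapply(species, function(s) s$profile$per_aa_ratio))
    colnames(aa_mat) <- names(species)
    keep <- stats::complete.cases(aa_mat)
    aa_mat <- aa_mat[keep, , drop = FALSE]
    pairs <- utils::combn(colnames(aa_mat), 2L)
    pairwise_r <- data.frame(
      a = pairs[1L, ], b = pairs[2L, ],
      r = apply(pairs, 2L, function(p) {
        pearson_r(aa_mat[, p[[1]]], aa_mat[, p[[2]]])$statistic_r
      })
    )

    cross <- list(
      matrix = m,
      distance = d,
      dendrogram = hc,
      clades = top_clades(hc),
      pca = if (length(species) >= 3L) pca_scores(m) else NULL,
      pairwise_r = pairwise_r,
      cronbach_alpha = cronbach_alpha(aa_mat),
      t_vs_1 = t_one_sample(as.vector(aa_mat), 1)
    )
  } else {
    warning("single record: cross-species stages skipped")
  }

  result <- structure(list(species = species, summary = summary_df,
                           cross = cross, matrix_mode = matrix_mode),
                      class = "scub_pipeline_result")
  if (!is.null(out_dir)) write_report_bundle(result, out_dir)
  result
}

#' Write the report bundle of a pipeline result
#'
#' One subdirectory per species (codon table, amino-acid ratios, structure
#' and context-ratio TSVs) plus cross-species TSVs, the Newick dendrogram
#' and a JSON summary.
#'
#' @param result A `scub_pipeline_result`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report_bundle <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gcmap <- genetic_code()
  for (an in result$species) {
    sp_dir <- file.path(out_dir, an$accession)
    dir.create(sp_dir, showWarnings = FALSE)
    sc <- synonymous_codons()
    codon_df <- data.frame(
      codon = sc,
      amino_acid = unname(gcmap[sc]),
      count = unname(an$table$counts[sc]),
      frequency = unname(an$profile$per_codon_freq[sc]),
      rscu = unname(an$profile$rscu[sc])
    )
    .write_tsv(codon_df, file.path(sp_dir, "codon_table.tsv"))
    aa_df <- data.frame(aa = names(an$profile$per_aa_ratio),
                        nncg_to_nnat = unname(an$profile$per_aa_ratio))
    .write_tsv(aa_df, file.path(sp_dir, "amino_acid_ratios.tsv"))
    .write_tsv(an$by_intron_class, file.path(sp_dir, "scub_by_intron_class.tsv"))
    for (k in names(an$by_exon_position)) {
      .write_tsv(an$by_exon_position[[k]],
                 file.path(sp_dir, sprintf("scub_by_exon_intron%s.tsv", k)))
    }
    .write_tsv(an$context$second_pos, file.path(sp_dir, "second_position_ratios.tsv"))
    .write_tsv(an$context$junction, file.path(sp_dir, "junction_ratios.tsv"))
    .write_tsv(an$context$per_aa_gc, file.path(sp_dir, "per_aa_g_to_c.tsv"))
    .write_tsv(an$rejections, file.path(sp_dir, "rejections.tsv"))
  }
  .write_tsv(result$summary, file.path(out_dir, "species_summary.tsv"))
  if (!is.null(result$cross)) {
    .write_tsv(result$cross$pairwise_r, file.path(out_dir, "pairwise_r.tsv"))
    write_dendrogram_newick(result$cross$dendrogram,
                            file.path(out_dir, "dendrogram.nwk"))
    if (!is.null(result$cross$pca)) {
      sc_df <- data.frame(accession = rownames(result$cross$pca$scores),
                          result$cross$pca$scores)
      .write_tsv(sc_df, file.path(out_dir, "pca_scores.tsv"))
      .write_tsv(data.frame(component = seq_along(result$cross$pca$explained),
                            explained = result$cross$pca$explained),
                 file.path(out_dir, "pca_explained.tsv"))
    }
    jsonlite::write_json(
      list(cronbach_alpha = result$cross$cronbach_alpha,
           t_vs_1 = result$cross$t_vs_1[c("statistic", "p_value", "df")],
           clades = as.list(result$cross$clades)),
      file.path(out_dir, "cross_species_stats.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(out_dir)
}
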