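# Species ordination over 59-SC frequency or RSCU vectors: correlation
# distance, average-linkage (UPGMA-style) clustering with Newick export, and
# centered PCA with a fixed sign convention.

#' Species-by-codon matrix
#'
#' Builds the ordination input: one row per species, one column per codon in
#' the 59-SC universe; values are either per-codon relative frequencies
#' (each SC count over the total SC count, so rows sum to 1) or RSCU.
#'
#' @param tables Named list of `codon_count_table` objects (names = species).
#' @param mode `"frequency"` or `"rscu"`.
#' @return Numeric matrix (species x 59 codons).
#' @export
species_matrix <- function(tables, mode = c("frequency", "rscu")) {
  mode <- match.arg(mode)
  sc <- synonymous_codons()
  rows <- lapply(tables, function(t) {
    if (mode == "frequency") {
      cnt <- t$counts[sc]
      cnt / sum(cnt)
    } else {
      rscu(t)[sc]
    }
  })
  m <- do.call(rbind, rows)
  rownames(m) <- names(tables)
  colnames(m) <- sc
  if (anyNA(m)) stop("missing values in species matrix (empty codon family?)")
  m
}

#' Pairwise correlation distance
#'
#' d(i, j) = 1 - Pearson r between row profiles; 0 on the diagonal.
#'
#' @param m Numeric matrix with >= 2 rows.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
correlation_distance <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 rows")
  v <- apply(m, 1, stats::var)
  if (any(v == 0)) stop("zero-variance row: ", rownames(m)[which(v == 0)[1]])
  d <- 1 - stats::cor(t(m))
  diag(d) <- 0
  d
}

#' Average-linkage hierarchical clustering
#'
#' UPGMA-style agglomeration on a distance matrix (ties broken
#' deterministically by `stats::hclust`).
#'
#' @param d Symmetric distance matrix (e.g. from [correlation_distance()]).
#' @return An `hclust` object.
#' @export
average_linkage <- function(d) {
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d)))) stop("distance matrix is not symmetric")
  stats::hclust(stats::as.dist(d), method = "average")
}

#' Export a dendrogram as Newick
#' @param hc An `hclust` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Top-level clade membership of a dendrogram
#'
#' Cuts the tree at its root into two groups — used for the "two distinct
#' clades" claim.
#'
#' @param hc An `hclust` object.
#' @return Named integer vector of group labels (1 or 2) per leaf.
#' @export
top_clades <- function(hc) {
  stats::cutree(hc, k = 2)
}

#' PCA scores of a species matrix
#'
#' Column-centered PCA (covariance mode by default; `scale = TRUE` gives the
#' correlation-matrix variant). The sign of each component is fixed so that
#' its largest-magnitude loading is positive, making score plots
#' reproducible.
#'
#' @param m Numeric matrix (species x codons), >= 3 rows.
#' @param n_components Number of components to keep (default 3; truncated
#'   with a warning if the matrix rank is lower).
#' @param scale Standardize columns before PCA (default `FALSE`).
#' @return List with `scores` (species x components), `loadings`,
#'   `explained` (variance fractions per kept component).
#' @export
pca_scores <- function(m, n_components = 3L, scale = FALSE) {
  m <- as.matrix(m)
  if (nrow(m) < 3L) stop("need at least 3 rows")
  if (scale) {
    keep <- apply(m, 2, stats::var) > 0
    m <- m[, keep, drop = FALSE]
  }
  p <- stats::prcomp(m, center = TRUE, scale. = scale)
  rank <- sum(p$sdev > max(p$sdev) * 1e-10)
  k <- n_components
  if (k > rank) {
    warning("requested ", n_components, " components but rank is ", rank,
            "; truncating")
    k <- rank
  }
  scores <- p$x[, seq_len(k), drop = FALSE]
  loadings <- p$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    lead <- which.max(abs(loadings[, j]))
    if (loadings[lead, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  explained <- (p$sdev^2 / sum(p$sdev^2))[seq_len(k)]
  list(scores = scores, loadings = loadings, explained = explained)
}
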