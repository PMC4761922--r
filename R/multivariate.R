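# ---------------------------------------------------------------------------
# Multivariate views: PCA over samples, Pearson-distance hierarchical
# clustering over proteins
# ---------------------------------------------------------------------------

#' Principal component analysis of samples
#'
#' PCA on the normalized spectra with samples as observations and proteins
#' as variables, centered per protein and unscaled by default (the spectra
#' are already on a common scale after normalization; per-protein
#' z-scaling is available by flag). Proteins with zero variance across
#' samples are dropped with a message. The sign of each component is fixed
#' so that its largest-magnitude protein loading is positive, making
#' scores reproducible across platforms.
#'
#' @param norm a `normalized_table` (or `spectral_count_table`).
#' @param scale. z-scale each protein before the decomposition.
#' @return object of class `pca_result`: list with `scores` (samples x
#'   components), `loadings`, `var_explained` (fractions, non-increasing),
#'   `groups`, `n_dropped`.
#' @export
pca_samples <- function(norm, scale. = FALSE) {
  vals <- if (inherits(norm, "normalized_table")) norm$values
          else if (inherits(norm, "spectral_count_table")) norm$counts
          else stop("norm must be a normalized_table or spectral_count_table")
  if (ncol(vals) < 2) stop("PCA needs at least 2 samples")
  v <- apply(vals, 1, var)
  keep <- v > 0
  if (!any(keep)) stop("no protein varies across samples: nothing to decompose")
  if (any(!keep))
    message(sum(!keep), " zero-variance protein(s) dropped before PCA")
  x <- t(vals[keep, , drop = FALSE])
  pc <- prcomp(x, center = TRUE, scale. = scale.)
  # deterministic orientation: largest-|loading| protein positive per PC
  for (k in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[i, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, loadings = pc$rotation,
                 var_explained = ve, groups = norm$groups,
                 n_dropped = sum(!keep)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples, PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), 100 * x$var_explained[1],
              100 * x$var_explained[2]))
  invisible(x)
}

#' Hierarchical clustering of proteins by Pearson correlation
#'
#' Pairwise protein similarity is the Pearson correlation of their spectra
#' across samples; the clustering distance is `1 - r` (range 0 to 2) with
#' average linkage. Rows with zero variance (correlation undefined) are
#' excluded with a warning. The merge tree and leaf order drive heat-map
#' row arrangement; [dendrogram_newick()] serializes the tree.
#'
#' @param norm a `normalized_table` (or `spectral_count_table`).
#' @param subset optional accession subset to cluster (default all rows).
#' @return object of class `protein_dendrogram`: list with `hclust` (the
#'   merge tree), `labels`, `order` (leaf order, as accessions),
#'   `excluded` (zero-variance rows).
#' @export
hcluster_rows <- function(norm, subset = NULL) {
  vals <- if (inherits(norm, "normalized_table")) norm$values
          else if (inherits(norm, "spectral_count_table")) norm$counts
          else stop("norm must be a normalized_table or spectral_count_table")
  if (!is.null(subset)) {
    miss <- setdiff(subset, rownames(vals))
    if (length(miss) > 0)
      stop("protein(s) not in table: ", paste(miss, collapse = ", "))
    vals <- vals[subset, , drop = FALSE]
  }
  v <- apply(vals, 1, var)
  excluded <- rownames(vals)[v == 0]
  if (length(excluded) > 0) {
    warning(sprintf("%d zero-variance row(s) excluded from clustering",
                    length(excluded)))
    vals <- vals[v > 0, , drop = FALSE]
  }
  if (nrow(vals) < 2) stop("need at least 2 rows with variance to cluster")
  d <- as.dist(1 - cor(t(vals)))
  hc <- hclust(d, method = "average")
  structure(list(hclust = hc, labels = rownames(vals),
                 order = rownames(vals)[hc$order], excluded = excluded),
            class = "protein_dendrogram")
}

#' Serialize a protein dendrogram to Newick
#'
#' @param dend a `protein_dendrogram` from [hcluster_rows()].
#' @param path optional output path; when `NULL` the Newick string is
#'   returned invisibly without writing.
#' @return the Newick string, invisibly.
#' @export
dendrogram_newick <- function(dend, path = NULL) {
  stopifnot(inherits(dend, "protein_dendrogram"))
  phy <- ape::as.phylo(dend$hclust)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}
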