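# ---------------------------------------------------------------------------
# Hypergeometric over-representation per cluster and the dominant-term call
# ---------------------------------------------------------------------------

#' Upper-tail hypergeometric over-representation p-value
#'
#' Probability of drawing at least `k` annotated genes when `n` genes are
#' sampled without replacement from a universe of `N` genes of which `K`
#' carry the term: `p = sum_{i=k}^{min(K,n)} C(K,i) C(N-K,n-i) / C(N,n)`.
#' Each term of the sum is evaluated in log space via `lchoose` so large
#' universes do not overflow.
#'
#' @param N universe size.
#' @param K term genes in the universe.
#' @param n cluster size in the universe.
#' @param k overlap between cluster and term.
#' @return the upper-tail p-value in `(0, 1]`.
#' @export
hypergeom_test <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n))
    stop(sprintf("inconsistent counts: N=%d K=%d n=%d k=%d", N, K, n, k))
  if (k == 0) return(1)
  i <- k:min(K, n)
  logp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  p <- sum(exp(logp))
  min(p, 1)
}

#' Per-cluster term over-representation with a dominant-term call
#'
#' Tests every term with at least one gene in the universe against one
#' cluster with [hypergeom_test()], adjusts the p-values across the
#' cluster's tested terms by Benjamini-Hochberg, and calls the dominant
#' term: smallest adjusted p, ties resolved toward the larger overlap `k`,
#' then the lexicographically smallest `term_id`. Terms that do not touch
#' the cluster (k = 0) are tested (p = 1) but can never be dominant; a
#' cluster with no annotated member yields no dominant term. The dominant
#' row carries the conventional "k of n" label.
#'
#' @param members character vector of cluster gene symbols.
#' @param annotations an [annotation_table()].
#' @param universe character vector of universe gene symbols (must contain
#'   the cluster; conventionally all filter-passing proteins).
#' @return data.frame of class `enrichment_result` with columns term_id,
#'   term_name, namespace, N, K, n, k, p_value, adjusted_p, dominant,
#'   label; ordered by adjusted then raw p.
#' @export
enrich_cluster <- function(members, annotations, universe) {
  stopifnot(inherits(annotations, "annotation_table"))
  members <- unique(toupper(members))
  universe <- unique(toupper(universe))
  if (length(members) == 0) stop("cluster is empty")
  out_univ <- setdiff(members, universe)
  if (length(out_univ) > 0)
    stop("cluster member(s) outside the universe: ",
         paste(out_univ, collapse = ", "))
  ann <- as.data.frame(annotations)
  ann <- ann[ann$gene_symbol %in% universe, , drop = FALSE]
  if (nrow(ann) == 0) {
    message("no term has a gene in the universe; nothing to test")
    res <- data.frame(term_id = character(0), term_name = character(0),
                      namespace = character(0), N = integer(0), K = integer(0),
                      n = integer(0), k = integer(0), p_value = numeric(0),
                      adjusted_p = numeric(0), dominant = logical(0),
                      label = character(0), stringsAsFactors = FALSE)
    class(res) <- c("enrichment_result", "data.frame")
    return(res)
  }
  N <- length(universe)
  n <- length(members)
  terms <- split(ann$gene_symbol, ann$term_id)
  info <- ann[!duplicated(ann$term_id), c("term_id", "term_name", "namespace")]
  rownames(info) <- info$term_id
  tid <- names(terms)
  K <- lengths(terms)
  k <- vapply(terms, function(gs) length(intersect(gs, members)), integer(1))
  p <- mapply(hypergeom_test, N = N, K = K, n = n, k = k)
  adj <- p.adjust(p, method = "BH")
  res <- data.frame(term_id = tid,
                    term_name = info[tid, "term_name"],
                    namespace = info[tid, "namespace"],
                    N = N, K = as.integer(K), n = n, k = as.integer(k),
                    p_value = unname(p), adjusted_p = unname(adj),
                    stringsAsFactors = FALSE)
  res$dominant <- FALSE
  cand <- res[res$k >= 1, , drop = FALSE]
  if (nrow(cand) > 0) {
    ord <- order(cand$adjusted_p, -cand$k, cand$term_id)
    res$dominant[res$term_id == cand$term_id[ord[1]]] <- TRUE
  } else {
    message("cluster has no annotated member; no dominant term called")
  }
  res$label <- ifelse(res$dominant, sprintf("%d of %d", res$k, res$n), "")
  res <- res[order(res$adjusted_p, res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Enrichment over a set of ranked clusters
#'
#' Applies [enrich_cluster()] to each cluster of a [rank_clusters()]
#' result and binds the tables with a `cluster_rank` column.
#'
#' @param ranked data.frame from [rank_clusters()] (carries the member
#'   lists as an attribute).
#' @param annotations an [annotation_table()].
#' @param universe universe gene symbols.
#' @return combined `enrichment_result` data.frame with `cluster_rank`.
#' @export
enrich_clusters <- function(ranked, annotations, universe) {
  clusters <- attr(ranked, "clusters")
  if (is.null(clusters)) stop("ranked must come from rank_clusters()")
  res <- lapply(seq_along(clusters), function(i) {
    r <- enrich_cluster(clusters[[i]], annotations, universe)
    if (nrow(r) > 0) r$cluster_rank <- ranked$rank[i]
    r
  })
  res <- res[vapply(res, nrow, integer(1)) > 0]
  if (length(res) == 0) return(invisible(NULL))
  out <- do.call(rbind, res)
  class(out) <- c("enrichment_result", "data.frame")
  out
}
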