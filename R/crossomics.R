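# ---------------------------------------------------------------------------
# Cross-omics intersection of upregulated transcripts and proteins
# ---------------------------------------------------------------------------

#' Shared transcript-protein differential signature
#'
#' Matches the protein differential result against a transcript
#' differential table on canonicalized gene symbols (uppercase, optional
#' alias map) and returns the genes significant and concordantly directed
#' on both sides: `shared_up` collects genes with fold change above 1 and
#' p at or below `p_cut` in both omics, `shared_down` the mirror image.
#' Rows are ordered by protein fold change (descending for up, ascending
#' for down) with lexicographic tie-break, the order used for heat-map
#' rendering. Discordant matches (significant on both sides, opposite
#' direction) are excluded from both lists but reported when
#' `report_discordant = TRUE`.
#'
#' @param de a `differential_result`; gene symbols are taken from `meta`.
#' @param meta a [protein_meta()] mapping accessions to gene symbols.
#' @param transcripts a [transcript_de_table()].
#' @param alias optional alias map from [read_alias_map()], applied to
#'   both sides before matching.
#' @param p_cut significance cutoff applied to both omics.
#' @param fc_cut optional minimum fold change (as a ratio above 1 for up,
#'   below 1/fc_cut for down) applied to both omics.
#' @param report_discordant also return the discordant matches for audit.
#' @return object of class `shared_signature`: list with data.frames
#'   `shared_up`, `shared_down` (columns gene_symbol, accession,
#'   protein_fc, protein_p, transcript_fc, transcript_p), optional
#'   `discordant`, and `stats` (matched / unmatched symbol counts).
#' @export
intersect_signatures <- function(de, meta, transcripts, alias = NULL,
                                 p_cut = 0.05, fc_cut = NULL,
                                 report_discordant = FALSE) {
  stopifnot(inherits(transcripts, "transcript_de_table"))
  if (!all(c("accession", "fold_change", "p_value") %in% colnames(de)))
    stop("de must carry accession, fold_change and p_value columns")
  prot <- data.frame(accession = de$accession,
                     gene_symbol = canonicalize_symbols(
                       meta$gene_symbol[match(de$accession, meta$accession)],
                       alias),
                     fold_change = de$fold_change,
                     p_value = de$p_value,
                     stringsAsFactors = FALSE)
  if ("passed_filter" %in% colnames(de)) prot <- prot[de$passed_filter, ]
  prot <- prot[!is.na(prot$gene_symbol) & !is.na(prot$p_value), ]
  tr <- as.data.frame(transcripts)
  tr$gene_symbol <- canonicalize_symbols(tr$gene_symbol, alias)

  min_fc <- if (is.null(fc_cut)) 1 else max(1, fc_cut)
  p_up <- prot[prot$fold_change > 1 & prot$fold_change >= min_fc &
                 prot$p_value <= p_cut, ]
  p_dn <- prot[prot$fold_change < 1 & prot$fold_change <= 1 / min_fc &
                 prot$p_value <= p_cut, ]
  t_up <- tr[tr$direction == "up" & tr$fold_change >= min_fc &
               tr$p_value <= p_cut, ]
  t_dn <- tr[tr$direction == "down" & tr$fold_change <= 1 / min_fc &
               tr$p_value <= p_cut, ]

  join <- function(p_side, t_side, decreasing) {
    genes <- intersect(p_side$gene_symbol, t_side$gene_symbol)
    pm <- p_side[match(genes, p_side$gene_symbol), , drop = FALSE]
    tm <- t_side[match(genes, t_side$gene_symbol), , drop = FALSE]
    out <- data.frame(gene_symbol = genes,
                      accession = pm$accession,
                      protein_fc = pm$fold_change,
                      protein_p = pm$p_value,
                      transcript_fc = tm$fold_change,
                      transcript_p = tm$p_value,
                      stringsAsFactors = FALSE)
    ord <- if (decreasing) order(-out$protein_fc, out$gene_symbol)
           else order(out$protein_fc, out$gene_symbol)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  shared_up <- join(p_up, t_up, decreasing = TRUE)
  shared_down <- join(p_dn, t_dn, decreasing = FALSE)

  res <- list(shared_up = shared_up, shared_down = shared_down,
              stats = c(protein_up = nrow(p_up), protein_down = nrow(p_dn),
                        transcript_up = nrow(t_up),
                        transcript_down = nrow(t_dn),
                        transcript_unmatched =
                          sum(!tr$gene_symbol %in% prot$gene_symbol),
                        protein_unmatched =
                          sum(!prot$gene_symbol %in% tr$gene_symbol)))
  if (report_discordant) {
    disc <- sort(c(intersect(p_up$gene_symbol, t_dn$gene_symbol),
                   intersect(p_dn$gene_symbol, t_up$gene_symbol)))
    res$discordant <- disc
  }
  class(res) <- "shared_signature"
  res
}

#' @export
print.shared_signature <- function(x, ...) {
  cat(sprintf("shared_signature: %d up, %d down\n",
              nrow(x$shared_up), nrow(x$shared_down)))
  invisible(x)
}

#' Write a shared signature as TSV
#'
#' Up rows first (protein FC descending) then down rows, with a
#' `direction` column, ready for heat-map rendering.
#'
#' @param sig a `shared_signature`.
#' @param path output path.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "shared_signature"))
  up <- sig$shared_up; dn <- sig$shared_down
  if (nrow(up) > 0) up$direction <- "up"
  if (nrow(dn) > 0) dn$direction <- "down"
  out <- rbind(up, dn)
  if (is.null(out) || nrow(out) == 0)
    out <- data.frame(gene_symbol = character(0), accession = character(0),
                      protein_fc = numeric(0), protein_p = numeric(0),
                      transcript_fc = numeric(0), transcript_p = numeric(0),
                      direction = character(0))
  write.table(.fmt_frame(out), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
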