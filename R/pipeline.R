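# ---------------------------------------------------------------------------
# End-to-end orchestration: normalize -> differential -> volcano ->
# abundance -> PCA -> network/MCL/enrichment (up and down separately) ->
# cross-omics signature, with every intermediate written and a JSON report
# ---------------------------------------------------------------------------

#' Pipeline configuration
#'
#' Collects stage parameters, input paths and the simulation settings in
#' one validated object. When `inputs` is `NULL` the pipeline simulates
#' its inputs from `sim` (overriding the simulation seed with the run
#' seed); otherwise `inputs` must name the five tables on disk.
#'
#' @param inputs `NULL`, or a named list with paths `counts`, `meta`,
#'   `edges`, `annotations`, `transcripts` and a named character vector
#'   `group_map` (sample -> group); optional `alias` path.
#' @param sim a [sim_config()] used when `inputs` is `NULL`.
#' @param eps fold-change pseudocount.
#' @param case,control group labels (fold change is case / control).
#' @param p_cut significance cutoff for the network universes and the
#'   cross-omics intersection.
#' @param threshold association-score cutoff for graph building.
#' @param inflation,prune,tol,max_iter MCL parameters.
#' @param top_k clusters to rank and annotate per direction.
#' @param abundance_mode aggregation mode for [abundance_index()].
#' @param seed run seed (drives the simulation when inputs are simulated).
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs = NULL, sim = sim_config(),
                            eps = 0.5, case = "injured",
                            control = "control", p_cut = 0.05,
                            threshold = 0.4, inflation = 1.9,
                            prune = 1e-5, tol = 1e-6, max_iter = 100,
                            top_k = 8, abundance_mode = "mean_all",
                            seed = 1L) {
  cfg <- list(inputs = inputs, sim = sim, eps = eps, case = case,
              control = control, p_cut = p_cut, threshold = threshold,
              inflation = inflation, prune = prune, tol = tol,
              max_iter = max_iter, top_k = top_k,
              abundance_mode = abundance_mode, seed = as.integer(seed))
  if (!is.null(inputs)) {
    need <- c("counts", "meta", "edges", "annotations", "transcripts")
    miss <- setdiff(need, names(inputs))
    if (length(miss) > 0)
      stop("inputs missing entries: ", paste(miss, collapse = ", "))
    for (f in need)
      if (!file.exists(inputs[[f]]))
        stop("input path does not exist: ", inputs[[f]])
    if (is.null(inputs$group_map))
      stop("inputs must include group_map (sample -> group)")
  } else {
    stopifnot(inherits(sim, "sim_config"))
  }
  if (cfg$eps < 0 || cfg$p_cut <= 0 || cfg$p_cut > 1 ||
      cfg$threshold < 0 || cfg$threshold > 1 || cfg$inflation <= 1)
    stop("parameter out of range")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' The JSON mirrors the arguments of [pipeline_config()]; a `sim` object
#' holds [sim_config()] fields.
#'
#' @param path JSON file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- if (!is.null(js$sim)) do.call(sim_config, as.list(js$sim))
         else sim_config()
  inputs <- js$inputs
  if (!is.null(inputs) && !is.null(inputs$group_map))
    inputs$group_map <- unlist(inputs$group_map)
  args <- js[setdiff(names(js), c("sim", "inputs"))]
  do.call(pipeline_config, c(list(inputs = inputs, sim = sim), args))
}

.write_tsv <- function(df, path) {
  write.table(.fmt_frame(df), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# network + clustering + enrichment for one direction; returns report chunk
.network_stage <- function(universe, edges, annotations, enrich_universe,
                           cfg, outdir, tag) {
  if (length(universe) < 2) {
    message("universe '", tag, "' has fewer than 2 nodes; network stage skipped")
    return(list(n_nodes = length(universe), n_edges = 0L, n_clusters = 0L,
                dominant_terms = character(0)))
  }
  ig <- build_graph(edges, universe, threshold = cfg$threshold)
  cs <- mcl_cluster(ig, inflation = cfg$inflation, prune = cfg$prune,
                    tol = cfg$tol, max_iter = cfg$max_iter)
  ranked <- rank_clusters(cs, ig, top_k = cfg$top_k)
  btw <- node_betweenness(ig)
  .write_tsv(data.frame(node = names(cs$membership),
                        cluster = unname(cs$membership),
                        betweenness = unname(btw[names(cs$membership)])),
             file.path(outdir, sprintf("clusters_%s.tsv", tag)))
  .write_tsv(ranked[c("rank", "size", "internal_weight", "members")],
             file.path(outdir, sprintf("subnetworks_%s.tsv", tag)))
  enr <- enrich_clusters(ranked, annotations, enrich_universe)
  dom <- character(0)
  if (!is.null(enr) && nrow(enr) > 0) {
    .write_tsv(enr, file.path(outdir, sprintf("enrichment_%s.tsv", tag)))
    d <- enr[enr$dominant, , drop = FALSE]
    d <- d[order(d$cluster_rank), , drop = FALSE]
    dom <- sprintf("cluster %d: %s (%s)", d$cluster_rank, d$term_name, d$label)
  }
  list(n_nodes = igraph::vcount(ig$graph),
       n_edges = igraph::ecount(ig$graph),
       n_clusters = length(cs$clusters),
       dominant_terms = dom)
}

#' Run the full pipeline
#'
#' Executes normalization, differential expression, volcano and abundance
#' tables, sample PCA, interaction-network construction and MCL clustering
#' separately on the up- and downregulated universes (raw p at or below
#' `p_cut`), per-subnetwork term enrichment with dominant-term calls, and
#' the cross-omics intersection. Every intermediate is written as TSV
#' under `outdir` together with a versioned, machine-readable
#' `report.json` of stage counts. Any stage failure aborts with the stage
#' name.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return the report, invisibly (a named list, same content as
#'   `report.json`).
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (is.null(config$inputs)) {
    sim <- config$sim
    sim$seed <- config$seed
    simdat <- stage("simulate", gen_counts(sim))
    counts <- simdat$counts; meta <- simdat$meta; truth <- simdat$truth
    edges <- stage("simulate", gen_network(sim, truth))
    annotations <- stage("simulate", gen_annotations(sim, truth))
    transcripts <- stage("simulate", gen_transcripts(sim, truth))
    alias <- NULL
    write_count_table(counts, file.path(outdir, "counts.tsv"))
    write_protein_meta(meta, file.path(outdir, "meta.tsv"))
    write_edge_table(edges, file.path(outdir, "edges.tsv"))
    write_annotations(annotations, file.path(outdir, "annotations.tsv"))
    write_transcript_table(transcripts, file.path(outdir, "transcripts.tsv"))
    .write_tsv(data.frame(accession = names(truth$log2fc),
                          log2_fc = unname(truth$log2fc),
                          module = unname(truth$module[truth$gene_of]),
                          transcript_overlap =
                            names(truth$log2fc) %in% truth$overlap_accessions),
               file.path(outdir, "truth.tsv"))
  } else {
    inp <- config$inputs
    counts <- stage("read", read_count_table(inp$counts, inp$group_map))
    meta <- stage("read", read_protein_meta(inp$meta))
    edges <- stage("read", read_edge_table(inp$edges))
    annotations <- stage("read", read_annotations(inp$annotations))
    transcripts <- stage("read", read_transcript_table(inp$transcripts))
    alias <- if (!is.null(inp$alias)) read_alias_map(inp$alias) else NULL
  }

  norm <- stage("normalize", normalize_spectra(counts))
  .write_tsv(data.frame(accession = rownames(norm$values), norm$values,
                        check.names = FALSE),
             file.path(outdir, "normalized.tsv"))

  de <- stage("differential",
              differential_expression(norm, case = config$case,
                                      control = config$control,
                                      eps = config$eps))
  .write_tsv(de, file.path(outdir, "differential.tsv"))
  volc <- stage("volcano", volcano_table(de))
  .write_tsv(volc, file.path(outdir, "volcano.tsv"))

  abund <- stage("abundance",
                 abundance_index(counts, meta, mode = config$abundance_mode))
  .write_tsv(abund, file.path(outdir, "abundance.tsv"))

  pca <- stage("pca", pca_samples(norm))
  .write_tsv(data.frame(sample = rownames(pca$scores),
                        group = unname(norm$groups[rownames(pca$scores)]),
                        PC1 = pca$scores[, 1], PC2 = pca$scores[, 2]),
             file.path(outdir, "pca_scores.tsv"))

  sym <- setNames(meta$gene_symbol, meta$accession)
  tested <- de[de$passed_filter & !is.na(de$p_value), ]
  sig <- tested[tested$p_value <= config$p_cut, ]
  up_univ <- unname(sym[sig$accession[sig$fold_change > 1]])
  down_univ <- unname(sym[sig$accession[sig$fold_change < 1]])
  enr_univ <- unname(sym[tested$accession])

  net_up <- stage("network_up",
                  .network_stage(up_univ, edges, annotations, enr_univ,
                                 config, outdir, "up"))
  net_down <- stage("network_down",
                    .network_stage(down_univ, edges, annotations, enr_univ,
                                   config, outdir, "down"))

  sigshare <- stage("crossomics",
                    intersect_signatures(de, meta, transcripts,
                                         alias = alias,
                                         p_cut = config$p_cut))
  write_signature(sigshare, file.path(outdir, "signature.tsv"))

  report <- list(
    schema_version = "1.0",
    seed = config$seed,
    n_proteins = nrow(counts$counts),
    n_samples = ncol(counts$counts),
    n_passed_filter = sum(de$passed_filter),
    n_tested = nrow(tested),
    n_sig_p05 = sum(tested$p_value <= 0.05),
    n_sig_p01 = sum(tested$p_value <= 0.01),
    n_up_universe = length(up_univ),
    n_down_universe = length(down_univ),
    network_up = net_up,
    network_down = net_down,
    shared_up = nrow(sigshare$shared_up),
    shared_down = nrow(sigshare$shared_down))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
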