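# ---------------------------------------------------------------------------
# Synthetic-data generator: negative-binomial spectral counts with planted
# differential expression, planted interaction-network modules, term
# annotations concentrated in modules, and a transcript table with a
# controlled overlap against the planted up-regulated protein set.
# ---------------------------------------------------------------------------

# independent deterministic substream seed per generator stage, so stages
# can be regenerated in isolation; kept below 2^31 - 1
.substream <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 2654435) %% 2147483647)
}

.mean_residue_mass <- 111.1254  # Da, unweighted mean of the 20 standard residues

#' Simulation configuration
#'
#' Collects every tunable of the synthetic world in one validated object.
#' Counts for protein i in sample j are negative binomial with mean
#' `mu_ij = baseline_scale * L_i^alpha * a_i * lib_j * 2^(beta_i * g_j)`
#' where `L_i` is the simulated protein length (residues), `a_i` a
#' lognormal per-protein abundance, `lib_j` a per-sample library factor,
#' `beta_i` the planted signed log2 fold change (0 for non-DE proteins)
#' and `g_j` the 0/1 group indicator; the variance is `mu + dispersion *
#' mu^2` (`dispersion = 0` degenerates to Poisson).
#'
#' @param n_proteins number of simulated proteins.
#' @param n_per_group samples per group (>= 2); the study design is 3 vs 3.
#' @param baseline_scale expected spectra per residue at unit abundance.
#' @param length_exponent exponent `alpha` on protein length: longer
#'   proteins yield proportionally more assignable spectra at 1.
#' @param abundance_sigma lognormal sd of the per-protein abundance
#'   (meanlog chosen so the mean abundance is 1).
#' @param dispersion negative-binomial overdispersion `phi`.
#' @param library_factors optional positive multiplier per sample (length
#'   `2 * n_per_group`); `NULL` draws them lognormal with sdlog 0.15 to
#'   mimic modest run-to-run loading differences.
#' @param de_fraction fraction of proteins with a planted fold change.
#' @param lfc_mean,lfc_sd mean and sd of the magnitude of the planted log2
#'   fold change; the sign is +/- with equal probability.
#' @param n_modules,module_size planted network modules (disjoint;
#'   `n_modules * module_size <= n_proteins`).
#' @param p_in,p_out within/between-module edge probabilities of the
#'   stochastic block model.
#' @param term_coverage fraction `f` of each module's members carried by
#'   its planted annotation term.
#' @param annotation_background background genes added to each term, as a
#'   fraction of its covered members.
#' @param transcript_overlap fraction `rho` of planted up-regulated
#'   proteins that the transcript table also marks as significantly up.
#' @param n_noise_transcripts transcript-only noise genes (probes without a
#'   protein identification) added to the transcript table.
#' @param seed integer master seed; each generator stage derives its own
#'   substream from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 2000,
                       n_per_group = 3,
                       baseline_scale = 0.05,
                       length_exponent = 1.0,
                       abundance_sigma = 1.0,
                       dispersion = 0.2,
                       library_factors = NULL,
                       de_fraction = 0.1,
                       lfc_mean = 2,
                       lfc_sd = 0.5,
                       n_modules = 4,
                       module_size = 15,
                       p_in = 0.9,
                       p_out = 0.02,
                       term_coverage = 0.8,
                       annotation_background = 0.05,
                       transcript_overlap = 0.5,
                       n_noise_transcripts = 300,
                       seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_per_group = as.integer(n_per_group),
              baseline_scale = baseline_scale,
              length_exponent = length_exponent,
              abundance_sigma = abundance_sigma,
              dispersion = dispersion,
              library_factors = library_factors,
              de_fraction = de_fraction,
              lfc_mean = lfc_mean, lfc_sd = lfc_sd,
              n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              p_in = p_in, p_out = p_out,
              term_coverage = term_coverage,
              annotation_background = annotation_background,
              transcript_overlap = transcript_overlap,
              n_noise_transcripts = as.integer(n_noise_transcripts),
              seed = as.integer(seed))
  if (cfg$n_proteins < 1) stop("n_proteins must be positive")
  if (cfg$n_per_group < 2) stop("n_per_group must be >= 2")
  if (cfg$baseline_scale <= 0) stop("baseline_scale must be positive")
  if (cfg$abundance_sigma <= 0) stop("abundance_sigma must be positive")
  if (cfg$dispersion < 0) stop("dispersion must be >= 0")
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1)
    stop("de_fraction must be in [0,1]")
  if (cfg$transcript_overlap < 0 || cfg$transcript_overlap > 1)
    stop("transcript_overlap must be in [0,1]")
  if (cfg$term_coverage <= 0 || cfg$term_coverage > 1)
    stop("term_coverage must be in (0,1]")
  if (cfg$n_modules * cfg$module_size > cfg$n_proteins)
    stop("n_modules * module_size exceeds n_proteins")
  if (any(cfg$p_in < 0 | cfg$p_in > 1 | cfg$p_out < 0 | cfg$p_out > 1))
    stop("p_in and p_out must be probabilities")
  if (!is.null(cfg$library_factors)) {
    if (length(cfg$library_factors) != 2 * cfg$n_per_group)
      stop("library_factors must have one entry per sample")
    if (any(cfg$library_factors <= 0))
      stop("library_factors must be positive")
  }
  structure(cfg, class = "sim_config")
}

#' Generate spectral counts, protein metadata and the ground truth
#'
#' Draws the count matrix under the model described in [sim_config()],
#' derives protein masses from the simulated lengths, and sets
#' unique-peptide counts to `ceiling(counts / 5)` (at least one peptide
#' wherever a spectrum was assigned) so the two-unique-peptide inclusion
#' filter is exercisable. The returned truth fixes the planted DE set, the
#' planted network-module labels, the per-module term ids and the planted
#' transcript-overlap set, so the same truth drives [gen_network()],
#' [gen_annotations()] and [gen_transcripts()]; it also records the
#' per-protein baseline mean `mu_base` and the realized library factors,
#' making the generator's distributional claims directly checkable.
#'
#' @param config a [sim_config()].
#' @return list with elements `counts` (a [spectral_count_table()]),
#'   `meta` (a [protein_meta()]) and `truth` (class `sim_truth`).
#' @export
gen_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.substream(config$seed, 1L))
  n <- config$n_proteins
  npg <- config$n_per_group
  acc <- sprintf("P%05d", seq_len(n))
  gene <- sprintf("GENE%04d", seq_len(n))
  samples <- c(sprintf("C%d", seq_len(npg)), sprintf("I%d", seq_len(npg)))
  groups <- setNames(rep(c("control", "injured"), each = npg), samples)
  g <- rep(c(0, 1), each = npg)

  len <- pmax(50L, round(rlnorm(n, meanlog = log(450), sdlog = 0.5)))
  mass_kda <- (len * .mean_residue_mass + .water_mass) / 1000
  abund <- rlnorm(n, meanlog = -config$abundance_sigma^2 / 2,
                  sdlog = config$abundance_sigma)
  lib <- config$library_factors
  if (is.null(lib)) lib <- rlnorm(2 * npg, 0, 0.15)

  n_de <- round(config$de_fraction * n)
  de_idx <- if (n_de > 0) sort(sample.int(n, n_de)) else integer(0)
  beta <- numeric(n)
  if (n_de > 0) {
    mag <- pmax(abs(rnorm(n_de, config$lfc_mean, config$lfc_sd)), 0.25)
    beta[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) * mag
  }

  mu <- config$baseline_scale * (len ^ config$length_exponent) * abund
  mu_mat <- outer(mu, lib) * 2 ^ outer(beta, g)
  counts <- if (config$dispersion == 0) {
    matrix(rpois(length(mu_mat), mu_mat), nrow = n)
  } else {
    matrix(rnbinom(length(mu_mat), mu = mu_mat, size = 1 / config$dispersion),
           nrow = n)
  }
  dimnames(counts) <- list(acc, samples)
  up <- ceiling(counts / 5)
  up[counts > 0 & up < 1] <- 1

  # planted modules: disjoint blocks over a random protein subset
  module <- integer(n)
  mod_idx <- sample.int(n, config$n_modules * config$module_size)
  module[mod_idx] <- rep(seq_len(config$n_modules), each = config$module_size)
  names(module) <- gene

  de_up_idx <- de_idx[beta[de_idx] > 0]
  de_down_idx <- de_idx[beta[de_idx] < 0]
  n_overlap <- round(config$transcript_overlap * length(de_up_idx))
  overlap_idx <- if (n_overlap > 0) sort(sample(de_up_idx, n_overlap)) else integer(0)

  meta <- protein_meta(data.frame(
    accession = acc, gene_symbol = gene,
    description = sprintf("simulated protein %d (%d aa)", seq_len(n), len),
    mass_kda = mass_kda, ecm_category = "other",
    stringsAsFactors = FALSE))
  meta$aa_length <- len

  truth <- structure(list(
    mu_base = setNames(mu, acc),
    library_factors = setNames(lib, samples),
    log2fc = setNames(beta, acc),
    gene_of = setNames(gene, acc),
    de_accessions = acc[de_idx],
    de_up_accessions = acc[de_up_idx],
    de_down_accessions = acc[de_down_idx],
    module = module,
    module_terms = sprintf("MOD%02d", seq_len(config$n_modules)),
    overlap_accessions = acc[overlap_idx],
    overlap_genes = gene[overlap_idx]),
    class = "sim_truth")

  list(counts = spectral_count_table(counts, groups, unique_peptides = up),
       meta = meta, truth = truth)
}

#' Generate a stochastic-block-model edge table
#'
#' Pairs of proteins in the same planted module are connected with
#' probability `p_in` and carry association scores Uniform(0.6, 1); all
#' other pairs connect with probability `p_out` and score Uniform(0.15,
#' 0.5), so that the conventional 0.4 score threshold preferentially
#' retains module structure.
#'
#' @param config a [sim_config()].
#' @param truth the `sim_truth` from [gen_counts()].
#' @return an [edge_table()] keyed by gene symbol.
#' @export
gen_network <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  if (config$p_in <= config$p_out)
    warning("p_in <= p_out: module recovery is not guaranteed")
  set.seed(.substream(config$seed, 2L))
  module <- truth$module
  n <- length(module)
  idx <- which(upper.tri(matrix(logical(1), n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  within <- module[i] > 0 & module[i] == module[j]
  keep <- runif(length(i)) < ifelse(within, config$p_in, config$p_out)
  i <- i[keep]; j <- j[keep]; within <- within[keep]
  score <- numeric(length(i))
  score[within] <- runif(sum(within), 0.6, 1.0)
  score[!within] <- runif(sum(!within), 0.15, 0.5)
  edge_table(data.frame(node_a = names(module)[i],
                        node_b = names(module)[j],
                        score = score, stringsAsFactors = FALSE))
}

#' Generate module-concentrated term annotations
#'
#' Emits one term per planted module carrying `term_coverage` of its
#' members plus `annotation_background` (as a fraction of the covered set,
#' rounded) genes drawn uniformly from outside the module.
#'
#' @param config a [sim_config()].
#' @param truth the `sim_truth` from [gen_counts()].
#' @return an [annotation_table()].
#' @export
gen_annotations <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  set.seed(.substream(config$seed, 3L))
  module <- truth$module
  genes <- names(module)
  recs <- lapply(seq_len(config$n_modules), function(m) {
    members <- genes[module == m]
    n_cov <- max(1L, round(config$term_coverage * length(members)))
    covered <- if (n_cov >= length(members)) members else
      sample(members, n_cov)
    n_bg <- round(config$annotation_background * n_cov)
    bg <- if (n_bg > 0) sample(genes[module != m], n_bg) else character(0)
    data.frame(term_id = truth$module_terms[m],
               term_name = sprintf("module-%02d-process", m),
               namespace = "BP",
               gene_symbol = c(covered, bg),
               stringsAsFactors = FALSE)
  })
  annotation_table(do.call(rbind, recs))
}

#' Generate a transcript differential-expression table
#'
#' The planted overlap set (a `transcript_overlap` fraction of the planted
#' up-regulated proteins, fixed in the truth) appears as significantly
#' upregulated transcripts (p drawn Uniform(0.001, 0.05), fold change
#' `2^|beta|`). Noise genes are transcript-only probes (symbols absent
#' from the simulated proteome, as most array probes have no protein
#' identification) with lognormal fold changes and uniform p-values.
#'
#' @param config a [sim_config()].
#' @param truth the `sim_truth` from [gen_counts()].
#' @return a [transcript_de_table()].
#' @export
gen_transcripts <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  set.seed(.substream(config$seed, 4L))
  ov_genes <- truth$overlap_genes
  ov_beta <- abs(truth$log2fc[truth$overlap_accessions])
  planted <- data.frame(gene_symbol = ov_genes,
                        fold_change = unname(2 ^ ov_beta),
                        p_value = runif(length(ov_genes), 0.001, 0.05),
                        direction = rep("up", length(ov_genes)),
                        stringsAsFactors = FALSE)
  n_noise <- config$n_noise_transcripts
  fc <- rlnorm(n_noise, 0, 0.5)
  noise <- data.frame(gene_symbol = sprintf("TRX%04d", seq_len(n_noise)),
                      fold_change = fc,
                      p_value = runif(n_noise),
                      direction = ifelse(fc >= 1, "up", "down"),
                      stringsAsFactors = FALSE)
  transcript_de_table(rbind(planted, noise))
}

#' Differential-expression table implied by the simulation truth
#'
#' Builds the protein-side differential result directly from the planted
#' truth (fold change `2^beta`, nominal p of 1e-6 for planted proteins and
#' 1 otherwise), bypassing the statistical test. Used to validate the
#' cross-omics intersection machinery independently of t-test power.
#'
#' @param truth the `sim_truth` from [gen_counts()].
#' @param meta the matching [protein_meta()].
#' @return data.frame with the columns [differential_expression()] emits.
#' @export
truth_to_differential <- function(truth, meta) {
  stopifnot(inherits(truth, "sim_truth"))
  acc <- names(truth$log2fc)
  beta <- unname(truth$log2fc)
  data.frame(accession = acc,
             gene_symbol = unname(truth$gene_of[acc]),
             fold_change = 2 ^ beta,
             log2_fc = beta,
             p_value = ifelse(beta != 0, 1e-6, 1),
             passed_filter = TRUE,
             stringsAsFactors = FALSE)
}
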