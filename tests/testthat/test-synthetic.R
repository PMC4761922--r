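# Synthetic-data generator: determinism, planted-truth bookkeeping, and
# distributional properties of the count/network models.

test_that("seeded generation is bit-identical and substreams are isolated", {
  cfg <- sim_config(n_proteins = 120, seed = 42)
  a <- gen_counts(cfg)
  b <- gen_counts(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth$log2fc, b$truth$log2fc)
  expect_identical(gen_network(cfg, a$truth), gen_network(cfg, b$truth))
  expect_identical(gen_annotations(cfg, a$truth), gen_annotations(cfg, a$truth))
  expect_identical(gen_transcripts(cfg, a$truth), gen_transcripts(cfg, a$truth))
  # regenerating the network does not disturb the annotation stream
  c1 <- gen_annotations(cfg, a$truth)
  invisible(gen_network(cfg, a$truth))
  expect_identical(gen_annotations(cfg, a$truth), c1)
})

test_that("planted-set sizes follow the stated rounding rules", {
  cfg0 <- sim_config(n_proteins = 100, de_fraction = 0, seed = 3)
  expect_length(gen_counts(cfg0)$truth$de_accessions, 0)

  cfg <- sim_config(n_proteins = 2000, de_fraction = 0.1, seed = 3)
  tr <- gen_counts(cfg)$truth
  expect_length(tr$de_accessions, 200)
  expect_true(all(tr$overlap_accessions %in% tr$de_up_accessions))
  expect_length(tr$overlap_accessions,
                round(0.5 * length(tr$de_up_accessions)))

  expect_error(sim_config(n_per_group = 1), "n_per_group")
  expect_error(sim_config(n_modules = 10, module_size = 20, n_proteins = 100),
               "exceeds n_proteins")
})

test_that("unique peptides follow ceiling(counts/5) with floor 1 on support", {
  d <- gen_counts(sim_config(n_proteins = 200, seed = 9))
  cnt <- d$counts$counts; up <- d$counts$unique_peptides
  expect_true(all(up[cnt == 0] == 0))
  expect_true(all(up[cnt > 0] >= 1))
  expect_identical(up[cnt > 0], pmax(ceiling(cnt[cnt > 0] / 5), 1))
})

test_that("empirical means converge to the stated NB mean model", {
  # 10,000 samples (5,000 per group), no DE, unit library factors: the
  # empirical per-protein mean must approach mu_base within 5% relative
  cfg <- sim_config(n_proteins = 6, n_per_group = 5000, de_fraction = 0,
                    library_factors = rep(1, 10000), n_modules = 1,
                    module_size = 2, n_noise_transcripts = 5, seed = 21)
  d <- gen_counts(cfg)
  emp <- rowMeans(d$counts$counts)
  mu <- d$truth$mu_base[names(emp)]
  expect_true(all(abs(emp - mu) / mu < 0.05))
  # and the variance tracks mu + phi mu^2 for well-observed proteins
  v_emp <- apply(d$counts$counts, 1, var)
  v_th <- mu + cfg$dispersion * mu^2
  big <- mu > 5
  expect_true(all(abs(v_emp[big] - v_th[big]) / v_th[big] < 0.25))
})

test_that("doubling a library factor doubles that sample's expected total", {
  cfg <- sim_config(n_proteins = 3000, n_per_group = 2, de_fraction = 0,
                    library_factors = c(1, 2, 1, 1), n_modules = 2,
                    module_size = 5, seed = 13)
  d <- gen_counts(cfg)
  tot <- colSums(d$counts$counts)
  mu <- d$truth$mu_base
  # var of a sample total under NB(mu_j, phi): sum(mu_j + phi mu_j^2)
  sd_diff <- sqrt(sum(2 * mu + cfg$dispersion * (2 * mu)^2) +
                    4 * sum(mu + cfg$dispersion * mu^2))
  expect_lt(abs(tot[2] - 2 * tot[1]), 3 * sd_diff)
})

test_that("SBM network hits boundary cases and its binomial expectation", {
  cfg1 <- sim_config(n_proteins = 40, n_modules = 3, module_size = 6,
                     p_in = 1, p_out = 0, seed = 5)
  tr <- gen_counts(cfg1)$truth
  ed <- gen_network(cfg1, tr)
  expect_equal(nrow(ed), 3 * choose(6, 2))  # three cliques, no cross edges
  mods <- tr$module[ed$node_a]
  expect_true(all(mods == tr$module[ed$node_b] & mods > 0))
  expect_true(all(ed$score >= 0.6))

  # expected edge count: within C(m,2) p_in per module + cross pairs p_out
  cfg2 <- sim_config(n_proteins = 60, n_modules = 4, module_size = 15,
                     p_in = 0.9, p_out = 0.02)
  n_within <- 4 * choose(15, 2)
  n_cross <- choose(60, 2) - n_within
  expected <- n_within * 0.9 + n_cross * 0.02
  v <- n_within * 0.9 * 0.1 + n_cross * 0.02 * 0.98
  counts <- vapply(1:20, function(s) {
    cfg2$seed <- s
    nrow(gen_network(cfg2, gen_counts(cfg2)$truth))
  }, numeric(1))
  expect_lt(abs(mean(counts) - expected), 3 * sqrt(v / 20))

  cfg3 <- sim_config(p_in = 0.1, p_out = 0.2, n_proteins = 50,
                     n_modules = 2, module_size = 5, seed = 1)
  expect_warning(gen_network(cfg3, gen_counts(cfg3)$truth), "p_in <= p_out")
})

test_that("annotations cover modules as configured", {
  cfg <- sim_config(n_proteins = 80, n_modules = 3, module_size = 8,
                    term_coverage = 1, annotation_background = 0, seed = 2)
  tr <- gen_counts(cfg)$truth
  ann <- gen_annotations(cfg, tr)
  for (m in 1:3) {
    members <- names(tr$module)[tr$module == m]
    expect_setequal(ann$gene_symbol[ann$term_id == tr$module_terms[m]],
                    members)
  }
})

test_that("transcript overlap obeys rho including the boundaries", {
  for (rho in c(0, 0.5, 1)) {
    cfg <- sim_config(n_proteins = 600, transcript_overlap = rho, seed = 8)
    d <- gen_counts(cfg)
    trx <- gen_transcripts(cfg, d$truth)
    up_genes <- trx$gene_symbol[trx$direction == "up" & trx$p_value <= 0.05]
    planted_up <- d$truth$gene_of[d$truth$de_up_accessions]
    expect_length(d$truth$overlap_genes,
                  round(rho * length(planted_up)))
    expect_true(all(d$truth$overlap_genes %in% up_genes))
    if (rho == 1) expect_true(all(planted_up %in% up_genes))
  }
})
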