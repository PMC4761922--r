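# Normalization, differential expression, volcano, abundance index, ddCt.

test_that("normalization applies the mean-total/sample-total ratio", {
  # totals (100, 200, 300), one protein at (10, 10, 30) -> (20, 10, 20)
  m <- matrix(c(10, 90, 10, 190, 30, 270), nrow = 2,
              dimnames = list(c("PA", "PB"), c("s1", "s2", "s3")))
  x <- spectral_count_table(m, c(s1 = "a", s2 = "a", s3 = "b"))
  nr <- normalize_spectra(x)
  expect_equal(nr$mean_total, 200)
  expect_equal(unname(nr$values["PA", ]), c(20, 10, 20))
  expect_equal(unname(colSums(nr$values)), rep(200, 3))

  # equal totals: identity
  eq <- make_equal_total_table(matrix(c(5, 3, 2, 6), 2,
                                      dimnames = list(c("P1", "P2"),
                                                      c("C1", "I1"))),
                               groups33)
  expect_equal(normalize_spectra(eq)$values, eq$counts)

  z <- spectral_count_table(matrix(c(1, 0), 1, 2,
                                   dimnames = list("P1", c("s1", "s2"))),
                            c(s1 = "a", s2 = "b"))
  expect_error(normalize_spectra(z), "zero total spectra: s2")
})

test_that("column totals equal the mean raw total on random fixtures", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(3:40, 1); k <- sample(3:8, 1)
    m <- matrix(rpois(n * k, 8) + 1, n,
                dimnames = list(sprintf("P%d", 1:n), sprintf("s%d", 1:k)))
    x <- spectral_count_table(m, setNames(rep("g", k), colnames(m)))
    nr <- normalize_spectra(x)
    expect_equal(unname(colSums(nr$values)), rep(nr$mean_total, k),
                 tolerance = 1e-12)
  }
})

test_that("differential expression matches the hand-evaluated pooled t", {
  v <- matrix(c(1, 2, 3, 7, 8, 9), nrow = 1,
              dimnames = list("P1", names(groups33)))
  de <- differential_expression(make_norm(v, groups33), eps = 0)
  # hand sum: means 2 and 8, pooled variance 1, se = sqrt(2/3), df = 4
  expect_equal(de$t_stat, 6 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(abs(de$t_stat), 7.348, tolerance = 1e-3)
  orc <- oracle_pooled_t(c(1, 2, 3), c(7, 8, 9))
  expect_equal(de$p_value, orc$p, tolerance = 1e-12)
  expect_lt(abs(de$p_value - 0.0018), 3e-4)
  expect_equal(de$fold_change, 4)
  expect_equal(de$tier, "p01")
})

test_that("degenerate and pseudocount cases behave as documented", {
  v <- matrix(c(5, 5, 5, 5, 5, 5), nrow = 1,
              dimnames = list("P1", names(groups33)))
  expect_message(de <- differential_expression(make_norm(v, groups33),
                                               eps = 0),
                 "degenerate")
  expect_equal(de$fold_change, 1)
  expect_equal(de$p_value, 1)
  expect_true(de$degenerate)

  v2 <- matrix(c(0, 0, 0, 4, 4, 4), nrow = 1,
               dimnames = list("P1", names(groups33)))
  de2 <- suppressMessages(
    differential_expression(make_norm(v2, groups33), eps = 0.5))
  expect_equal(de2$fold_change, 4.5 / 0.5)

  expect_error(differential_expression(make_norm(v, groups33), eps = -1),
               "non-negative")
})

test_that("the unique-peptide inclusion filter withholds p-values", {
  v <- matrix(c(1, 2, 3, 9, 8, 7, 1, 2, 3, 9, 8, 7), nrow = 2, byrow = TRUE,
              dimnames = list(c("PA", "PB"), names(groups33)))
  up <- v; up["PB", ] <- 1  # PB never reaches 2 unique peptides
  de <- differential_expression(make_norm(v, groups33, unique_peptides = up))
  expect_true(de$passed_filter[de$accession == "PA"])
  expect_false(de$passed_filter[de$accession == "PB"])
  expect_true(is.na(de$p_value[de$accession == "PB"]))
  expect_false(is.na(de$p_value[de$accession == "PA"]))
})

test_that("Welch flag reproduces stats::t.test", {
  set.seed(7)
  v <- matrix(rlnorm(6, 3, 0.4), nrow = 1,
              dimnames = list("P1", names(groups33)))
  de <- differential_expression(make_norm(v, groups33), var_equal = FALSE)
  ref <- t.test(v[1, 4:6], v[1, 1:3], var.equal = FALSE)
  expect_equal(de$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("volcano table computes the log axes and tiers", {
  de <- data.frame(accession = c("A", "B", "C"),
                   fold_change = c(1, 8, 2),
                   log2_fc = log2(c(1, 8, 2)),
                   p_value = c(1, 0.001, 0.05),
                   passed_filter = TRUE,
                   tier = c("ns", "p01", "p05"))
  class(de) <- c("differential_result", "data.frame")
  v <- volcano_table(de)
  expect_equal(v$log2_fc, c(0, 3, 1))
  expect_equal(v$neg_log10_p, c(0, 3, -log10(0.05)))
  expect_equal(v$tier, c("ns", "p01", "p05"))  # 0.05 boundary inclusive
  expect_equal(v$direction, c("flat", "up", "up"))
})

test_that("abundance index divides aggregate spectra by mass", {
  m <- matrix(c(22, 22, 50, 10), nrow = 2, byrow = TRUE,
              dimnames = list(c("PA", "PB"), c("s1", "s2")))
  x <- spectral_count_table(m, c(s1 = "a", s2 = "a"))
  meta <- protein_meta(data.frame(accession = c("PA", "PB"),
                                  gene_symbol = c("GA", "GB"),
                                  description = "", mass_kda = c(10, 60),
                                  ecm_category = "other"))
  ai <- abundance_index(x, meta, mode = "mean_all")
  expect_equal(ai$ratio[ai$accession == "PA"], 2.2)
  expect_equal(ai$rank, c(1, 2))
  ai_sum <- abundance_index(x, meta, mode = "sum_all")
  expect_equal(ai_sum$aggregate[ai_sum$accession == "PA"], 44)

  # equal masses: ranking reduces to ranking by aggregate spectra
  meta2 <- meta; meta2$mass_kda <- c(10, 10)
  ai2 <- abundance_index(x, meta2)
  expect_equal(ai2$accession[order(ai2$rank)],
               names(sort(rowMeans(m), decreasing = TRUE)))

  # scale consistency: tripling counts triples ratios, preserves ranks
  x3 <- spectral_count_table(m * 3, c(s1 = "a", s2 = "a"))
  ai3 <- abundance_index(x3, meta)
  expect_equal(ai3$ratio, ai$ratio * 3)
  expect_equal(ai3$rank, ai$rank)

  meta_na <- meta; meta_na$mass_kda[2] <- NA
  expect_error(abundance_index(x, meta_na), "missing molecular mass.*PB")
})

test_that("ddCt fold change follows 2^-ddCt", {
  expect_equal(ddct_fold_change(20, 15, 22, 17), 1)   # ddCt = 0
  expect_equal(ddct_fold_change(19, 15, 22, 17), 2)   # ddCt = -1
  expect_equal(ddct_fold_change(24, 18, 26, 18), 4)   # ddCt = -2
  expect_error(ddct_fold_change(-1, 18, 26, 18), "positive")
})
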